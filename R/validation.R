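#' Inner leave-one-out selection of the number of latent variables
#'
#' For each candidate component count `1..a_max`, every training sample
#' is left out in turn, a PLS-DA model is fitted on the rest (with
#' scaling recomputed on that inner fold) and the left-out sample is
#' classified; the count minimising the inner misclassification total is
#' returned, ties going to the smaller (more parsimonious) model.
#'
#' @param x Training samples x variables matrix.
#' @param labels Training class labels.
#' @param a_max Largest component count examined; capped at
#'   `min(n - 2, p)` because each inner fold loses one more sample.
#' @param class_order Optional ordered class names.
#' @return The selected component count, with the per-count inner
#'   misclassification totals in attribute `errors`.
#' @export
inner_loo_select_ncomp <- function(x, labels, a_max = 10L,
                                   class_order = NULL) {
  x <- as_num_matrix(x)
  if (nrow(x) < 3L)
    stop("inner cross-validation needs at least 3 samples", call. = FALSE)
  y <- dummy_code(labels, class_order)
  a_max <- min(stopifnot_scalar_count(a_max, "a_max"),
               nrow(x) - 2L, ncol(x))
  errs <- as.integer(.cpp_inner_errs(x, y, a_max))
  sel <- which.min(errs)  # which.min takes the first minimum: smallest A
  structure(as.integer(sel), errors = errs)
}

#' Double (two-nested leave-one-out) cross-validated PLS-DA
#'
#' The unbiased classification protocol: in the outer loop each sample is
#' set aside in turn and a PLS-DA model is built on the remainder; the
#' component count for that model is chosen by an inner leave-one-out
#' loop over the remaining samples ([inner_loo_select_ncomp()]). The
#' left-out sample is then classified by a model that never saw it —
#' autoscaling parameters included, since scaling is recomputed on every
#' training portion and applied to its held-out sample. The procedure
#' yields one model (and one honest class prediction) per sample; the
#' per-model regression coefficients feed [rank_products()].
#'
#' @param x Samples x variables matrix (or fused matrix). Scaling is
#'   handled internally per fold; `x` should be the feature matrix, not
#'   pre-scaled per-fold.
#' @param labels Class labels, one per sample (>= 2 classes, each with at
#'   least 2 samples).
#' @param a_max Cap on the number of latent variables (default
#'   `min(n - 3, p, 10)`).
#' @param class_order Optional ordered class names.
#' @return An object of class `plsda_dcv`: `predictions` (data.frame of
#'   sample, true and predicted class, selected component count),
#'   `misclassifications` (count M), `coefficients`
#'   (variables x classes x models array) and bookkeeping fields.
#' @export
#' @examples
#' gen <- generate_feature_blocks(sim_config(n_per_class = 8,
#'   platform_dims = c(ms = 30), n_discriminative = c(ms = 5),
#'   effect_size = 4, seed = 7))
#' dcv <- double_cv(gen$blocks$ms$values, generate_metadata(
#'   sim_config(n_per_class = 8, platform_dims = c(ms = 30)))$group)
#' dcv$misclassifications
double_cv <- function(x, labels, a_max = NULL, class_order = NULL) {
  x <- as_num_matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("double cross-validation needs at least 4 samples",
                   call. = FALSE)
  if (length(labels) != n)
    stop("`labels` must have one entry per sample", call. = FALSE)
  y <- dummy_code(labels, class_order)
  class_order <- attr(y, "class_order")
  if (length(class_order) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  if (min(colSums(y)) < 2L)
    stop("every class needs at least 2 samples (outer folds would lose ",
         "a class)", call. = FALSE)
  if (is.null(a_max)) a_max <- 10L
  a_max <- min(stopifnot_scalar_count(a_max, "a_max"), n - 3L, ncol(x))
  if (a_max < 1L) stop("too few samples for the nested loops", call. = FALSE)
  res <- .cpp_double_cv(x, y, a_max)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  predicted <- class_order[res$predicted]
  dimnames(res$coefficients) <- list(colnames(x), class_order, ids)
  structure(list(
    predictions = data.frame(sample_id = ids,
                             true = as.character(labels),
                             predicted = predicted,
                             ncomp = as.integer(res$ncomp_selected),
                             stringsAsFactors = FALSE),
    misclassifications = sum(predicted != as.character(labels)),
    n = n, a_max = a_max, class_order = class_order,
    y_predicted = res$y_predicted,
    coefficients = res$coefficients), class = "plsda_dcv")
}

#' @export
print.plsda_dcv <- function(x, ...) {
  cat(sprintf("double cross-validated PLS-DA: %d/%d misclassified\n",
              x$misclassifications, x$n))
  cat("  selected components:",
      paste(sort(unique(x$predictions$ncomp)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.plsda_dcv <- function(object, ...) {
  out <- list(
    misclassifications = object$misclassifications,
    error_rate = object$misclassifications / object$n,
    confusion = table(true = object$predictions$true,
                      predicted = factor(object$predictions$predicted,
                                         levels = object$class_order)),
    ncomp = table(object$predictions$ncomp))
  class(out) <- "summary.plsda_dcv"
  out
}

#' @export
print.summary.plsda_dcv <- function(x, ...) {
  cat(sprintf("misclassifications: %d (error rate %.3f)\n",
              x$misclassifications, x$error_rate))
  print(x$confusion)
  cat("selected component counts:\n")
  print(x$ncomp)
  invisible(x)
}

#' Permutation test of the double cross-validation error
#'
#' Re-runs the complete double cross-validation — inner component
#' selection included — on class labels randomly shuffled among the
#' samples (class sizes preserved), building the null distribution of
#' the misclassification count M. The p-value uses the add-one
#' correction `p = (1 + #(null M <= observed M)) / (1 + n_permutations)`,
#' so it can never be exactly zero.
#'
#' @param x Samples x variables matrix (or fused matrix).
#' @param labels Class labels.
#' @param n_permutations Number of label shuffles (>= 19; default 1000).
#' @param a_max,class_order Passed to [double_cv()].
#' @param seed RNG seed for the shuffles.
#' @return An object of class `plsda_perm`: `observed` (the true-label
#'   [double_cv()] result), `null_m` (null misclassification counts),
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(x, labels, n_permutations = 1000L,
                             a_max = NULL, class_order = NULL,
                             seed = NULL) {
  if (n_permutations < 19L)
    stop("`n_permutations` must be at least 19", call. = FALSE)
  x <- as_num_matrix(x)
  observed <- double_cv(x, labels, a_max = a_max,
                        class_order = class_order)
  null_m <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      one <- function() double_cv(x, sample(labels), a_max = a_max,
                                  class_order = class_order)
      r <- tryCatch(one(), error = function(e) tryCatch(one(),
        error = function(e2) stop("permutation ", b, " failed twice: ",
                                  conditionMessage(e2), call. = FALSE)))
      r$misclassifications
    }, integer(1))
  })
  p <- (1 + sum(null_m <= observed$misclassifications)) /
    (1 + n_permutations)
  structure(list(observed = observed, null_m = null_m, p_value = p,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "plsda_perm")
}

#' @export
print.plsda_perm <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed M = %d/%d, p = %.4g (%d permutations)\n",
    x$observed$misclassifications, x$observed$n, x$p_value,
    x$n_permutations))
  cat(sprintf("  null M: median %.0f, range %d-%d\n",
              stats::median(x$null_m), min(x$null_m), max(x$null_m)))
  invisible(x)
}

#' Rank products of PLS-DA regression coefficients across CV models
#'
#' Within each of the n cross-validation models, variables are ranked by
#' descending absolute regression coefficient (rank 1 = largest |B|;
#' ties receive average ranks). The per-variable ranks are combined
#' across models as a product — computed as the sum of log-ranks, which
#' is monotone-equivalent and cannot overflow — and reported alongside
#' the geometric-mean rank `exp(mean(log(rank)))`. Variables with low
#' rank products were consistently near the top of the coefficient
#' rankings and are the most important for the class contrast.
#'
#' @param dcv A [double_cv()] result (or a variables x classes x models
#'   coefficient array).
#' @return An object of class `rank_product_table`: matrices `log_sum`
#'   and `geo_mean_rank` (variables x classes), `n_models`,
#'   `class_order`.
#' @export
rank_products <- function(dcv) {
  B <- if (inherits(dcv, "plsda_dcv")) dcv$coefficients else dcv
  if (!(is.array(B) && length(dim(B)) == 3L))
    stop("need a variables x classes x models coefficient array",
         call. = FALSE)
  p <- dim(B)[1]; q <- dim(B)[2]; n <- dim(B)[3]
  log_sum <- matrix(0, p, q, dimnames = dimnames(B)[1:2])
  for (i in seq_len(n)) {
    for (cc in seq_len(q)) {
      r <- rank(-abs(B[, cc, i]), ties.method = "average")
      log_sum[, cc] <- log_sum[, cc] + log(r)
    }
  }
  structure(list(log_sum = log_sum,
                 geo_mean_rank = exp(log_sum / n),
                 n_models = n,
                 class_order = colnames(log_sum)),
            class = "rank_product_table")
}

#' @export
print.rank_product_table <- function(x, n = 10L, ...) {
  cat(sprintf("rank products over %d models (%d variables)\n",
              x$n_models, nrow(x$log_sum)))
  ord <- order(x$log_sum[, 1L])[seq_len(min(n, nrow(x$log_sum)))]
  cat(sprintf("top variables (class %s):\n", x$class_order[1L]))
  print(data.frame(variable = rownames(x$log_sum)[ord],
                   geo_mean_rank = round(x$geo_mean_rank[ord, 1L], 2)),
        row.names = FALSE)
  invisible(x)
}

#' Report the most discriminating variables with per-class statistics
#'
#' Selects the `top_k` variables with the lowest rank product for a
#' class and tabulates, per class, the mean and standard deviation on
#' the raw measurement scale plus a higher/lower flag marking where each
#' class's mean sits among the compared groups (the colour coding of the
#' usual discriminant tables).
#'
#' @param rp A [rank_products()] table.
#' @param x Raw (unscaled) samples x variables matrix the
#'   cross-validation was run on.
#' @param labels Class labels, one per sample.
#' @param top_k Number of variables to report (default 10).
#' @param class Class column of the rank-product table to order by
#'   (default the first; for two-class runs the two columns give the
#'   same ordering).
#' @return A data.frame with one row per reported variable: variable
#'   name, geometric-mean rank, and per class `mean_<class>`,
#'   `sd_<class>`, `level_<class>` ("higher"/"lower"/"mid").
#' @export
summarize_discriminators <- function(rp, x, labels, top_k = 10L,
                                     class = 1L) {
  stopifnot(inherits(rp, "rank_product_table"))
  x <- as_num_matrix(x)
  stopifnot(nrow(x) == length(labels),
            ncol(x) == nrow(rp$log_sum))
  top_k <- min(stopifnot_scalar_count(top_k, "top_k"), nrow(rp$log_sum))
  ord <- order(rp$log_sum[, class])[seq_len(top_k)]
  classes <- rp$class_order
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  out <- data.frame(variable = rownames(rp$log_sum)[ord],
                    geo_mean_rank = rp$geo_mean_rank[ord, class],
                    row.names = NULL, stringsAsFactors = FALSE)
  means <- sapply(classes, function(cl)
    colMeans(x[labels == cl, ord, drop = FALSE]))
  if (top_k == 1L) means <- matrix(means, nrow = 1L,
                                   dimnames = list(NULL, classes))
  for (cl in classes) {
    out[[paste0("mean_", cl)]] <- means[, cl]
    out[[paste0("sd_", cl)]] <-
      apply(x[labels == cl, ord, drop = FALSE], 2, sd)
  }
  for (cl in classes) {
    out[[paste0("level_", cl)]] <- apply(means, 1, function(m)
      if (m[cl] == max(m)) "higher"
      else if (m[cl] == min(m)) "lower" else "mid")
  }
  out
}
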