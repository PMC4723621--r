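#' A single platform's feature block
#'
#' Samples-by-variables intensity matrix for one analytical platform,
#' with unique sample IDs and variable names and no missing values — the
#' unit that sample alignment, autoscaling and concatenation operate on.
#'
#' @param values Numeric samples x variables matrix; row names are sample
#'   IDs, column names variable names.
#' @param platform Platform tag (single string).
#' @return An object of class `feature_block` with fields `platform`,
#'   `sample_ids`, `variable_names`, `values`.
#' @export
feature_block <- function(values, platform) {
  values <- as_num_matrix(values, "values")
  stopifnot(is.character(platform), length(platform) == 1L)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s:v%04d", platform, seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample IDs in block '", platform, "'", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated variable names in block '", platform, "'",
         call. = FALSE)
  if (anyNA(values))
    stop("missing values in block '", platform, "'", call. = FALSE)
  structure(list(platform = platform,
                 sample_ids = rownames(values),
                 variable_names = colnames(values),
                 values = values),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block '%s': %d samples x %d variables\n",
              x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$values)

#' Restrict blocks to their common samples, in a common order
#'
#' Keeps only the samples present in every block and puts all blocks in
#' one canonical order (the surviving samples in the first block's
#' order). A warning lists the samples each block loses.
#'
#' @param blocks List of [feature_block()]s.
#' @return List of aligned `feature_block`s.
#' @export
align_samples <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  ids <- Reduce(intersect, lapply(blocks, function(b) b$sample_ids))
  if (length(ids) == 0)
    stop("no sample is present in every block", call. = FALSE)
  ids <- blocks[[1L]]$sample_ids[blocks[[1L]]$sample_ids %in% ids]
  dropped <- lapply(blocks, function(b) setdiff(b$sample_ids, ids))
  if (any(lengths(dropped) > 0)) {
    msg <- mapply(function(b, d)
      sprintf("%s: %s", b$platform, paste(d, collapse = ", ")),
      blocks[lengths(dropped) > 0], dropped[lengths(dropped) > 0])
    warning("dropped samples absent from some block — ",
            paste(msg, collapse = "; "), call. = FALSE)
  }
  lapply(blocks, function(b)
    feature_block(b$values[ids, , drop = FALSE], b$platform))
}

#' Autoscale a matrix (unit-variance scaling)
#'
#' Centers every column to mean 0 and divides by its sample standard
#' deviation (n-1 denominator), giving every variable equal a priori
#' weight regardless of its measurement scale. Zero-variance columns are
#' undefined under autoscaling and are removed with a warning.
#'
#' @param x Numeric matrix (or `feature_block`).
#' @return The scaled matrix, with attributes `center` and `scale`
#'   holding the per-column means and SDs used.
#' @export
#' @examples
#' drop(autoscale(matrix(1:3)))
autoscale <- function(x) {
  x <- as_num_matrix(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    warning("removed ", sum(s == 0), " zero-variance column(s): ",
            paste(head(colnames(x)[s == 0], 5), collapse = ", "),
            call. = FALSE)
    x <- x[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  m <- colMeans(x)
  out <- sweep(sweep(x, 2, m, `-`), 2, s, `/`)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Fuse aligned platform blocks into one analysis matrix
#'
#' Column-concatenates the blocks (optionally autoscaling every variable
#' first) into a single samples-by-variables matrix, recording each
#' column's platform of origin. With scaling on, every column of the
#' fused matrix has mean 0 and SD 1, so no platform dominates by virtue
#' of its intensity scale or variable count.
#'
#' Note the full-matrix scaling here serves unsupervised exploration
#' (PCA, clustering); supervised cross-validation recomputes scaling on
#' each training fold internally.
#'
#' @param blocks List of aligned [feature_block()]s (see
#'   [align_samples()]).
#' @param scale Autoscale each variable (default `TRUE`)?
#' @return An object of class `fused_matrix`: fields `values`,
#'   `sample_ids`, `platform` (per column), `variable_names`, and (when
#'   scaled) `center`/`scale`.
#' @export
concatenate_blocks <- function(blocks, scale = TRUE) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  ids <- blocks[[1L]]$sample_ids
  for (b in blocks)
    if (!identical(b$sample_ids, ids))
      stop("blocks are not sample-aligned; run align_samples() first",
           call. = FALSE)
  vals <- lapply(blocks, function(b) b$values)
  platform <- unlist(lapply(blocks, function(b)
    rep(b$platform, ncol(b$values))), use.names = FALSE)
  x <- do.call(cbind, vals)
  center <- scl <- NULL
  if (scale) {
    p0 <- ncol(x)
    x <- autoscale(x)
    if (ncol(x) < p0)
      platform <- platform[match(colnames(x),
                                 unlist(lapply(vals, colnames)))]
    center <- attr(x, "center")
    scl <- attr(x, "scale")
    attr(x, "center") <- attr(x, "scale") <- NULL
  }
  structure(list(values = x, sample_ids = ids, platform = platform,
                 variable_names = colnames(x), scaled = scale,
                 center = center, scale = scl),
            class = "fused_matrix")
}

#' @export
print.fused_matrix <- function(x, ...) {
  cat(sprintf("fused_matrix: %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "autoscaled" else "raw"))
  tab <- table(factor(x$platform, levels = unique(x$platform)))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.fused_matrix <- function(x) dim(x$values)
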