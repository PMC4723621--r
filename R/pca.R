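#' Principal component analysis by singular value decomposition
#'
#' PCA of an autoscaled (or at least column-centered) matrix. Scores are
#' `U D`, loadings `V`; the variance fraction of component k is
#' `sigma_k^2 / sum(sigma^2)`. For reproducibility across linear-algebra
#' backends, each loading vector's largest-magnitude entry is made
#' positive.
#'
#' @param x Numeric matrix or [concatenate_blocks()] result.
#' @param max_components Number of components to keep; at most
#'   `min(n - 1, p)` (the default).
#' @return An object of class `pca_model` with `scores`
#'   (samples x components), `loadings` (variables x components),
#'   `explained` (variance fractions) and `sdev`.
#' @export
pca_fit <- function(x, max_components = NULL) {
  x <- as_num_matrix(x)
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (is.null(max_components)) max_components <- kmax
  if (max_components > kmax)
    stop("`max_components` cannot exceed min(n - 1, p) = ", kmax,
         call. = FALSE)
  s <- svd(x, nu = max_components, nv = max_components)
  d <- s$d[seq_len(max_components)]
  # sign convention: largest-|entry| of each loading positive
  flip <- vapply(seq_len(max_components), function(k) {
    v <- s$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(s$v, 2, flip, `*`)
  scores <- sweep(s$u, 2, d * flip, `*`)
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC",
                                                   seq_len(max_components))
  structure(list(scores = scores, loadings = loadings,
                 explained = s$d^2 / sum(s$d^2), sdev = s$d / sqrt(n - 1)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("pca_model: %d components\n", k))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained[seq_len(min(k, 8))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_model <- function(x, components = c(1, 2), labels = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  pct <- 100 * x$explained[components]
  graphics::plot(s[, 1], s[, 2],
                 xlab = sprintf("PC%d (%.1f%%)", components[1], pct[1]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2], pct[2]),
                 ...)
  if (!is.null(labels)) graphics::text(s[, 1], s[, 2], labels, pos = 3)
  invisible(x)
}

# Rank-`rank` reconstruction of a matrix with missing entries by EM /
# iterative SVD: missing cells start at 0 (the column mean of autoscaled
# data) and are refilled with the current low-rank fit until convergence.
em_svd_reconstruct <- function(x, rank, tol = 1e-4, max_iter = 200L) {
  miss <- is.na(x)
  xc <- x
  xc[miss] <- 0
  for (it in seq_len(max_iter)) {
    s <- svd(xc, nu = rank, nv = rank)
    fit <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    delta <- sqrt(mean((fit[miss] - xc[miss])^2))
    xc[miss] <- fit[miss]
    if (delta < tol) break
  }
  fit
}

#' Cross-validated count of significant principal components
#'
#' Element-wise k-fold cross-validation of the PCA rank: matrix cells are
#' randomly split into `folds` groups; each group in turn is set missing
#' and reconstructed from rank-a models fitted by EM on the remaining
#' cells. The predictive power of component a is
#' `Q2_a = 1 - PRESS_a / PRESS_(a-1)` (with `PRESS_0` the total sum of
#' squares of the held-out cells); components are counted while
#' `Q2 > threshold`.
#'
#' @param x Autoscaled numeric matrix or fused matrix.
#' @param max_components Largest rank examined (default
#'   `min(n - 1, p, 10)`).
#' @param folds Number of element folds (default 7).
#' @param threshold Q2 acceptance limit (default 0.05).
#' @param seed RNG seed for the fold assignment.
#' @return Integer: the number of leading components with `Q2` above the
#'   threshold.
#' @export
select_significant_pcs <- function(x, max_components = NULL, folds = 7L,
                                   threshold = 0.05, seed = NULL) {
  x <- as_num_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(max_components)) max_components <- min(n - 1L, p, 10L)
  max_components <- min(max_components, n - 1L, p)
  fold_of <- with_seed(seed,
    matrix(sample(rep(seq_len(folds), length.out = n * p)), n, p))
  press_prev <- sum(x^2)
  n_sig <- 0L
  for (a in seq_len(max_components)) {
    press <- 0
    for (f in seq_len(folds)) {
      xm <- x
      xm[fold_of == f] <- NA
      fit <- em_svd_reconstruct(xm, a)
      press <- press + sum((x[fold_of == f] - fit[fold_of == f])^2)
    }
    q2 <- 1 - press / press_prev
    if (q2 <= threshold) break
    n_sig <- a
    press_prev <- press
  }
  n_sig
}
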