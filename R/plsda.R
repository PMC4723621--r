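#' Dummy-code class labels as a 0/1 indicator matrix
#'
#' One column per class; each row carries a single 1 in its class column.
#'
#' @param labels Vector (or factor) of class labels.
#' @param class_order Ordered class names; defaults to the sorted unique
#'   labels. Also fixes the tie-break order of [classify()].
#' @return Samples x classes 0/1 matrix with attribute `class_order`.
#' @export
#' @examples
#' dummy_code(c("a", "b", "a"))
dummy_code <- function(labels, class_order = NULL) {
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- sort(unique(labels))
  idx <- match(labels, class_order)
  if (anyNA(idx))
    stop("label(s) not in `class_order`: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  y <- matrix(0, length(labels), length(class_order),
              dimnames = list(names(labels), class_order))
  y[cbind(seq_along(idx), idx)] <- 1
  attr(y, "class_order") <- class_order
  y
}

#' Fit a PLS(-DA) model by NIPALS
#'
#' PLS2 regression of a response matrix on predictors via latent
#' variables: each component extracts the direction of X with maximal
#' covariance with Y, X is deflated, Y is not. For discriminant analysis
#' pass class labels (factor/character) as `y`; they are dummy-coded as a
#' 0/1 indicator matrix. Regression coefficients are recovered in closed
#' form as `B = W (P'W)^-1 Q'`, mapping autoscaled predictors to centered
#' responses.
#'
#' @param x Numeric samples x variables matrix.
#' @param y Class labels (factor/character) or a numeric response matrix.
#' @param ncomp Number of latent variables. If this exceeds the
#'   achievable rank the model is fitted up to that rank with a warning.
#' @param scale Autoscale `x` internally (default). With
#'   `scale = FALSE`, `x` is used as given (it should already be
#'   centered/scaled) and only `y` is centered.
#' @param class_order Optional ordered class names (label `y` only).
#' @param tol,maxiter Convergence tolerance and iteration cap of the
#'   per-component NIPALS inner loop.
#' @return An object of class `plsda`: weights `W`, X-loadings `P`,
#'   scores `T`, Y-loadings `Q`, coefficients `B`, the training scaling
#'   parameters, and `class_order` when fitted on labels.
#' @seealso [predict.plsda()], [double_cv()]
#' @export
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- ifelse(x[, 1] > 0, "a", "b")
#' fit <- pls_fit(x, y, ncomp = 2)
#' table(predict(fit, x, type = "class"), y)
pls_fit <- function(x, y, ncomp = 2L, scale = TRUE, class_order = NULL,
                    tol = 1e-12, maxiter = 500L) {
  x <- as_num_matrix(x)
  if (!is.numeric(y)) {
    y <- dummy_code(y, class_order)
    class_order <- attr(y, "class_order")
  } else if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  if (nrow(y) != nrow(x))
    stop("`x` and `y` disagree on the number of samples", call. = FALSE)
  ncomp <- stopifnot_scalar_count(ncomp, "ncomp")
  if (ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("`ncomp` cannot exceed min(n - 1, p)", call. = FALSE)
  if (scale) {
    xs <- autoscale(x)
    center <- attr(xs, "center"); scl <- attr(xs, "scale")
    attr(xs, "center") <- attr(xs, "scale") <- NULL
  } else {
    xs <- x
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    names(center) <- names(scl) <- colnames(x)
  }
  y_center <- colMeans(y)
  fit <- .cpp_nipals(xs, sweep(y, 2, y_center), ncomp, tol, maxiter)
  if (fit$ncomp < ncomp)
    warning("rank exhausted: fitted ", fit$ncomp, " of ", ncomp,
            " requested components", call. = FALSE)
  dimnames(fit$coefficients) <- list(colnames(xs), colnames(y))
  rownames(fit$weights) <- rownames(fit$loadings) <- colnames(xs)
  rownames(fit$y_loadings) <- colnames(y)
  rownames(fit$scores) <- rownames(x)
  structure(list(ncomp = fit$ncomp, ncomp_requested = ncomp,
                 weights = fit$weights, loadings = fit$loadings,
                 scores = fit$scores, y_loadings = fit$y_loadings,
                 coefficients = fit$coefficients,
                 x_center = center, x_scale = scl, y_center = y_center,
                 class_order = class_order,
                 variable_names = colnames(xs)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d latent variable(s), %d variables\n",
              x$ncomp, nrow(x$coefficients)))
  if (!is.null(x$class_order))
    cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' Predict responses or classes from a fitted PLS(-DA) model
#'
#' New samples are scaled with the model's stored training parameters,
#' multiplied by the regression coefficients, and the training response
#' means are added back. For models fitted on class labels,
#' `type = "class"` applies [classify()] to the continuous predictions.
#'
#' @param object A [pls_fit()] model.
#' @param newdata Samples x variables matrix over the model's variables
#'   (a single profile may be given as a vector).
#' @param type `"response"` (continuous per-class predictions) or
#'   `"class"`.
#' @param ... Unused.
#' @return Predictions matrix, or character vector of class names.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$x_center)) {
    if (!is.null(colnames(newdata)) &&
        all(object$variable_names %in% colnames(newdata)))
      newdata <- newdata[, object$variable_names, drop = FALSE]
    else
      stop("`newdata` does not match the model's variable set",
           call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, `/`)
  pred <- sweep(xs %*% object$coefficients, 2, object$y_center, `+`)
  if (type == "response") return(pred)
  if (is.null(object$class_order))
    stop("model was not fitted on class labels", call. = FALSE)
  classify(pred, object$class_order)
}

#' Assign classes from continuous PLS-DA predictions
#'
#' Argmax over the per-class predicted indicator values; exact ties go to
#' the earliest class in `class_order`.
#'
#' @param predictions Samples x classes matrix (or single vector) of
#'   continuous predictions.
#' @param class_order Class names, in tie-break order.
#' @return Character vector of class names.
#' @export
#' @examples
#' classify(c(0.5, 0.5), c("a", "b"))
classify <- function(predictions, class_order) {
  if (!is.matrix(predictions)) predictions <- matrix(predictions, nrow = 1L)
  stopifnot(ncol(predictions) == length(class_order))
  class_order[apply(predictions, 1, argmax_first)]
}
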