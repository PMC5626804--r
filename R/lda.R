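# Linear discriminant analysis on the selected CSP features.

#' Fit a two-class LDA classifier
#'
#' Classical Fisher LDA with equal priors (the recording protocol is
#' balanced): `w = S_pooled^-1 (mu_1 - mu_2)`, bias placing the boundary at
#' the pooled midpoint.  A ridge `1e-6 * trace/p * I` stabilizes the pooled
#' covariance.
#'
#' @param features numeric `N x p` matrix.
#' @param labels class labels in \{1, 2\}, both present.
#' @return object of class `lda_model`: `weights`, `bias`, `class_order`.
#' @export
fit_lda <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!all(c(1L, 2L) %in% labels)) stop("both classes must be present")
  X1 <- features[labels == 1L, , drop = FALSE]
  X2 <- features[labels == 2L, , drop = FALSE]
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  p <- ncol(features)
  cov0 <- function(X) if (nrow(X) > 1) stats::cov(X) * (nrow(X) - 1) else matrix(0, p, p)
  Sp <- (cov0(X1) + cov0(X2)) / max(1, nrow(features) - 2)
  Sp <- Sp + diag(1e-6 * max(sum(diag(Sp)), .Machine$double.eps) / p, p)
  w <- tryCatch(solve(Sp, mu1 - mu2),
                error = function(e) stop("pooled covariance is singular beyond the ridge"))
  if (!all(is.finite(w))) stop("non-finite LDA weights")
  structure(list(weights = as.numeric(w),
                 bias = -sum(w * (mu1 + mu2) / 2),
                 class_order = c(1L, 2L)),
            class = "lda_model")
}

#' Predict classes from an LDA model
#'
#' Decision score is `x'w + b`; class 1 iff the score is strictly positive
#' (an exact tie on the boundary goes to class 2, the rest class, for
#' determinism).
#'
#' @param object an `lda_model`.
#' @param newdata numeric vector of length p or `N x p` matrix.
#' @param ... unused.
#' @return list with `class` (integer vector) and `score` (numeric vector).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != length(object$weights)) {
    stop("feature dimension ", ncol(X), " does not match model (",
         length(object$weights), ")")
  }
  score <- as.numeric(X %*% object$weights + object$bias)
  list(class = ifelse(score > 0, 1L, 2L), score = score)
}
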