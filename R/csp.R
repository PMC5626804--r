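# Common spatial patterns: per-trial covariance machinery and the
# simultaneous-diagonalization filter fit.

#' Unit-trace covariance of a single trial
#'
#' Returns `X %*% t(X) / trace(X %*% t(X))`: the spatial covariance of one
#' band-passed trial, normalized to unit trace so that trials of different
#' amplitude contribute equally to class averages (classical CSP practice;
#' the log-variance features are invariant to this normalization).
#'
#' @param trial numeric `n x s` matrix (channels x samples), `s >= 2`.
#' @return symmetric positive-semidefinite `n x n` matrix with unit trace.
#' @export
trial_covariance <- function(trial) {
  trial <- as.matrix(trial)
  if (ncol(trial) < 2) stop("trial must have at least 2 samples")
  C <- tcrossprod(trial)
  tr <- sum(diag(C))
  if (tr <= 0 || !is.finite(tr)) {
    stop("trial has zero (or non-finite) power; unit-trace covariance undefined")
  }
  C / tr
}

#' Class-conditional average covariances for one band
#'
#' Arithmetic mean of unit-trace trial covariances over each class.
#'
#' @param be a `banded_epochs` object.
#' @param band band index.
#' @return an object of class `class_covariances`: `sigma_1`, `sigma_2`
#'   (symmetric PSD, unit trace) with trial counts `n_trials_1`, `n_trials_2`.
#' @export
class_covariances <- function(be, band) {
  stopifnot(inherits(be, "banded_epochs"))
  arr <- be$data[[band]]
  sig <- vector("list", 2)
  nt <- integer(2)
  for (j in 1:2) {
    idx <- which(be$labels == j)
    if (!length(idx)) stop("no trials of class ", j, " present")
    C <- 0
    for (i in idx) C <- C + trial_covariance(arr[, , i])
    sig[[j]] <- C / length(idx)
    nt[j] <- length(idx)
  }
  class_covariances_obj(sig[[1]], sig[[2]], nt[1], nt[2])
}

# plain constructor, shared with the adaptation module
class_covariances_obj <- function(sigma_1, sigma_2, n_trials_1 = NA_integer_,
                                  n_trials_2 = NA_integer_) {
  structure(list(sigma_1 = sigma_1, sigma_2 = sigma_2,
                 n_trials_1 = n_trials_1, n_trials_2 = n_trials_2),
            class = "class_covariances")
}

#' Fit CSP spatial filters for one band
#'
#' Solves the generalized eigenvalue problem `C1 w = (C1 + C2) w d` by
#' whitening `C1 + C2` and diagonalizing the whitened `C1`.  Rows of `W` are
#' spatial filters sorted by descending eigenvalue; under this convention
#' `W (C1 + C2) W' = I`, `W C1 W'` is diagonal with entries in [0, 1], and the
#' class-2 eigenvalues are their complements.  Only the first and last `m`
#' rows (largest class-1 / largest class-2 variance ratio) are retained for
#' feature extraction.
#'
#' @param cc a `class_covariances` object.
#' @param m number of filter pairs to retain; `2 * m <= n`.
#' @return an object of class `csp_model` with elements `W` (n x n, rows =
#'   filters), `eigvals` (descending), `retained` (row indices), `n`.
#' @export
fit_csp <- function(cc, m = 2L) {
  stopifnot(inherits(cc, "class_covariances"))
  C1 <- as_spd(cc$sigma_1, "sigma_1")
  n <- nrow(C1)
  if (2 * m > n) stop("2m = ", 2 * m, " exceeds channel count ", n)
  Ct <- (C1 + cc$sigma_2)
  Ct <- (Ct + t(Ct)) / 2
  if (kappa(Ct, exact = FALSE) > 1e12) {
    Ct <- Ct + diag(1e-10 * sum(diag(Ct)), n)
  }
  et <- eigen(Ct, symmetric = TRUE)
  if (min(et$values) <= 0) {
    stop("C1 + C2 is rank-deficient beyond regularization (min eigenvalue ",
         format(min(et$values), digits = 3), ")")
  }
  Wh <- (1 / sqrt(et$values)) * t(et$vectors)       # whitening: Wh Ct Wh' = I
  S1 <- Wh %*% C1 %*% t(Wh)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)                 # descending by default
  W <- t(e1$vectors) %*% Wh
  # sign convention: largest-magnitude entry of each filter made positive
  flip <- apply(W, 1, function(r) sign(r[which.max(abs(r))]))
  W <- W * flip
  structure(list(W = W, eigvals = pmin(pmax(e1$values, 0), 1),
                 retained = c(seq_len(m), seq(n - m + 1, n)), n = n, m = m),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> n = ", x$n, ", m = ", x$m, " pairs; top/bottom eigenvalues: ",
      paste(format(x$eigvals[x$retained], digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}
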