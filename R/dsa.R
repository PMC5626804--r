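# Data space adaptation: Gaussian KL divergence, the closed-form per-band
# alignment transform, the adaptation buffer, and deviation diagnostics.
#
# Model: a band-pass-filtered single trial is (approximately) a draw from a
# zero-mean multichannel Gaussian, so the class-conditional distribution of a
# session in one band is summarized by an average covariance matrix.  The
# alignment transform V maps evaluation trials as h = V' x so that the summed
# class-wise KL divergence to the calibration covariances is reduced.

#' Kullback-Leibler divergence between zero-mean Gaussians
#'
#' `KL[N(0, sigma) || N(0, sigma_ref)] =
#'   (tr(sigma_ref^-1 sigma) - ln(det sigma / det sigma_ref) - d) / 2`.
#' Positive-semidefinite inputs are nudged by `1e-10 * trace * I`; inputs not
#' positive definite after that raise an error.
#'
#' @param sigma,sigma_ref symmetric positive-definite matrices of equal size;
#'   `sigma_ref` is the reference (second) distribution.
#' @return scalar >= 0, zero iff the matrices are equal.
#' @export
gaussian_kl <- function(sigma, sigma_ref) {
  S <- as_spd(sigma, "sigma")
  R <- as_spd(sigma_ref, "sigma_ref")
  if (nrow(S) != nrow(R)) stop("dimension mismatch")
  d <- nrow(S)
  0.5 * (sum(diag(solve(R, S))) - (logdet_spd(S) - logdet_spd(R)) - d)
}

#' Closed-form per-band alignment transform
#'
#' Computes `V* = sqrt(2) * ((Sb1^-1 S1 + Sb2^-1 S2)^+)^(1/2)` where `S_j` are
#' the evaluation-session class covariances, `Sb_j` the calibration ones, `^+`
#' the Moore-Penrose pseudoinverse (singular values below `1e-10 * max`
#' dropped) and the square root is the principal matrix square root (computed
#' from the eigendecomposition; a relative imaginary residue above `1e-6` is
#' an error reporting the asymmetry).  When the evaluation covariances equal
#' the calibration ones per class, `V*` is exactly the identity.
#'
#' This closed form solves the stationarity condition of the summed-KL loss
#' [adaptation_loss()] exactly when all four matrices commute (always in one
#' dimension) and is a near-optimal approximation for the near-identity
#' session shifts it is designed for; see the methods vignette for its
#' behaviour on strongly non-commuting inputs.
#'
#' @param eval_cov,calib_cov `class_covariances` objects (or lists with
#'   `sigma_1`, `sigma_2`); calibration covariances must be positive definite.
#' @return the `n x n` transform matrix `V*`.
#' @export
solve_transform <- function(eval_cov, calib_cov) {
  S1 <- as_spd(eval_cov$sigma_1, "evaluation sigma_1")
  S2 <- as_spd(eval_cov$sigma_2, "evaluation sigma_2")
  B1 <- as_spd(calib_cov$sigma_1, "calibration sigma_1")
  B2 <- as_spd(calib_cov$sigma_2, "calibration sigma_2")
  M <- solve(B1, S1) + solve(B2, S2)
  sqrt(2) * sqrtm_principal(pinv(M))
}

#' Summed class-wise KL adaptation loss
#'
#' `L(V) = sum_j KL[N(0, V' S_j V) || N(0, Sb_j)]`: the objective the
#' alignment transform aims to minimize.
#'
#' @param V invertible `n x n` matrix.
#' @param eval_cov,calib_cov as in [solve_transform()].
#' @return scalar loss.
#' @export
adaptation_loss <- function(V, eval_cov, calib_cov) {
  if (abs(det(V)) < .Machine$double.eps) stop("V is singular")
  kl1 <- gaussian_kl(t(V) %*% eval_cov$sigma_1 %*% V, calib_cov$sigma_1)
  kl2 <- gaussian_kl(t(V) %*% eval_cov$sigma_2 %*% V, calib_cov$sigma_2)
  kl1 + kl2
}

#' Apply an alignment transform to one trial
#'
#' @param V `n x n` transform.
#' @param trial `n x s` matrix.
#' @return `t(V) %*% trial`.
#' @export
apply_transform <- function(V, trial) {
  if (nrow(V) != nrow(trial)) stop("channel-count mismatch between V and trial")
  crossprod(V, trial)
}

#' Frobenius deviation of a transform from the identity
#'
#' `||V - I||_F`; zero iff `V` is exactly the identity.  Used per band as a
#' diagnostic of how strongly two sessions differ in that band.
#'
#' @param V square matrix.
#' @return scalar >= 0.
#' @export
band_deviation <- function(V) {
  if (nrow(V) != ncol(V)) stop("V must be square")
  sqrt(sum((V - diag(nrow(V)))^2))
}

## Adaptation buffer ---------------------------------------------------------

#' Create an empty adaptation buffer
#'
#' A pair of FIFO queues (one per class) holding the most recent labeled
#' evaluation trials, capped at `capacity` trials per class.  The default
#' matches the standard protocol: a 20-trial buffer means the 10 most recent
#' trials of each class.
#'
#' @param capacity maximum trials retained per class.
#' @return object of class `adaptation_buffer`.
#' @export
adaptation_buffer <- function(capacity = 10L) {
  stopifnot(capacity >= 0)
  structure(list(class_1 = list(), class_2 = list(),
                 capacity = as.integer(capacity)),
            class = "adaptation_buffer")
}

#' Push a labeled trial into the buffer
#'
#' Appends the trial to its class queue; once a queue exceeds capacity the
#' oldest entry is evicted (first-in, first-out).
#'
#' @param buf an `adaptation_buffer`.
#' @param trial arbitrary per-trial payload (the evaluation loop stores the
#'   per-band unit-trace trial covariances).
#' @param label 1 or 2.
#' @return the updated buffer.
#' @export
update_buffer <- function(buf, trial, label) {
  stopifnot(inherits(buf, "adaptation_buffer"), label %in% c(1L, 2L))
  key <- if (label == 1L) "class_1" else "class_2"
  q <- c(buf[[key]], list(trial))
  if (length(q) > buf$capacity) q <- q[-seq_len(length(q) - buf$capacity)]
  buf[[key]] <- q
  buf
}

#' @export
print.adaptation_buffer <- function(x, ...) {
  cat("<adaptation_buffer> ", length(x$class_1), "/", length(x$class_2),
      " trials (capacity ", x$capacity, " per class)\n", sep = "")
  invisible(x)
}

# Ledoit-Wolf-style shrinkage of an averaged trial covariance, with intensity
# estimated from the dispersion of the K trial covariances around their mean.
# `covs` is the list of unit-trace trial covariances entering the average.
#
# Target choice matters for adaptation.  The default ("lw") shrinks the
# small-buffer evaluation covariance toward the *calibration* covariance of
# the same class -- the natural no-shift prior: sampling noise (b2, the
# estimated variance of the mean covariance) is damped while a genuine
# between-session difference (d2 large) passes through, so the resulting
# transform degrades to the identity exactly when there is nothing to
# correct.  "trials" reproduces the fixed-intensity identity-target variant
# gamma = max(0, 1 - K/n).
shrink_covariance <- function(sigma, covs, method = c("lw", "trials", "none"),
                              target = NULL) {
  method <- match.arg(method)
  n <- nrow(sigma)
  K <- length(covs)
  if (method == "none" || K == 0) return(sigma)
  if (method == "trials" || is.null(target)) {
    target <- diag(sum(diag(sigma)) / n, n)
  }
  if (method == "trials" || K < 2) {
    # with fewer than two trials the sampling variance of the mean covariance
    # is inestimable; fall back to the deterministic trial-count intensity
    gamma <- max(0, 1 - K / n)
  } else {
    d2 <- sum((sigma - target)^2)
    if (d2 <= .Machine$double.eps) return(target)
    b2 <- sum(vapply(covs, function(C) sum((C - sigma)^2), 0)) / K^2
    gamma <- min(1, b2 / d2)
  }
  (1 - gamma) * sigma + gamma * target
}

#' Compute per-band alignment transforms from the current buffer
#'
#' For every frequency band that has features selected in the calibration
#' model (all bands if `adapt_all_bands` is configured), the evaluation class
#' covariances are estimated by averaging the buffered unit-trace trial
#' covariances per class (shrunk toward scaled identity when the buffer is
#' small; see `dsa_shrinkage` in [pipeline_config()]) and fed to
#' [solve_transform()] against the stored calibration covariances.  Bands
#' without selected features keep the exact identity.  Degenerate buffers --
#' fewer than one trial in either class, or inputs on which the closed form
#' fails -- degrade to the identity rather than erroring.
#'
#' @param buf an `adaptation_buffer` whose entries carry `$cov`, the list of
#'   per-band unit-trace trial covariances (as stored by
#'   [evaluate_adaptive()]).
#' @param model a `calibration_model`.
#' @return object of class `dsa_transform`: `V` (list of per-band matrices),
#'   `bands_adapted`, `source`.
#' @export
compute_band_transforms <- function(buf, model) {
  stopifnot(inherits(buf, "adaptation_buffer"), inherits(model, "calibration_model"))
  nb <- nrow(model$cfg$bands)
  n <- length(model$channels)
  V <- rep(list(diag(n)), nb)
  sel_bands <- if (model$cfg$dsa$adapt_all_bands) seq_len(nb) else
    sort(unique(model$selection_bands))
  n1 <- length(buf$class_1)
  n2 <- length(buf$class_2)
  adapted <- integer(0)
  if (n1 >= 1 && n2 >= 1) {
    for (b in sel_bands) {
      covs1 <- lapply(buf$class_1, function(e) e$cov[[b]])
      covs2 <- lapply(buf$class_2, function(e) e$cov[[b]])
      S1 <- shrink_covariance(Reduce(`+`, covs1) / n1, covs1, model$cfg$dsa$shrinkage,
                              target = model$calib_cov[[b]]$sigma_1)
      S2 <- shrink_covariance(Reduce(`+`, covs2) / n2, covs2, model$cfg$dsa$shrinkage,
                              target = model$calib_cov[[b]]$sigma_2)
      Vb <- tryCatch(
        solve_transform(class_covariances_obj(S1, S2, n1, n2), model$calib_cov[[b]]),
        error = function(e) NULL
      )
      if (!is.null(Vb)) {
        V[[b]] <- Vb
        adapted <- c(adapted, b)
      }
    }
  }
  structure(list(V = V, bands_adapted = adapted,
                 source = sprintf("buffer %d+%d trials", n1, n2)),
            class = "dsa_transform")
}

#' @export
print.dsa_transform <- function(x, ...) {
  dev <- vapply(x$V, band_deviation, 0)
  cat("<dsa_transform> ", x$source, "; adapted bands: ",
      if (length(x$bands_adapted)) paste(x$bands_adapted, collapse = ", ") else "none",
      "\n  ||V - I||_F per band: ", paste(format(dev, digits = 3), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
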