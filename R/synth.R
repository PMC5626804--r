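# Synthetic two-class, two-session EEG generator.
#
# A session is built from band-limited Gaussian sources passed through a
# subject-specific linear forward model (mixing matrix), plus spatially
# correlated 1/f background noise.  The motor class (label 1) attenuates the
# variance of designated mu/low-beta sources over the motor channels --
# an event-related-desynchronization-like contrast.  The subject seed fixes
# the forward model; the session seed drives trial noise, so two sessions of
# one "subject" share spatial structure but contain fresh trials.  A
# between-session perturbation is applied separately by
# [apply_session_shift()].

#' Default 27-channel montage
#'
#' A plausible 27-name motor-centric montage; the six motor-cortex channels
#' (`C3, CP3, CF3, C4, CP4, CF4`) carry the planted class contrast.
#' @return character vector of 27 channel names.
#' @export
default_montage_27 <- function() {
  c("F3", "Fz", "F4", "FC3", "FCz", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CF3", "CF4", "CP3", "CPz", "CP4",
    "P3", "Pz", "P4", "T7", "T8", "O1", "Oz", "O2", "POz")
}

#' The six motor-cortex channels
#' @return character vector.
#' @export
motor_channels <- function() c("C3", "CP3", "CF3", "C4", "CP4", "CF4")

#' Specification of a synthetic recording
#'
#' @param n_channels number of EEG channels (default 27).
#' @param fs sampling rate, Hz (default 250).
#' @param n_trials_per_class trials per class per session (default 40).
#' @param window_length_s analysis-window length in seconds (default 2);
#'   epochs carry window `c(0.5, 0.5 + window_length_s)` relative to cue.
#' @param contrast_bands 2-column matrix of Hz band edges carrying the class
#'   contrast (default mu 8-12 and low beta 12-16 Hz).
#' @param effect_size class variance ratio (rest / motor) on the contrast
#'   sources; 1 means no contrast at all (a null session).  Default 2.5,
#'   i.e. a 60 percent band-power suppression -- a strong but physiologically
#'   ordinary motor-rhythm desynchronization.
#' @param snr_db signal-to-noise ratio, in dB, of contrast-source power to
#'   background power within the contrast bands on the motor channels
#'   (default 0).
#' @param n_background_sources broadband common sources with no class
#'   contrast (default 8).
#' @param shift_strength between-session perturbation strength `lambda`
#'   recorded for manifests; the shift itself is applied by
#'   [apply_session_shift()].
#' @param seed subject seed fixing the forward model.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 27L, fs = 250, n_trials_per_class = 40L,
                       window_length_s = 2, contrast_bands = rbind(c(8, 12), c(12, 16)),
                       effect_size = 2.5, snr_db = 0, n_background_sources = 8L,
                       shift_strength = 0, seed = 1L) {
  stopifnot(effect_size >= 1, shift_strength >= 0, n_channels >= 8,
            fs > 2 * max(contrast_bands))
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 window_length_s = window_length_s,
                 contrast_bands = contrast_bands,
                 effect_size = effect_size, snr_db = snr_db,
                 n_background_sources = as.integer(n_background_sources),
                 shift_strength = shift_strength, seed = as.integer(seed)),
            class = "synth_spec")
}

# band-limited unit-variance Gaussian series: white noise shaped in the
# frequency domain.  Returns an s x k matrix.
band_limited_noise <- function(s, k, fs, band, shape = c("flat", "one_over_f")) {
  shape <- match.arg(shape)
  f <- seq(0, fs - fs / s, length.out = s)
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  mask <- as.numeric(f >= band[1] & f <= band[2])
  mask[1] <- 0                               # no DC: zero-mean by construction
  if (shape == "one_over_f") mask <- mask / sqrt(pmax(f, 1))
  W <- matrix(stats::rnorm(s * k), s, k) + 1i * matrix(stats::rnorm(s * k), s, k)
  X <- Re(stats::mvfft(W * mask, inverse = TRUE)) / s
  sdv <- sqrt(colMeans(X^2))
  sdv[sdv == 0] <- 1
  sweep(X, 2, sdv, "/")
}

# subject-level forward model, drawn from the subject seed only
synth_forward_model <- function(spec) {
  n <- spec$n_channels
  montage <- if (n == 27L) default_montage_27() else
    c(motor_channels(), sprintf("ch%02d", seq_len(n - 6L)))
  motor_idx <- match(motor_channels(), montage)
  left <- motor_idx[1:3]                      # C3, CP3, CF3
  right <- motor_idx[4:6]                     # C4, CP4, CF4
  withr::with_seed(spec$seed, {
    n_cs <- 2L * nrow(spec$contrast_bands)    # one left + one right per band
    A_c <- matrix(stats::rnorm(n * n_cs, sd = 0.05), n, n_cs)
    for (k in seq_len(n_cs)) {
      side <- if (k %% 2 == 1) left else right
      A_c[side, k] <- A_c[side, k] + c(1, 0.7, 0.5)
    }
    A_b <- matrix(stats::rnorm(n * spec$n_background_sources), n,
                  spec$n_background_sources) / sqrt(n)
    B_noise <- matrix(stats::rnorm(n * n), n, n) / sqrt(n)
    list(montage = montage, motor_idx = motor_idx, A_c = A_c, A_b = A_b,
         B_noise = B_noise,
         contrast_band_of_source = rep(seq_len(nrow(spec$contrast_bands)), each = 2L))
  })
}

#' Generate one synthetic session
#'
#' Draws balanced labeled trials from the spec's generative model: contrast
#' sources (band-limited, class-1 variance attenuated by `effect_size`),
#' broadband common sources, and spatially correlated 1/f background noise
#' scaled so that motor-channel contrast-band power matches the configured
#' SNR.  Deterministic given `(spec$seed, session_seed)`; trials arrive in a
#' seeded random class order.
#'
#' @param spec a `synth_spec`.
#' @param session_seed seed for the trial-level randomness; defaults to
#'   `spec$seed + 1000` so a bare spec still yields a reproducible session.
#' @param return_sources attach the latent contrast-source signals as
#'   attribute `"sources"` (array `n_contrast_sources x s x N`) for
#'   generator-level diagnostics.
#' @return an `epoch_set` with `2 * n_trials_per_class` trials.
#' @export
generate_session <- function(spec, session_seed = NULL, return_sources = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(session_seed)) session_seed <- spec$seed + 1000L
  fm <- synth_forward_model(spec)
  n <- spec$n_channels
  s <- round(spec$window_length_s * spec$fs)
  N <- 2L * spec$n_trials_per_class
  n_cs <- ncol(fm$A_c)
  n_bg <- ncol(fm$A_b)
  # noise amplitude from the forward model, not from realized draws: sessions
  # of one subject then share their SNR exactly.  Sources have unit variance,
  # contrast sources are fully inside the contrast bands, and the 1/f noise
  # has an analytically known in-band power fraction.
  cb <- range(spec$contrast_bands)
  p_sig <- mean(rowSums(fm$A_c^2)[fm$motor_idx])
  frac <- noise_band_fraction(s, spec$fs, cb)
  p_noise <- mean(rowSums(fm$B_noise^2)[fm$motor_idx]) * frac
  alpha <- sqrt(p_sig / p_noise) * 10^(-spec$snr_db / 20)
  withr::with_seed(session_seed, {
    labels <- sample(rep(1:2, spec$n_trials_per_class))
    bg_bands <- cbind(seq(4, 36, length.out = n_bg),
                      seq(8, 40, length.out = n_bg))
    # contrast sources: s x N per source, attenuated on motor-task trials
    S_c <- array(0, c(s, N, n_cs))
    att <- ifelse(labels == 1L, 1 / sqrt(spec$effect_size), 1)
    for (k in seq_len(n_cs)) {
      band <- spec$contrast_bands[fm$contrast_band_of_source[k], ]
      S_c[, , k] <- band_limited_noise(s, N, spec$fs, band) *
        rep(att, each = s)
    }
    S_b <- array(0, c(s, N, n_bg))
    for (k in seq_len(n_bg)) {
      S_b[, , k] <- band_limited_noise(s, N, spec$fs, bg_bands[k, ])
    }
    E <- array(band_limited_noise(s, N * n, spec$fs, c(1, spec$fs / 2 - 1),
                                  shape = "one_over_f"), c(s, N, n))
    mix <- function(A, S) {
      # A: n x k loadings; S: s x N x k sources -> n x (s N) signal
      k <- ncol(A)
      A %*% t(matrix(aperm(S, c(1, 2, 3)), s * N, k))
    }
    X <- mix(fm$A_c, S_c) + mix(fm$A_b, S_b) + alpha * mix(fm$B_noise, E)
    dim(X) <- c(n, s, N)
    es <- epoch_set(aperm(X, c(3, 1, 2)), labels = labels, fs = spec$fs,
                    channels = fm$montage,
                    window = c(0.5, 0.5 + spec$window_length_s))
    if (return_sources) attr(es, "sources") <- aperm(S_c, c(3, 1, 2))
    es
  })
}

# fraction of a unit-variance 1/f source's power falling inside `band`,
# computed from the same spectral mask used to synthesize it
noise_band_fraction <- function(s, fs, band) {
  f <- seq(0, fs - fs / s, length.out = s)
  f <- pmin(f, fs - f)
  full <- f >= 1 & f <= fs / 2 - 1
  m2 <- ifelse(full, 1 / pmax(f, 1), 0)
  sum(m2[f >= band[1] & f <= band[2] & full]) / sum(m2)
}

#' Apply a between-session linear perturbation
#'
#' Models inter-session variation (electrode repositioning, impedance and
#' cognitive-state changes) as a global linear remixing
#' `A = diag(g) (I + lambda E)` with `E` a seeded random matrix of unit
#' Frobenius norm and per-channel gains `g = 1 + N(0, (0.25 lambda)^2)`, so
#' the nominal shift `lambda = 0.4` carries a 10 percent gain spread --
#' ordinary across-day electrode variation.
#' `lambda = 0` returns the data unchanged (exactly).  Class covariances of
#' the shifted session equal `A Sigma A'` up to sampling error.
#'
#' @param es an `epoch_set`.
#' @param lambda shift strength >= 0.
#' @param seed RNG seed for `E` and the gains.
#' @return the shifted `epoch_set`, with the applied matrix as attribute
#'   `"shift_matrix"`; an (essentially) singular `A` is an error.
#' @export
apply_session_shift <- function(es, lambda, seed = 1L) {
  validate_epoch_set(es)
  stopifnot(lambda >= 0)
  if (lambda == 0) return(es)
  n <- length(es$channels)
  A <- withr::with_seed(seed, {
    E <- matrix(stats::rnorm(n * n), n, n)
    E <- E / sqrt(sum(E^2))
    g <- 1 + lambda * stats::rnorm(n, sd = 0.25)
    diag(g) %*% (diag(n) + lambda * E)
  })
  if (rcond(A) < 1e-10) stop("shift matrix is singular; lambda = ", lambda, " is too large")
  d <- dim(es$data)
  X <- aperm(es$data, c(2, 3, 1))              # n x s x N
  dim(X) <- c(n, d[3] * d[1])
  X <- A %*% X
  dim(X) <- c(n, d[3], d[1])
  out <- epoch_set(aperm(X, c(3, 1, 2)), labels = es$labels, fs = es$fs,
                   channels = es$channels, window = es$window)
  attr(out, "shift_matrix") <- A
  out
}
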