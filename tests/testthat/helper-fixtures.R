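# shared test helpers: random SPD matrices, small synthetic sessions

rspd <- function(n, jitter = 0.1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(jitter, n)
}

# small, fast session: 12 channels, 10 trials/class unless overridden
small_spec <- function(seed, n_trials_per_class = 10L, ...) {
  synth_spec(n_channels = 12L, n_trials_per_class = n_trials_per_class,
             seed = seed, ...)
}

# strongly separable world for planted-effect tests
strong_spec <- function(seed, ...) {
  small_spec(seed, effect_size = 4, snr_db = 6, ...)
}

# wrap a plain array (n x s x N) + labels as a single-band banded_epochs
as_banded <- function(arr, labels, fs = 250) {
  structure(list(data = list(arr), bands = filter_bank_bands(1L),
                 labels = as.integer(labels), fs = fs,
                 channels = sprintf("ch%02d", seq_len(dim(arr)[1])),
                 window = c(0.5, 0.5 + dim(arr)[2] / fs)),
            class = "banded_epochs")
}

# hand-made csp_model with given filter matrix (rows = filters)
fake_csp <- function(W, m = 2L) {
  n <- nrow(W)
  structure(list(W = W, eigvals = seq(1, 0, length.out = n),
                 retained = c(seq_len(m), seq(n - m + 1, n)), n = n, m = m),
            class = "csp_model")
}

# Gaussian trials with a fixed spatial covariance: n x s x N array
gaussian_trials <- function(Sigma, s, N) {
  n <- nrow(Sigma)
  R <- chol(Sigma)
  arr <- array(0, c(n, s, N))
  for (i in seq_len(N)) arr[, , i] <- t(R) %*% matrix(rnorm(n * s), n, s)
  arr
}
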