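# Chebyshev Type II band-pass filter bank.
#
# The IIR design follows the classical analog-prototype route: Chebyshev II
# low-pass prototype (zeros/poles/gain) -> low-pass-to-band-pass transform ->
# bilinear transform with prewarped edges -> second-order sections.  Filtering
# runs per biquad as an FIR step plus a C-level linear recurrence
# (stats::filter, method = "recursive"), columnwise over a whole session at
# once, forward-backward for zero phase, with odd-reflection padding.

# analog low-pass prototype; cutoff convention: stopband edge at w = 1
cheb2ap <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  m <- if (n %% 2) c(seq(-n + 1, -2, 2), seq(2, n - 1, 2)) else seq(-n + 1, n - 1, 2)
  z <- -Conj(1i / sin(m * pi / (2 * n)))
  p <- -exp(1i * pi * seq(-n + 1, n - 1, 2) / (2 * n))
  p <- 1 / (sinh(mu) * Re(p) + 1i * cosh(mu) * Im(p))
  list(z = z, p = p, k = Re(prod(-p) / prod(-z)))
}

lp2bp_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zl <- zpk$z * bw / 2
  pl <- zpk$p * bw / 2
  zb <- c(zl + sqrt(as.complex(zl^2 - wo^2)), zl - sqrt(as.complex(zl^2 - wo^2)))
  pb <- c(pl + sqrt(as.complex(pl^2 - wo^2)), pl - sqrt(as.complex(pl^2 - wo^2)))
  list(z = c(zb, rep(0 + 0i, degree)), p = pb, k = zpk$k * bw^degree)
}

bilinear_zpk <- function(zpk, fs) {
  degree <- length(zpk$p) - length(zpk$z)
  fs2 <- 2 * fs
  list(z = c((fs2 + zpk$z) / (fs2 - zpk$z), rep(-1 + 0i, degree)),
       p = (fs2 + zpk$p) / (fs2 - zpk$p),
       k = zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p)))
}

# group conjugate pairs; pair pole pairs (closest to unit circle first) with
# the nearest zero pair; overall gain folded into the last section
zpk_to_sos <- function(zpk) {
  split_pairs <- function(v) {
    up <- v[Im(v) > 1e-9]
    re <- sort(Re(v[abs(Im(v)) <= 1e-9]))
    pairs <- lapply(up, function(x) c(x, Conj(x)))
    while (length(re) >= 2) {
      pairs[[length(pairs) + 1]] <- c(re[1] + 0i, re[2] + 0i)
      re <- re[-(1:2)]
    }
    pairs
  }
  zp <- split_pairs(zpk$z)
  pp <- split_pairs(zpk$p)
  if (length(zp) != length(pp)) stop("unbalanced pole/zero pairs in SOS conversion")
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), 0))]
  used <- rep(FALSE, length(zp))
  sos <- matrix(0, length(pp), 6)
  for (i in seq_along(pp)) {
    d <- vapply(seq_along(zp),
                function(j) if (used[j]) Inf else Mod(zp[[j]][1] - pp[[i]][1]), 0)
    j <- which.min(d)
    used[j] <- TRUE
    sos[i, ] <- Re(c(1, -(zp[[j]][1] + zp[[j]][2]), zp[[j]][1] * zp[[j]][2],
                     1, -(pp[[i]][1] + pp[[i]][2]), pp[[i]][1] * pp[[i]][2]))
  }
  sos[nrow(sos), 1:3] <- sos[nrow(sos), 1:3] * zpk$k
  sos
}

.sos_cache <- new.env(parent = emptyenv())

#' Design a Chebyshev Type II band-pass filter as second-order sections
#'
#' @param low_hz,high_hz passband edges in Hz.
#' @param fs sampling rate in Hz; `high_hz` must be below Nyquist.
#' @param order prototype order (the band-pass filter has `2 * order` poles).
#' @param stopband_db stopband attenuation in dB.
#' @return a `k x 6` matrix of biquad coefficients `(b0, b1, b2, a0, a1, a2)`.
#' @export
cheby2_bandpass <- function(low_hz, high_hz, fs, order = 6L, stopband_db = 40) {
  if (high_hz >= fs / 2) {
    stop("band edge ", high_hz, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  key <- paste(low_hz, high_hz, fs, order, stopband_db, sep = "|")
  if (!is.null(.sos_cache[[key]])) return(.sos_cache[[key]])
  warped <- 2 * fs * tan(pi * c(low_hz, high_hz) / fs)
  zpk <- bilinear_zpk(lp2bp_zpk(cheb2ap(order, stopband_db),
                                wo = sqrt(prod(warped)), bw = diff(warped)), fs)
  .sos_cache[[key]] <- zpk_to_sos(zpk)
  .sos_cache[[key]]
}

# single-pass SOS filtering of every column of x (time along rows);
# the inner recurrence lives in compiled code (src/sosfilt.cpp)
sosfilt_mat <- function(sos, x) {
  .sosfilt_cpp(sos, x)
}

#' Zero-phase (forward-backward) SOS filtering with odd-reflection padding
#'
#' @param sos biquad matrix from [cheby2_bandpass()].
#' @param x numeric matrix, time along rows, one series per column.
#' @param padlen samples of odd-reflection padding at each end (default three
#'   transfer-function lengths, `3 * (4 * nrow(sos) + 1)`, capped at
#'   `nrow(x) - 1`).
#' @param zero_phase if `FALSE`, a single causal pass is used.
#' @return filtered matrix, same shape as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL, zero_phase = TRUE) {
  x <- as.matrix(x)
  nt <- nrow(x)
  if (is.null(padlen)) padlen <- min(nt - 1, 3 * (4 * nrow(sos) + 1))
  if (padlen > 0) {
    top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[seq(padlen + 1, 2), , drop = FALSE]
    bot <- 2 * matrix(x[nt, ], padlen, ncol(x), byrow = TRUE) -
      x[seq(nt - 1, nt - padlen), , drop = FALSE]
    x <- rbind(top, x, bot)
  }
  y <- sosfilt_mat(sos, x)
  if (zero_phase) {
    y <- y[nrow(y):1, , drop = FALSE]
    y <- sosfilt_mat(sos, y)
    y <- y[nrow(y):1, , drop = FALSE]
  }
  if (padlen > 0) y <- y[seq(padlen + 1, padlen + nt), , drop = FALSE]
  y
}

#' Decompose an epoch set into band-pass-filtered copies
#'
#' Applies the configured filter bank (by default nine 4-Hz Chebyshev Type II
#' band-passes, zero-phase) to every trial.  Filtering is per epoch; trial
#' count and labels are unchanged and each band's output is zero-mean per
#' channel up to filter leakage.
#'
#' @param es a validated `epoch_set`.
#' @param cfg a [pipeline_config()].
#' @return an object of class `banded_epochs`: a list with `data` (one
#'   `n x s x N` array per band), `bands`, `labels`, `fs`, `channels`.
#' @export
apply_filter_bank <- function(es, cfg = pipeline_config()) {
  validate_epoch_set(es)
  if (max(cfg$bands$high_hz) >= es$fs / 2) {
    stop("filter bank extends to ", max(cfg$bands$high_hz),
         " Hz but Nyquist is ", es$fs / 2, " Hz")
  }
  d <- dim(es$data)
  X <- aperm(es$data, c(3, 2, 1))        # s x n x N
  dim(X) <- c(d[3], d[2] * d[1])
  out <- vector("list", nrow(cfg$bands))
  for (b in seq_len(nrow(cfg$bands))) {
    sos <- cheby2_bandpass(cfg$bands$low_hz[b], cfg$bands$high_hz[b], es$fs,
                           cfg$filter$order, cfg$filter$stopband_db)
    Y <- sos_filtfilt(sos, X, zero_phase = cfg$filter$zero_phase)
    dim(Y) <- c(d[3], d[2], d[1])
    out[[b]] <- aperm(Y, c(2, 1, 3))     # n x s x N
  }
  structure(list(data = out, bands = cfg$bands, labels = es$labels,
                 fs = es$fs, channels = es$channels, window = es$window),
            class = "banded_epochs")
}

#' @export
print.banded_epochs <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat("<banded_epochs> ", length(x$data), " bands x ", d[3], " trials x ",
      d[1], " channels x ", d[2], " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Cut a sub-window out of an epoch set
#'
#' @param es an `epoch_set`.
#' @param start_s,end_s window edges in seconds relative to cue onset; must
#'   lie inside the recorded epoch extent.
#' @return an `epoch_set` with `round((end_s - start_s) * fs)` samples per
#'   trial; labels and channels preserved.
#' @export
extract_window <- function(es, start_s, end_s) {
  validate_epoch_set(es)
  if (start_s < es$window[1] - 1e-9 || end_s > es$window[2] + 1e-9 || end_s <= start_s) {
    stop("requested window [", start_s, ", ", end_s, "] s is outside the recorded epoch [",
         es$window[1], ", ", es$window[2], "] s")
  }
  offset <- round((start_s - es$window[1]) * es$fs)
  s_new <- round((end_s - start_s) * es$fs)
  epoch_set(es$data[, , offset + seq_len(s_new), drop = FALSE],
            labels = es$labels, fs = es$fs, channels = es$channels,
            window = c(start_s, end_s))
}
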