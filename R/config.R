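#' The standard 9-band filter bank
#'
#' Nine contiguous 4-Hz bands, 4-8 Hz up to 36-40 Hz, covering theta through
#' low gamma -- the standard FBCSP filter bank.
#'
#' @param n_bands number of bands (default 9).
#' @param width bandwidth in Hz of each band (default 4).
#' @param start lower edge of the first band in Hz (default 4).
#' @return a data.frame with columns `low_hz`, `high_hz`, `index`.
#' @export
filter_bank_bands <- function(n_bands = 9L, width = 4, start = 4) {
  low <- start + width * (seq_len(n_bands) - 1)
  data.frame(low_hz = low, high_hz = low + width, index = seq_len(n_bands))
}

#' Pipeline configuration
#'
#' Collects every tunable of the decoding pipeline.  Defaults follow standard
#' FBCSP practice for motor-imagery BCIs: nine 4-Hz bands, `m = 2` CSP filter
#' pairs per band, 4 best individual features (plus CSP-pair completion), a
#' 0.5-2.5 s post-cue analysis window, and a 20-trial adaptation buffer
#' (10 most recent labeled trials per class).
#'
#' @param bands filter-bank definition, see [filter_bank_bands()].
#' @param m number of CSP filter pairs retained per band (`2m` rows).
#' @param k_select number of best individual features selected by mutual
#'   information before pair completion.
#' @param window analysis window `c(start_s, end_s)` relative to cue onset.
#' @param buffer_size total adaptation-buffer size in trials (even, split
#'   half/half across the two classes); 0 disables adaptation.
#' @param filter_order Chebyshev Type II order per band-pass filter.
#' @param stopband_db stopband attenuation of each band-pass filter, dB.
#' @param zero_phase logical; apply the filter forward-backward.
#' @param mi_estimator mutual-information estimator: `"parzen"`
#'   (Gaussian-kernel Parzen window, the classical MIBIF choice) or
#'   `"histogram"`.
#' @param dsa_label_source `"true"` (offline protocol: adaptation consumes the
#'   true labels of past evaluation trials) or `"predicted"`.
#' @param dsa_shrinkage small-buffer covariance shrinkage toward scaled
#'   identity: `"lw"` (Ledoit-Wolf-style, data-driven; default), `"trials"`
#'   (fixed intensity `max(0, 1 - n_trials/n_channels)`), or `"none"`.
#' @param adapt_all_bands compute alignment transforms for all bands instead
#'   of only the bands with selected features.
#' @param chance_band accuracy interval (percent) regarded as chance level in
#'   cross-validation screening.
#' @param seed RNG seed used by seeded pipeline operations.
#' @return an object of class `fbdsa_config`.
#' @export
pipeline_config <- function(bands = filter_bank_bands(),
                            m = 2L,
                            k_select = 4L,
                            window = c(0.5, 2.5),
                            buffer_size = 20L,
                            filter_order = 6L,
                            stopband_db = 40,
                            zero_phase = TRUE,
                            mi_estimator = c("parzen", "histogram"),
                            dsa_label_source = c("true", "predicted"),
                            dsa_shrinkage = c("lw", "trials", "none"),
                            adapt_all_bands = FALSE,
                            chance_band = c(43, 57),
                            seed = 1L) {
  stopifnot(m >= 1, k_select >= 1, buffer_size >= 0, buffer_size %% 2 == 0,
            length(window) == 2, window[2] > window[1],
            all(bands$low_hz > 0), all(bands$high_hz > bands$low_hz))
  structure(
    list(bands = bands, m = as.integer(m), k_select = as.integer(k_select),
         window = as.numeric(window), buffer_size = as.integer(buffer_size),
         filter = list(order = as.integer(filter_order),
                       stopband_db = stopband_db,
                       zero_phase = isTRUE(zero_phase)),
         features = list(mi_estimator = match.arg(mi_estimator)),
         dsa = list(label_source = match.arg(dsa_label_source),
                    shrinkage = match.arg(dsa_shrinkage),
                    adapt_all_bands = isTRUE(adapt_all_bands)),
         chance_band = as.numeric(chance_band),
         seed = as.integer(seed)),
    class = "fbdsa_config"
  )
}

#' @export
print.fbdsa_config <- function(x, ...) {
  cat("<fbdsa_config> ", nrow(x$bands), " bands ",
      x$bands$low_hz[1], "-", max(x$bands$high_hz), " Hz | m = ", x$m,
      " | k_select = ", x$k_select, " | window ", x$window[1], "-", x$window[2],
      " s | buffer ", x$buffer_size, " trials\n", sep = "")
  cat("  filter: Chebyshev II order ", x$filter$order, ", ",
      x$filter$stopband_db, " dB stopband",
      if (x$filter$zero_phase) ", zero-phase" else "", "\n", sep = "")
  invisible(x)
}
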