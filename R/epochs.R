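#' Labeled single-trial multichannel EEG epochs
#'
#' An `epoch_set` is the package's canonical container for epoched EEG: an
#' `N x n x s` array of `N` trials, `n` channels and `s` samples per trial
#' (microvolts), a class label per trial (`1` = motor task, i.e. motor imagery
#' or passive movement; `2` = background rest), the sampling rate, the ordered
#' channel names, and the analysis window in seconds relative to cue onset.
#'
#' @param data numeric array of dimension `c(N, n, s)`.
#' @param labels integer vector of length `N`; every entry must be 1 or 2.
#' @param fs sampling rate in Hz.
#' @param channels character vector of `n` channel names.
#' @param window numeric length-2 vector `c(start_s, end_s)` of the epoch
#'   extent relative to cue onset; `s` must equal
#'   `round((end_s - start_s) * fs)`.
#' @return a validated object of class `epoch_set`.
#' @examples
#' es <- epoch_set(array(rnorm(4 * 2 * 10), c(4, 2, 10)),
#'                 labels = c(1, 2, 1, 2), fs = 5,
#'                 channels = c("C3", "C4"), window = c(0, 2))
#' es
#' @export
epoch_set <- function(data, labels, fs, channels, window) {
  es <- structure(
    list(data = data, labels = as.integer(labels), fs = fs,
         channels = as.character(channels), window = as.numeric(window)),
    class = "epoch_set"
  )
  validate_epoch_set(es)
}

#' Validate an epoch_set
#'
#' Checks every container invariant: label domain, dimension consistency with
#' `channels`/`fs`/`window`, and finiteness of the data.  Validation is
#' idempotent; all pipeline stages accept only validated epoch sets.
#'
#' @param es an `epoch_set`.
#' @return `es`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_epoch_set <- function(es) {
  if (!inherits(es, "epoch_set")) stop("not an epoch_set")
  d <- dim(es$data)
  if (length(d) != 3) stop("data must be a 3-d array [trials x channels x samples]")
  if (d[1] != length(es$labels)) {
    stop("number of trials (", d[1], ") != number of labels (", length(es$labels), ")")
  }
  if (!all(es$labels %in% c(1L, 2L))) {
    stop("labels must all be in {1, 2}; found: ",
         paste(setdiff(unique(es$labels), c(1L, 2L)), collapse = ", "))
  }
  if (d[2] != length(es$channels)) {
    stop("number of channels (", d[2], ") != number of channel names (",
         length(es$channels), ")")
  }
  if (length(es$window) != 2 || es$window[2] <= es$window[1]) {
    stop("window must be c(start_s, end_s) with end > start")
  }
  s_expect <- round(diff(es$window) * es$fs)
  if (d[3] != s_expect) {
    stop("sample count (", d[3], ") != round((end - start) * fs) = ", s_expect)
  }
  if (!all(is.finite(es$data))) stop("data contains non-finite values")
  invisible(es)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3], " samples",
      " @ ", x$fs, " Hz\n", sep = "")
  cat("  window: [", x$window[1], ", ", x$window[2], "] s; labels: ",
      sum(x$labels == 1L), " motor / ", sum(x$labels == 2L), " rest\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fixture serialization.
#
# Canonical on-disk container: a self-describing plain-text file.
#   line 1:  "#FBDSA-EPOCHS 1"
#   line 2:  "#HEADER " followed by a JSON object with fields
#            fs, window, channels, labels, dim = [N, n, s]
#   then N*n data rows (trial-major, channel fastest), each holding the s
#   samples of one channel of one trial, tab-separated, printed with "%.17g"
#   so that every IEEE double round-trips bit-exactly.
# ---------------------------------------------------------------------------

FIXTURE_MAGIC <- "#FBDSA-EPOCHS 1"

#' Write an epoch_set to the canonical fixture container
#'
#' The file is plain text, self-describing, byte-deterministic given identical
#' inputs, and round-trips every array element exactly (17 significant digits
#' per sample).  See [read_fixture()] for the layout.
#'
#' @param es a valid `epoch_set` (non-finite data is refused).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(es, path) {
  validate_epoch_set(es)
  d <- dim(es$data)
  header <- jsonlite::toJSON(
    list(fs = es$fs, window = es$window, channels = es$channels,
         labels = es$labels, dim = d),
    auto_unbox = FALSE, digits = NA
  )
  # trial-major rows, channel fastest: row (i-1)*n + c <- data[i, c, ]
  M <- aperm(es$data, c(2, 1, 3))        # n x N x s
  dim(M) <- c(d[2] * d[1], d[3])
  txt <- sprintf("%.17g", M)
  dim(txt) <- dim(M)
  con <- file(path, open = "wb")         # binary mode: fixed "\n", no CRLF
  on.exit(close(con))
  writeLines(c(FIXTURE_MAGIC, paste0("#HEADER ", header)), con, sep = "\n")
  writeLines(do.call(paste, c(asplit(txt, 2), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read an epoch_set from the canonical fixture container
#'
#' @param path file produced by [write_fixture()].
#' @return a validated `epoch_set`; format violations raise a format error,
#'   invalid content (e.g. labels outside \{1, 2\}) a validation error.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("fixture file does not exist: ", path)
  top <- readLines(path, n = 2L)
  if (length(top) < 2L || top[1] != FIXTURE_MAGIC || !startsWith(top[2], "#HEADER ")) {
    stop("not a recognizable epoch fixture (bad magic/header): ", path)
  }
  hdr <- jsonlite::fromJSON(sub("^#HEADER ", "", top[2]))
  need <- c("fs", "window", "channels", "labels", "dim")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("fixture header is missing field(s): ", paste(miss, collapse = ", "))
  d <- as.integer(hdr$dim)
  M <- as.matrix(data.table::fread(path, skip = 2L, header = FALSE, sep = "\t",
                                   colClasses = "numeric"))
  if (nrow(M) != d[1] * d[2] || ncol(M) != d[3]) {
    stop("fixture data block has wrong shape: got ", nrow(M), " x ", ncol(M),
         ", header promises ", d[1] * d[2], " x ", d[3])
  }
  dim(M) <- c(d[2], d[1], d[3])
  epoch_set(aperm(M, c(2, 1, 3)), labels = hdr$labels, fs = hdr$fs,
            channels = hdr$channels, window = hdr$window)
}
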