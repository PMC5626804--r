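# CSP log-variance features and mutual-information best-individual-feature
# (MIBIF) selection.

#' Extract CSP log-variance features for every trial and band
#'
#' For trial `x` and band `b`, let `z` be the retained rows of `W_b %*% x`.
#' The feature vector is `log(diag(z z') / tr(z z'))`: the log proportion of
#' spatially filtered variance captured by each retained filter.  Features are
#' concatenated band by band (band-major, retained-row order within band), so
#' the matrix has `n_bands * 2m` columns.  The trace division makes every
#' feature invariant to positive rescaling of the trial.
#'
#' @param be a `banded_epochs` object.
#' @param models list of fitted `csp_model`s, one per band.
#' @return object of class `feature_matrix`: `values` (N x n_bands*2m, all
#'   entries <= 0), `band_of_feature`, `row_of_feature` (slot within band,
#'   1..2m), `labels`.
#' @export
extract_features <- function(be, models) {
  stopifnot(inherits(be, "banded_epochs"), length(models) == length(be$data))
  nb <- length(be$data)
  d <- dim(be$data[[1]])                 # n x s x N
  n <- d[1]; s <- d[2]; N <- d[3]
  p_band <- 2L * models[[1]]$m
  vals <- matrix(NA_real_, N, nb * p_band)
  grp <- rep(seq_len(N), each = s)
  for (b in seq_len(nb)) {
    mod <- models[[b]]
    if (mod$n != n) stop("csp model for band ", b, " expects ", mod$n,
                         " channels, data has ", n)
    Wr <- mod$W[mod$retained, , drop = FALSE]
    B <- be$data[[b]]
    dim(B) <- c(n, s * N)
    Z2 <- (Wr %*% B)^2
    v <- rowsum(t(Z2), grp)              # N x 2m: per-trial filter variances
    vals[, (b - 1L) * p_band + seq_len(p_band)] <- log(v / rowSums(v))
  }
  structure(list(values = vals,
                 band_of_feature = rep(seq_len(nb), each = p_band),
                 row_of_feature = rep(seq_len(p_band), nb),
                 labels = be$labels),
            class = "feature_matrix")
}

# partner column of each feature: the mirrored retained row in the same band
feature_partner <- function(fm) {
  p_band <- max(fm$row_of_feature)
  (fm$band_of_feature - 1L) * p_band + (p_band + 1L - fm$row_of_feature)
}

#' Mutual information between one feature and the class label
#'
#' `I(C; X) = H(C) - H(C | X)` in bits, with the class-conditional densities
#' estimated by a Gaussian-kernel Parzen window (normal-reference bandwidth
#' `sd * (4 / (3 n))^(1/5)`) evaluated on a 256-point grid spanning the
#' observed range plus three bandwidths, and the conditional entropy
#' integrated by the trapezoidal rule.  The histogram estimator (16 bins,
#' plug-in) is a cruder drop-in alternative.  A constant feature carries no
#' information and returns 0.
#'
#' @param feature numeric vector, one value per trial.
#' @param labels class labels in \{1, 2\}; both classes must be present.
#' @param estimator `"parzen"` (default) or `"histogram"`.
#' @param grid_size number of evaluation points for the Parzen estimator.
#' @return mutual information in bits (>= 0); deterministic given the data.
#' @export
mutual_information <- function(feature, labels, estimator = c("parzen", "histogram"),
                               grid_size = 256L) {
  estimator <- match.arg(estimator)
  labels <- as.integer(labels)
  if (!all(c(1L, 2L) %in% labels)) stop("both classes must be present")
  if (length(feature) != length(labels)) stop("feature/label length mismatch")
  rng <- range(feature)
  if (diff(rng) <= 0) return(0)
  pri <- c(mean(labels == 1L), mean(labels == 2L))
  h_class <- -sum(pri * log2(pri))
  if (estimator == "histogram") {
    brk <- seq(rng[1], rng[2], length.out = 17L)
    counts <- vapply(1:2, function(j) {
      tabulate(findInterval(feature[labels == j], brk, rightmost.closed = TRUE,
                            all.inside = TRUE), nbins = 16L)
    }, integer(16L))
    pxy <- counts / length(feature)
    px <- rowSums(pxy)
    hcond <- -sum(pxy[pxy > 0] * log2(sweep(pxy, 1, px, "/")[pxy > 0]))
    return(max(0, h_class - hcond))
  }
  xs <- split(feature, labels)
  bw <- vapply(xs, function(v) {
    b <- stats::sd(v) * (4 / (3 * length(v)))^0.2
    if (!is.finite(b)) b <- 0
    b
  }, 0)
  # resolvability floor: never narrower than one grid step (handles classes
  # that are point masses, e.g. feature == label)
  span0 <- diff(rng)
  bw <- pmax(bw, span0 / grid_size)
  grid <- seq(rng[1] - 3 * max(bw), rng[2] + 3 * max(bw), length.out = grid_size)
  dens <- vapply(1:2, function(j) {
    v <- xs[[as.character(j)]]
    rowMeans(outer(grid, v, function(g, x) stats::dnorm(g, x, bw[j])))
  }, numeric(grid_size))
  px <- as.numeric(dens %*% pri)
  post <- (dens * rep(pri, each = grid_size)) / ifelse(px > 0, px, 1)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_x <- -plogp(post[, 1]) - plogp(post[, 2])
  dx <- diff(grid)
  trapz <- function(y) sum(dx * (y[-1] + y[-length(y)]) / 2)
  mass <- trapz(as.numeric(px))
  if (mass <= 0) return(0)
  h_cond <- trapz(as.numeric(px) * h_x) / mass
  max(0, h_class - h_cond)
}

#' Select the most discriminative features (MIBIF with pair completion)
#'
#' Ranks every column of the feature matrix by mutual information with the
#' class label (ties broken toward the lower column index), keeps the top
#' `k_select` individual features, then adds the CSP pair partner (the
#' mirrored retained row in the same band) of every selected column that is
#' not already selected.  Order: MI-descending, then partners in the order of
#' the feature that recruited them.
#'
#' @param fm a `feature_matrix`.
#' @param k_select number of best individual features (default 4, giving 4-8
#'   columns after pair completion).
#' @param estimator mutual-information estimator, see [mutual_information()].
#' @return object of class `feature_selection`: `selected` (column indices),
#'   `mi_scores` (per column, bits).
#' @export
select_features <- function(fm, k_select = 4L,
                            estimator = c("parzen", "histogram")) {
  stopifnot(inherits(fm, "feature_matrix"))
  estimator <- match.arg(estimator)
  p <- ncol(fm$values)
  if (k_select > p) stop("k_select exceeds feature count")
  mi <- vapply(seq_len(p),
               function(j) mutual_information(fm$values[, j], fm$labels, estimator),
               0)
  ord <- order(-mi, seq_len(p))
  top <- ord[seq_len(k_select)]
  partner <- feature_partner(fm)
  sel <- top
  for (j in top) {
    if (!(partner[j] %in% sel)) sel <- c(sel, partner[j])
  }
  structure(list(selected = sel, mi_scores = mi), class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", length(x$selected), " columns: ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
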