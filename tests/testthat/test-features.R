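test_that("log-variance features follow the trace-ratio definition", {
  set.seed(1)
  # single band, identity filters: retained rows are the channels themselves
  W <- diag(4)
  mod <- fake_csp(W, m = 2)
  # trial with equal-variance orthogonal rows -> all features log(1/4)
  X <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1), c(1, 1, 1, 1))
  be <- as_banded(array(X, c(4, 4, 1)), 1L)
  f <- extract_features(be, list(mod))
  expect_equal(as.numeric(f$values), rep(log(1 / 4), 4), tolerance = 1e-12)

  # planted row variances (3, 1, 1, 1) -> log(c(3,1,1,1)/6)
  s <- 1000
  X2 <- matrix(rnorm(4 * s), 4)
  X2 <- X2 / sqrt(rowMeans(X2^2))          # exact unit row power
  X2[1, ] <- X2[1, ] * sqrt(3)
  be2 <- as_banded(array(X2, c(4, s, 1)), 1L)
  f2 <- extract_features(be2, list(mod))
  expect_equal(as.numeric(f2$values), log(c(3, 1, 1, 1) / 6), tolerance = 1e-9)

  # invariance to positive trial rescaling
  be3 <- as_banded(array(10 * X2, c(4, s, 1)), 1L)
  expect_equal(extract_features(be3, list(mod))$values, f2$values,
               tolerance = 1e-12)

  expect_error(extract_features(as_banded(array(rnorm(30), c(3, 10, 1)), 1L),
                                list(mod)), "channels")
})

test_that("feature matrix geometry is band-major with partner mirroring", {
  es <- generate_session(small_spec(seed = 4))
  be <- apply_filter_bank(es, pipeline_config())
  models <- lapply(1:9, function(b) fit_csp(class_covariances(be, b), 2))
  fm <- extract_features(be, models)
  expect_equal(ncol(fm$values), 36)
  expect_true(all(fm$values <= 0))
  expect_true(all(is.finite(fm$values)))
  expect_equal(fm$band_of_feature, rep(1:9, each = 4))
  expect_equal(fm$row_of_feature, rep(1:4, 9))
})

test_that("mutual information behaves like an MI estimator", {
  set.seed(7)
  labs <- rep(1:2, each = 500)
  # class-independent feature: zero bits
  expect_equal(mutual_information(rep(2.5, 1000), labs), 0)
  x <- rnorm(1000)
  expect_lt(mutual_information(x, sample(labs)), 0.05)

  # feature == label: the analytic one-bit limit
  expect_equal(mutual_information(as.numeric(labs), labs), 1, tolerance = 0.05)

  # Gaussian mixture, means +-1, unit variance: quadrature oracle
  set.seed(8)
  labs2 <- rep(1:2, each = 1000)
  x2 <- rnorm(2000, mean = ifelse(labs2 == 1, -1, 1))
  px <- function(t) 0.5 * dnorm(t, -1) + 0.5 * dnorm(t, 1)
  integrand <- function(t, mu) 0.5 * dnorm(t, mu) * log2(dnorm(t, mu) / px(t))
  truth <- integrate(integrand, -10, 10, mu = -1)$value +
    integrate(integrand, -10, 10, mu = 1)$value
  est <- mutual_information(x2, labs2)
  expect_equal(est, truth, tolerance = 0.05)
  # deterministic, and the histogram variant agrees roughly
  expect_identical(est, mutual_information(x2, labs2))
  expect_equal(mutual_information(x2, labs2, estimator = "histogram"), truth,
               tolerance = 0.1)

  expect_error(mutual_information(x2, rep(1, 2000)), "both classes")
})

test_that("MIBIF selection finds planted features and completes pairs", {
  set.seed(9)
  N <- 120
  labs <- rep(1:2, each = N / 2)
  vals <- matrix(rnorm(N * 36), N)
  informative <- c(2, 7, 18, 33)
  for (j in informative) vals[, j] <- ifelse(labs == 1, -1, 1) + 0.3 * rnorm(N)
  fm <- structure(list(values = vals, band_of_feature = rep(1:9, each = 4),
                       row_of_feature = rep(1:4, 9), labels = labs),
                  class = "feature_matrix")
  sel <- select_features(fm, 4)
  expect_setequal(sel$selected[1:4], informative)
  # partner completion: mirrored slot within the band
  partner <- (fm$band_of_feature - 1) * 4 + (5 - fm$row_of_feature)
  expect_true(all(partner[sel$selected] %in% sel$selected))
  expect_gte(length(sel$selected), 4)
  expect_lte(length(sel$selected), 8)

  # k_select = all columns -> everything selected
  expect_setequal(select_features(fm, 36)$selected, 1:36)

  # ranking equals a brute-force sort of the per-column MI
  mi <- vapply(1:36, function(j) mutual_information(vals[, j], labs), 0)
  expect_equal(sel$selected[1:4], order(-mi, 1:36)[1:4])

  # deterministic tie-break: duplicated informative column -> lower index first
  vals2 <- vals
  vals2[, 5] <- vals2[, 2]
  fm2 <- structure(list(values = vals2, band_of_feature = rep(1:9, each = 4),
                        row_of_feature = rep(1:4, 9), labels = labs),
                   class = "feature_matrix")
  sel2 <- select_features(fm2, 4)
  expect_lt(which(sel2$selected == 2), which(sel2$selected == 5))
})
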