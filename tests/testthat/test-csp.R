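test_that("trial_covariance matches its definition", {
  # rows orthogonal with equal power -> diag(1/2, 1/2)
  X <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(trial_covariance(X), diag(0.5, 2))

  # hand computation: XX' = [[2,0],[0,0]], trace 2
  expect_equal(trial_covariance(rbind(c(1, 1), c(0, 0))),
               rbind(c(1, 0), c(0, 0)))

  set.seed(1)
  X <- matrix(rnorm(5 * 40), 5)
  C <- X %*% t(X)
  expect_equal(trial_covariance(X), C / sum(diag(C)), tolerance = 1e-12)
  expect_equal(sum(diag(trial_covariance(X))), 1)

  expect_error(trial_covariance(matrix(0, 3, 10)), "zero")
  expect_error(trial_covariance(matrix(1, 3, 1)), "samples")
})

test_that("class_covariances averages unit-trace trial covariances", {
  set.seed(2)
  tr1 <- matrix(rnorm(3 * 20), 3)
  tr2 <- matrix(rnorm(3 * 20), 3)
  arr <- array(c(tr1, tr1, tr2), c(3, 20, 3))
  be <- as_banded(arr, c(1, 1, 2))
  cc <- class_covariances(be, 1)
  expect_equal(cc$sigma_1, trial_covariance(tr1))   # mean of equal items
  expect_equal(cc$sigma_2, trial_covariance(tr2))   # single-trial class
  expect_equal(c(cc$n_trials_1, cc$n_trials_2), c(2L, 1L))

  be_bad <- as_banded(arr, c(1, 1, 1))
  expect_error(class_covariances(be_bad, 1), "class 2")
})

test_that("estimated class covariance converges to the generating one", {
  set.seed(3)
  Sigma <- rspd(6)
  arr <- gaussian_trials(Sigma, s = 200, N = 200)
  be <- as_banded(arr, rep(1:2, 100))
  cc <- class_covariances(be, 1)
  truth <- Sigma / sum(diag(Sigma))
  expect_lt(sqrt(sum((cc$sigma_1 - truth)^2)), 0.05)
  expect_lt(sqrt(sum((cc$sigma_2 - truth)^2)), 0.05)
})

test_that("fit_csp solves the simultaneous diagonalization problem", {
  # equal class covariances: all eigenvalues 1/2
  C <- rspd(4)
  cc <- class_covariances_obj <- structure(
    list(sigma_1 = C / sum(diag(C)), sigma_2 = C / sum(diag(C)),
         n_trials_1 = 1L, n_trials_2 = 1L), class = "class_covariances")
  expect_equal(fit_csp(cc, 1)$eigvals, rep(0.5, 4), tolerance = 1e-10)

  # 2x2 closed form: eigenvalues (0.8, 0.2), axis-aligned filters
  cc2 <- structure(list(sigma_1 = diag(c(0.8, 0.2)), sigma_2 = diag(c(0.2, 0.8)),
                        n_trials_1 = 1L, n_trials_2 = 1L),
                   class = "class_covariances")
  m2 <- fit_csp(cc2, 1)
  expect_equal(m2$eigvals, c(0.8, 0.2), tolerance = 1e-10)
  Wn <- m2$W / sqrt(rowSums(m2$W^2))
  expect_equal(abs(Wn), diag(2), tolerance = 1e-8)

  # random SPD pair: W C1 W' and W C2 W' diagonal, summing to the identity
  set.seed(4)
  C1 <- rspd(6); C2 <- rspd(6)
  mod <- fit_csp(structure(list(sigma_1 = C1, sigma_2 = C2), class = "class_covariances"),
                 m = 2)
  D1 <- mod$W %*% C1 %*% t(mod$W)
  D2 <- mod$W %*% C2 %*% t(mod$W)
  expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
  expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
  expect_equal(D1 + D2, diag(6), tolerance = 1e-8)
  expect_equal(diag(D1), mod$eigvals, tolerance = 1e-10)
  expect_equal(mod$eigvals, sort(mod$eigvals, decreasing = TRUE))
  expect_equal(mod$retained, c(1, 2, 5, 6))

  expect_error(fit_csp(mod <- structure(list(sigma_1 = C1, sigma_2 = C2),
                                        class = "class_covariances"), m = 4),
               "exceeds")
})

test_that("fit_csp invariants: scale, duality, determinism", {
  set.seed(5)
  C1 <- rspd(5); C2 <- rspd(5)
  cc <- structure(list(sigma_1 = C1, sigma_2 = C2), class = "class_covariances")
  cc_scaled <- structure(list(sigma_1 = 7 * C1, sigma_2 = 7 * C2),
                         class = "class_covariances")
  a <- fit_csp(cc, 2); b <- fit_csp(cc_scaled, 2)
  expect_equal(a$eigvals, b$eigvals, tolerance = 1e-10)
  # filters identical up to the whitening scale convention
  ratio <- a$W / b$W
  expect_lt(max(abs(ratio - ratio[1, 1])), 1e-8 * abs(ratio[1, 1]))

  # eigenvalue duality under the whitening convention
  a2 <- fit_csp(structure(list(sigma_1 = C2, sigma_2 = C1),
                          class = "class_covariances"), 2)
  expect_equal(sort(a$eigvals + rev(a2$eigvals)), rep(1, 5), tolerance = 1e-10)

  # determinism incl. the sign convention
  expect_identical(fit_csp(cc, 2), fit_csp(cc, 2))
  expect_true(all(apply(a$W, 1, function(r) r[which.max(abs(r))]) > 0))
})
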