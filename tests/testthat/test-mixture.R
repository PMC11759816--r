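# Constrained-covariance EM, BIC selection and bootstrap proportion SEs.

test_that("G = 1 fit equals the closed-form Gaussian MLE", {
  set.seed(30)
  X <- matrix(rnorm(300), 100, 3)
  f <- em_fit(X, 1, "VVV")
  mu <- colMeans(X)
  S <- cov(X) * (nrow(X) - 1) / nrow(X)
  expect_equal(drop(f$means), mu, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(f$covariances[, , 1], S, ignore_attr = TRUE, tolerance = 1e-10)
  ll <- sum(mvtnorm_ll <- apply(X, 1, function(x)
    -1.5 * log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_equal(f$bic, 2 * ll - (3 + 6) * log(100), tolerance = 1e-8)
})

test_that("free-parameter counts match hand enumeration", {
  # G=2, d=2, VVV: 4 means + 1 proportion + 2 x 3 covariance = 11
  expect_equal(npar_mixture(2, 2, "VVV"), 11L)
  # G=2, d=3: VVV 6+2+12=20? means 6, prop 1, cov 2*6=12 -> 19
  expect_equal(npar_mixture(2, 3, "VVV"), 19L)
  # VEV d=3 G=2: 6 means + 1 prop + (2 volumes + 2 shape + 2*3 orientations)
  expect_equal(npar_mixture(2, 3, "VEV"), 6 + 1 + 2 + 2 + 6)
  # VVE d=3 G=2: 6 + 1 + (2 volumes + 4 shapes + 3 orientation)
  expect_equal(npar_mixture(2, 3, "VVE"), 6 + 1 + 2 + 4 + 3)
  # d=1: every model reduces to G free variances
  for (m in c("VVV", "VEV", "VVE")) {
    expect_equal(npar_mixture(3, 1, m), 3 + 2 + 3)
  }
})

test_that("well-separated sources are recovered under each covariance model", {
  set.seed(31)
  n1 <- 140; n2 <- 60
  X <- rbind(matrix(rnorm(n1 * 3, 0, 1), ncol = 3),
             sweep(matrix(rnorm(n2 * 3, 0, 0.6), ncol = 3), 2, c(7, 7, 7), "+"))
  truth <- rep(1:2, c(n1, n2))
  for (m in c("VVV", "VEV", "VVE")) {
    f <- em_fit(X, 2, m, n_restarts = 3, seed = 31)
    expect_lte(abs(f$proportions[1] - 0.7), 0.02)
    agree <- max(mean(f$classification == truth),
                 mean(f$classification == 3 - truth))
    expect_gte(agree, 0.99)
    expect_true(all(abs(f$proportions - rev(sort(f$proportions))) < 1e-12))
    expect_true(f$converged)
  }
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(32)
  X <- rbind(matrix(rnorm(90), ncol = 3), matrix(rnorm(90, 2.5), ncol = 3))
  a <- em_fit(X, 2, "VEV", n_restarts = 4, seed = 99)
  b <- em_fit(X, 2, "VEV", n_restarts = 4, seed = 99)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$proportions, b$proportions)
})

test_that("constrained M-steps respect their parameterizations", {
  set.seed(33)
  X <- rbind(matrix(rnorm(200, 0, 1), ncol = 2),
             sweep(matrix(rnorm(120, 0, 2), ncol = 2), 2, c(6, 0), "+"))
  fvev <- em_fit(X, 2, "VEV", n_restarts = 2, seed = 1)
  # VEV: shared shape -> equal sorted eigenvalue ratios across sources
  ev <- apply(fvev$covariances, 3, function(S) {
    v <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
    v / prod(v)^(1 / length(v))
  })
  expect_equal(ev[, 1], ev[, 2], tolerance = 1e-6)

  fvve <- em_fit(X, 2, "VVE", n_restarts = 2, seed = 1)
  # VVE: shared orientation -> the two covariances commute
  S1 <- fvve$covariances[, , 1]; S2 <- fvve$covariances[, , 2]
  expect_equal(S1 %*% S2, S2 %*% S1, tolerance = 1e-6 * norm(S1) * norm(S2))

  # constrained fits can never beat the free model's likelihood
  fvvv <- em_fit(X, 2, "VVV", n_restarts = 2, seed = 1)
  expect_gte(fvvv$loglik + 1e-6, fvev$loglik)
  expect_gte(fvvv$loglik + 1e-6, fvve$loglik)
})

test_that("BIC grid is ranked with non-negative deltas and canonical order", {
  set.seed(34)
  X <- rbind(matrix(rnorm(240), ncol = 2), matrix(rnorm(160, 4), ncol = 2))
  tab <- bic_select(X, 1:3, seed = 7)
  expect_true(all(diff(tab$bic) <= 0))
  expect_equal(tab$delta_bic[1], 0)
  expect_true(all(tab$delta_bic >= 0))
  expect_equal(attr(tab, "best")$G, tab$G[1])
  expect_equal(tab$G[1], 2)
})

test_that("signature transforms behave and guard their domain", {
  X <- cbind(a = c(1, 10, 100), b = c(2, 4, 8))
  lz <- transform_signatures(X, "log_zscore")
  expect_equal(colMeans(lz), c(a = 0, b = 0))
  expect_equal(apply(lz, 2, sd), c(a = 1, b = 1))
  expect_error(transform_signatures(cbind(c(-1, 2, 3)), "log_zscore"), "positive")
  expect_identical(transform_signatures(X, "none"), X)
})

test_that("bootstrap proportion SEs track the binomial rate", {
  set.seed(35)
  n <- 300; p <- 0.65
  lab <- rbinom(n, 1, p)
  X <- matrix(rnorm(n, mean = lab * 8, sd = 1), ncol = 1)
  f <- em_fit(X, 2, "VVV", n_restarts = 2, seed = 2)
  se <- proportion_se(f, X, B = 199, seed = 3)
  expect_equal(se[1], se[2], tolerance = 1e-9)  # proportions sum to 1
  analytic <- sqrt(p * (1 - p) / n)
  expect_lt(abs(se[1] - analytic) / analytic, 0.2)

  se2 <- proportion_se(f, X, B = 199, seed = 3)
  expect_identical(se, se2)

  expect_equal(proportion_se(em_fit(X, 1, "VVV"), X), 0)
  expect_warning(proportion_se(f, X, B = 20, seed = 1), "50")
})
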