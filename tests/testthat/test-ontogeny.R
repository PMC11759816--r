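# Paired stage contrasts (plain and with the event random intercept) and
# PERMANOVA on Mahalanobis distances, each checked against an independent
# route: textbook formulas, lme4, vegan, and brute-force permutation
# enumeration.

make_pairs <- function(d, event = NULL) {
  n <- length(d)
  ids <- sprintf("F%02d", seq_len(n))
  rbind(data.frame(fish_id = ids, region = "nuclear", y = 0,
                   event = if (is.null(event)) "e1" else event),
        data.frame(fish_id = ids, region = "marginal", y = d,
                   event = if (is.null(event)) "e1" else event))
}

test_that("paired contrast reproduces the textbook paired t-test", {
  set.seed(7)
  d <- 1 + rnorm(10, 0, 0.5)
  pc <- paired_contrast(make_pairs(d), "y")
  expect_equal(pc$t_statistic, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_equal(pc$df, 9)
  expect_equal(pc$p_value, 2 * pt(-abs(pc$t_statistic), 9), tolerance = 1e-12)
  expect_equal(pc$n_pairs, 10)

  # identical regions: t = 0, p = 1
  pc0 <- paired_contrast(make_pairs(rep(0, 8)), "y")
  expect_equal(pc0$t_statistic, 0)
  expect_equal(pc0$p_value, 1)

  expect_error(paired_contrast(make_pairs(c(1, 2)), "y"), "3")
})

test_that("event-grouped REML contrast matches lme4 and degenerates cleanly", {
  skip_if_not_installed("lme4")
  set.seed(8)
  ev <- rep(sprintf("E%d", 1:6), each = 5)
  d <- 2 + rep(rnorm(6, 0, 0.8), each = 5) + rnorm(30, 0, 0.5)
  pc <- paired_contrast(make_pairs(d, ev), "y", group_by_event = TRUE)
  lf <- lme4::lmer(d ~ 1 + (1 | ev), REML = TRUE)
  expect_equal(pc$estimate, unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(pc$se, sqrt(as.numeric(lme4::vcov.merMod(lf)[1, 1])),
               tolerance = 1e-5)

  # no event variance: centre the differences within events so the REML
  # profile sits on its boundary, then grouped and ungrouped t agree
  set.seed(9)
  ev0 <- rep(sprintf("E%d", 1:4), each = 6)
  d0 <- rnorm(24, 0, 0.4)
  d0 <- 1 + d0 - ave(d0, ev0)
  t_plain <- paired_contrast(make_pairs(d0), "y")$t_statistic
  t_group <- suppressMessages(
    paired_contrast(make_pairs(d0, ev0), "y", group_by_event = TRUE))$t_statistic
  expect_equal(t_group, t_plain, tolerance = 1e-6)
})

test_that("Mahalanobis distances match the quadratic-form definition", {
  # identity covariance: equals Euclidean distance
  set.seed(10)
  Z <- matrix(rnorm(60), 20, 3)
  Zw <- scale(Z) %*% solve(chol(cov(scale(Z))))  # whitened: cov = I
  expect_equal(mahalanobis_gram(Zw), as.matrix(dist(Zw)), tolerance = 1e-10)

  # three 2-d points with hand-computed S^{-1} quadratic form
  X <- rbind(c(0, 0), c(1, 0), c(3, 2), c(1, 1), c(0, 2))
  S <- cov(X)
  D <- mahalanobis_gram(X)
  for (i in 1:2) for (j in (i + 1):3) {
    v <- X[i, ] - X[j, ]
    expect_equal(D[i, j]^2, drop(t(v) %*% solve(S) %*% v), tolerance = 1e-10)
  }

  # duplicated point has distance zero
  Xd <- rbind(X, X[1, ])
  expect_equal(mahalanobis_gram(Xd)[1, 6], 0)

  # singular covariance is rejected with advice
  Xs <- cbind(1:6, (1:6) * 2)
  expect_error(mahalanobis_gram(Xs), "singular")
  expect_error(mahalanobis_gram(matrix(rnorm(6), 2, 3)), "more samples")
})

test_that("permanova pseudo-F matches vegan and handles degenerate groups", {
  skip_if_not_installed("vegan")
  set.seed(11)
  X <- matrix(rnorm(24 * 3), 24, 3)
  g <- rep(c("a", "b"), each = 12)
  X[g == "b", ] <- X[g == "b", ] + 0.8
  D <- as.matrix(dist(X))
  pv <- permanova(D, g, n_perm = 499, seed = 1)
  av <- vegan::adonis2(dist(X) ~ g, permutations = 499)
  expect_equal(pv$pseudo_F, av$F[1], tolerance = 1e-10)
  expect_equal(pseudo_f_oneway(D, g), av$F[1], tolerance = 1e-10)
  expect_equal(pv$df, c(groups = 1, residual = 22), ignore_attr = TRUE)

  # the two groups hold identical row sets: between-group numerator is zero
  Xi <- matrix(rnorm(8), 4, 2)
  expect_equal(permanova(as.matrix(dist(rbind(Xi, Xi))), rep(1:2, each = 4),
                         n_perm = 49, seed = 1)$pseudo_F, 0,
               tolerance = 1e-10)

  expect_error(permanova(D, c("a", rep("b", 23)), n_perm = 9), "2 members")
  expect_error(permanova(D[1:5, 1:6], g[1:5]), "symmetric|match")
})

test_that("pseudo-F is invariant to joint reordering of D and labels", {
  set.seed(12)
  X <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  D <- as.matrix(dist(X))
  perm <- sample(15)
  expect_equal(pseudo_f_oneway(D[perm, perm], g[perm]), pseudo_f_oneway(D, g),
               tolerance = 1e-12)
})

test_that("Monte-Carlo p agrees with full enumeration at n = 6", {
  set.seed(13)
  X <- matrix(rnorm(12), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  D <- as.matrix(dist(X))
  f_obs <- pseudo_f_oneway(D, g)
  # brute force over all 720 label permutations
  perms <- as.matrix(expand.grid(rep(list(1:6), 2)))  # placeholder
  allp <- combn(6, 3)
  f_all <- apply(allp, 2, function(idx) {
    gi <- rep("b", 6); gi[idx] <- "a"
    pseudo_f_oneway(D, gi)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  pv <- permanova(D, g, n_perm = 9999, seed = 3)
  expect_lt(abs(pv$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2e-4)
})

test_that("restricted permutations respect strata and the covariate is fixed", {
  set.seed(14)
  # paired design: 10 fish x 2 regions, strong fish effect, no region effect
  nfish <- 10
  fish <- rep(sprintf("F%d", 1:nfish), each = 2)
  region <- rep(c("nuclear", "marginal"), nfish)
  y <- rep(rnorm(nfish, 0, 3), each = 2) + rnorm(2 * nfish, 0, 0.3)
  D <- as.matrix(dist(cbind(y)))
  pv <- permanova(D, region, strata = fish, n_perm = 299, seed = 5)
  expect_gte(pv$p_value, 0.05)  # no region effect to find
  pv2 <- permanova(D, region, covariate = fish, strata = fish,
                   n_perm = 299, seed = 5)
  expect_true(is.finite(pv2$pseudo_F))
})
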