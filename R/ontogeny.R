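# Juvenile-vs-adult signature contrasts: paired within-fish mixed-model tests
# and permutational multivariate ANOVA (PERMANOVA) on Mahalanobis distances.

#' Paired within-fish contrast between otolith regions
#'
#' Computes adult-minus-juvenile (marginal minus nuclear) differences within
#' each fish and fits an intercept-only model, testing H0: intercept = 0 with a
#' t statistic (df = number of pairs - 1). With `group_by_event = TRUE` a
#' fishing-event random intercept is added, fitted by restricted maximum
#' likelihood through a one-dimensional profile optimisation on the variance
#' ratio psi = sigma_event^2 / sigma_resid^2; this absorbs the dependence
#' expected between fish caught in the same tow.
#'
#' @param signatures data.frame with `fish_id`, `region` (nuclear/marginal) and
#'   the variable column; optionally `event` per row or via `events`.
#' @param variable name of the column to contrast.
#' @param group_by_event add the fishing-event random intercept?
#' @param events optional named vector fish_id -> event id (used when the
#'   signatures table has no `event` column).
#' @return object of class `paired_contrast`: a one-row data.frame with the
#'   region means/SDs, t, df, p and n_pairs.
#' @export
paired_contrast <- function(signatures, variable, group_by_event = FALSE,
                            events = NULL) {
  nuc <- signatures[signatures$region == "nuclear", c("fish_id", variable)]
  mar <- signatures[signatures$region == "marginal", c("fish_id", variable)]
  m <- merge(nuc, mar, by = "fish_id", suffixes = c("_juv", "_adu"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop("paired_contrast needs at least 3 complete pairs")
  d <- m[[paste0(variable, "_adu")]] - m[[paste0(variable, "_juv")]]

  if (!group_by_event) {
    if (sd(d) == 0 && mean(d) == 0) {
      tstat <- 0; se <- 0
    } else {
      se <- sd(d) / sqrt(n)
      tstat <- mean(d) / se
    }
    est <- mean(d)
    df <- n - 1
  } else {
    ev <- if (!is.null(events)) {
      as.factor(events[as.character(m$fish_id)])
    } else if ("event" %in% names(signatures)) {
      key <- signatures[signatures$region == "marginal", ]
      as.factor(key$event[match(m$fish_id, key$fish_id)])
    } else stop("group_by_event = TRUE but no event information supplied")
    fit <- reml_intercept(d, ev)
    est <- fit$beta; se <- fit$se
    tstat <- if (se == 0) 0 else est / se
    df <- n - 1  # plain paired df by design; no Satterthwaite correction
  }
  p <- if (tstat == 0) 1 else 2 * pt(-abs(tstat), df)
  out <- data.frame(
    variable = variable,
    mean_juvenile = mean(m[[paste0(variable, "_juv")]]),
    sd_juvenile   = sd(m[[paste0(variable, "_juv")]]),
    mean_adult    = mean(m[[paste0(variable, "_adu")]]),
    sd_adult      = sd(m[[paste0(variable, "_adu")]]),
    estimate = est, se = se, t_statistic = tstat, df = df, p_value = p,
    n_pairs = n
  )
  class(out) <- c("paired_contrast", "data.frame")
  out
}

# REML fit of d_i = beta + b_{event(i)} + e_i with one random intercept.
# Profile restricted likelihood over psi = var_b / var_e on log scale.
reml_intercept <- function(d, event) {
  n <- length(d)
  Z <- stats::model.matrix(~ event - 1)
  one <- rep(1, n)
  crit <- function(log_psi) {
    psi <- exp(log_psi)
    V <- diag(n) + psi * tcrossprod(Z)
    ch <- chol(V)
    Vi_d <- backsolve(ch, backsolve(ch, d, transpose = TRUE))
    Vi_1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
    s11 <- sum(one * Vi_1)
    beta <- sum(one * Vi_d) / s11
    r <- d - beta * one
    Vi_r <- Vi_d - beta * Vi_1
    sig2 <- sum(r * Vi_r) / (n - 1)
    logdetV <- 2 * sum(log(diag(ch)))
    # restricted log-likelihood up to a constant
    -0.5 * ((n - 1) * log(sig2) + logdetV + log(s11)) -
      0.5 * (n - 1)
  }
  opt <- optimize(crit, interval = c(-15, 10), maximum = TRUE, tol = 1e-10)
  psi <- exp(opt$maximum)
  if (crit(-30) >= opt$objective - 1e-8) psi <- 0  # boundary: no event variance
  V <- diag(n) + psi * tcrossprod(Z)
  ch <- chol(V)
  Vi_d <- backsolve(ch, backsolve(ch, d, transpose = TRUE))
  Vi_1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  s11 <- sum(one * Vi_1)
  beta <- sum(one * Vi_d) / s11
  r <- d - beta
  Vi_r <- Vi_d - beta * Vi_1
  sig2 <- sum(r * Vi_r) / (n - 1)
  list(beta = beta, se = sqrt(sig2 / s11), psi = psi, sigma2 = sig2)
}

#' Pairwise Mahalanobis distance matrix
#'
#' \eqn{d(i,j)^2 = (x_i - x_j)^T S^{-1} (x_i - x_j)} with S the total-sample
#' covariance. Equivalent to Euclidean distance after whitening.
#'
#' @param X numeric matrix (rows = samples).
#' @return symmetric distance matrix with zero diagonal.
#' @export
mahalanobis_gram <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more samples than variables")
  S <- cov(X)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    stop("total-sample covariance is singular; reduce dimensions before computing Mahalanobis distances")
  }
  # whiten: rows of Y = R^-T x so that ||y_i - y_j||^2 = mahalanobis d^2
  Y <- t(backsolve(ch, t(X), transpose = TRUE))
  as.matrix(dist(Y))
}

#' Permutational multivariate analysis of variance
#'
#' McArdle--Anderson partition of squared distances. `groups` is the factor
#' under test; an optional `covariate` factor is entered first as a fixed term
#' (its sums of squares are removed before testing `groups`), and permutations
#' shuffle group labels -- within `strata` blocks when given -- while the
#' covariate stays fixed. The p-value is `(1 + #permuted F >= observed F) /
#' (1 + n_perm)`.
#'
#' @param D distance matrix (square symmetric, zero diagonal) or `dist`.
#' @param groups factor of group labels under test.
#' @param covariate optional factor entered as a fixed first term.
#' @param strata optional factor restricting permutations to blocks.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @return object of class `permanova`: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `n_samples`, df and sums of squares.
#' @export
permanova <- function(D, groups, covariate = NULL, strata = NULL,
                      n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0)) {
    stop("D must be a symmetric distance matrix with zero diagonal")
  }
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match D")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")

  if (is.null(covariate) && is.null(strata)) {
    return(permanova_oneway(D, groups, n_perm))
  }

  G <- gower_center(D)
  sst <- sum(diag(G))

  X0 <- if (is.null(covariate)) matrix(1, n, 1) else
    stats::model.matrix(~ as.factor(covariate))
  H0 <- hat_of(X0)
  ss0 <- sum(H0 * G)

  f_of <- function(g) {
    X1 <- cbind(X0, stats::model.matrix(~ g)[, -1, drop = FALSE])
    H1 <- hat_of(X1)
    df1 <- attr(H1, "rank") - attr(H0, "rank")
    df2 <- n - attr(H1, "rank")
    ssg <- sum(H1 * G) - ss0
    ssr <- sst - sum(H1 * G)
    list(F = (ssg / df1) / (ssr / df2), ssg = ssg, ssr = ssr,
         df1 = df1, df2 = df2)
  }
  obs <- f_of(groups)

  perm_index <- function() {
    if (is.null(strata)) sample.int(n) else {
      idx <- seq_len(n)
      for (b in split(idx, strata)) idx[b] <- b[sample.int(length(b))]
      idx
    }
  }
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    Fp <- f_of(groups[perm_index()])$F
    if (Fp >= obs$F - 1e-12) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = obs$F,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm, n_samples = n,
                 df = c(groups = obs$df1, residual = obs$df2),
                 ss = c(groups = obs$ssg, residual = obs$ssr, total = sst)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations, n = %d)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations,
              x$n_samples))
  invisible(x)
}

# One-way case: direct sums-of-squares partition, with all permutations
# evaluated at once through group-indicator matrix products. Identical
# statistic and p-value definition to the general path, just vectorised.
permanova_oneway <- function(D, groups, n_perm) {
  D2 <- D^2
  n <- nrow(D2)
  a <- nlevels(groups)
  sst <- sum(D2) / (2 * n)
  Z <- stats::model.matrix(~ groups - 1)            # n x a indicator
  ng <- colSums(Z)
  f_of_Z <- function(Zm) {
    ssw <- colSums(matrix(colSums(Zm * (D2 %*% Zm)), nrow = a) / (2 * ng))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of_Z(Z)
  # permutations in blocks to bound memory
  exceed <- 0L
  block <- 200L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Zp <- matrix(0, n, a * b)
    for (j in seq_len(b)) {
      Zp[, (j - 1) * a + seq_len(a)] <- Z[sample.int(n), ]
    }
    exceed <- exceed + sum(f_of_Z(Zp) >= f_obs - 1e-12)
    done <- done + b
  }
  ssw_obs <- colSums(matrix(colSums(Z * (D2 %*% Z)), nrow = a) / (2 * ng))
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm, n_samples = n,
                 df = c(groups = a - 1, residual = n - a),
                 ss = c(groups = sst - ssw_obs, residual = ssw_obs, total = sst)),
            class = "permanova")
}

# Gower-centred inner-product matrix of a distance matrix.
gower_center <- function(D) {
  A <- -0.5 * D^2
  J <- diag(nrow(D)) - 1 / nrow(D)
  J %*% A %*% J
}

hat_of <- function(X) {
  qrx <- qr(X)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  H <- tcrossprod(Q)
  attr(H, "rank") <- qrx$rank
  H
}

#' One-way pseudo-F for a distance matrix (fast path)
#'
#' Direct sums-of-squares form used by the permutation-calibration tests:
#' `SS_within = sum_g (sum_{i<j in g} d_ij^2) / n_g`. Equals the
#' McArdle--Anderson trace form for a one-way design.
#'
#' @param D distance matrix.
#' @param groups factor.
#' @return pseudo-F value.
#' @export
pseudo_f_oneway <- function(D, groups) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}
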