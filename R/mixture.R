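# Gaussian finite mixture models for nursery-source estimation.
#
# Covariance parameterizations follow the eigen-decomposition
# Sigma_g = lambda_g D_g A_g D_g' (volume, orientation, shape). Only the
# uneven-volume family is implemented (lambda_g free in every model):
#   VVV - everything varies (free covariances)
#   VEV - shared shape A, per-source orientation D_g
#   VVE - shared orientation D, per-source shape A_g
# BIC uses the 2*loglik - m*log(n) convention (maximised; values are negative
# at realistic n, as in the mixture-model literature this mirrors).

#' Transform chemical signatures before mixture fitting
#'
#' Element:Ca ratios are positive and span orders of magnitude, so the default
#' is log then column z-scoring; isotope columns are typically fitted
#' untransformed (`"zscore"` or `"none"`).
#'
#' @param X numeric matrix or data.frame of signatures.
#' @param method one of `"log_zscore"`, `"zscore"`, `"none"`.
#' @return numeric matrix with centring/scaling attributes.
#' @export
transform_signatures <- function(X, method = c("log_zscore", "zscore", "none")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "log_zscore") {
    if (any(X <= 0)) stop("log transform requires strictly positive values")
    X <- log(X)
  }
  if (method != "none") X <- scale(X)
  X
}

#' Free-parameter count of a constrained Gaussian mixture
#'
#' Means contribute `G*d`, mixing proportions `G - 1`, and covariances depend
#' on the parameterization: `G*d*(d+1)/2` (VVV),
#' `G + (d-1) + G*d*(d-1)/2` (VEV), `G + G*(d-1) + d*(d-1)/2` (VVE).
#'
#' @param G number of sources, `d` dimension, `model` parameterization.
#' @param d data dimension.
#' @param model covariance model name.
#' @return integer parameter count.
#' @export
npar_mixture <- function(G, d, model) {
  covp <- if (d == 1) G else switch(model,
    VVV = G * d * (d + 1) / 2,
    VEV = G + (d - 1) + G * d * (d - 1) / 2,
    VVE = G + G * (d - 1) + d * (d - 1) / 2,
    stop("unknown covariance model: ", model))
  as.integer(G * d + (G - 1) + covp)
}

# Row-wise log-sum-exp.
row_lse <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# log N(x; mu, Sigma) for all rows of X, via Cholesky. Errors on non-PD.
log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  ch <- chol(Sigma)
  z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# --- constrained M-steps ------------------------------------------------------

# Scatter matrices W_g = sum_i z_ig (x_i - mu_g)(x_i - mu_g)'.
scatter_matrices <- function(X, z, mu) {
  d <- ncol(X); G <- ncol(z)
  W <- array(0, c(d, d, G))
  for (g in seq_len(G)) {
    Xc <- sweep(X, 2, mu[, g]) * sqrt(z[, g])
    W[, , g] <- crossprod(Xc)
  }
  W
}

mstep_sigma <- function(model, W, ng, state = NULL) {
  d <- dim(W)[1]; G <- dim(W)[3]
  Sigma <- array(0, c(d, d, G))
  if (d == 1) {
    for (g in seq_len(G)) Sigma[, , g] <- W[, , g] / ng[g]
    return(list(Sigma = Sigma, state = state))
  }
  if (model == "VVV" || G == 1) {
    for (g in seq_len(G)) Sigma[, , g] <- W[, , g] / ng[g]
    return(list(Sigma = Sigma, state = state))
  }
  if (model == "VEV") {
    eigs <- lapply(seq_len(G), function(g) eigen(W[, , g], symmetric = TRUE))
    Om <- vapply(eigs, function(e) pmax(e$values, 1e-300), numeric(d))  # d x G
    lambda <- vapply(seq_len(G), function(g) prod(Om[, g])^(1 / d) / ng[g], 0)
    for (it in 1:100) {
      A <- rowSums(sweep(Om, 2, lambda, "/"))
      A <- pmax(A, 1e-300); A <- A / prod(A)^(1 / d)
      lambda_new <- colSums(Om / A) / (d * ng)
      if (max(abs(lambda_new - lambda) / (lambda + 1e-300)) < 1e-10) {
        lambda <- lambda_new; break
      }
      lambda <- lambda_new
    }
    for (g in seq_len(G)) {
      L <- eigs[[g]]$vectors
      Sigma[, , g] <- lambda[g] * L %*% (A * t(L))
    }
    return(list(Sigma = Sigma, state = state))
  }
  if (model == "VVE") {
    # common orientation D, per-source volume/shape; D updated by an MM scheme
    Wsum <- apply(W, c(1, 2), sum)
    D <- if (is.null(state$D)) eigen(Wsum, symmetric = TRUE)$vectors else state$D
    omax <- vapply(seq_len(G), function(g)
      max(eigen(W[, , g], symmetric = TRUE, only.values = TRUE)$values), 0)
    obj_old <- Inf
    lambda <- numeric(G); A <- matrix(0, d, G)
    for (it in 1:100) {
      C <- vapply(seq_len(G), function(g)
        pmax(diag(crossprod(D, W[, , g] %*% D)) / ng[g], 1e-300), numeric(d))
      lambda <- apply(C, 2, function(c) prod(c)^(1 / d))
      A <- sweep(C, 2, lambda, "/")
      obj <- sum(ng * d * log(lambda)) +
        sum(vapply(seq_len(G), function(g)
          sum(diag(crossprod(D, W[, , g] %*% D)) / (lambda[g] * A[, g])), 0))
      if (is.finite(obj_old) && obj_old - obj < 1e-10 * (abs(obj) + 1)) break
      obj_old <- obj
      Gp <- matrix(0, d, d)
      for (g in seq_len(G)) {
        Gp <- Gp + ((W[, , g] - omax[g] * diag(d)) %*% D) %*%
          diag(1 / (A[, g] * lambda[g]), d)
      }
      sv <- svd(Gp)
      D <- -sv$u %*% t(sv$v)
    }
    for (g in seq_len(G)) Sigma[, , g] <- D %*% (lambda[g] * A[, g] * t(D))
    return(list(Sigma = Sigma, state = list(D = D)))
  }
  stop("unknown covariance model: ", model)
}

# --- EM core ------------------------------------------------------------------

em_run <- function(X, G, model, z, tol, max_iter) {
  n <- nrow(X); d <- ncol(X)
  state <- NULL
  ll_old <- -Inf
  ll_path <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ng <- colSums(z)
    if (any(ng < d + 1e-8)) stop("degenerate component (empty source)")
    prop <- ng / n
    mu <- t(crossprod(z, X) / ng)                    # d x G
    W <- scatter_matrices(X, z, mu)
    ms <- mstep_sigma(model, W, ng, state)
    Sigma <- ms$Sigma; state <- ms$state
    logd <- matrix(0, n, G)
    for (g in seq_len(G)) {
      logd[, g] <- log(prop[g]) + log_dmvnorm(X, mu[, g], Sigma[, , g])
    }
    lse <- row_lse(logd)
    ll <- sum(lse)
    if (!is.finite(ll)) stop("degenerate component (non-finite likelihood)")
    # EM guarantee: the observed log-likelihood never decreases
    if (ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      stop(sprintf("EM log-likelihood decreased (%.10g -> %.10g)", ll_old, ll))
    }
    ll_path <- c(ll_path, ll)
    z <- exp(logd - lse)
    if (ll - ll_old < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(loglik = ll_old, prop = prop, mu = mu, Sigma = Sigma, z = z,
       n_iter = length(ll_path), ll_path = ll_path,
       converged = length(ll_path) < max_iter)
}

hard_z <- function(cl, G, n) {
  z <- matrix(1e-10, n, G)
  z[cbind(seq_len(n), cl)] <- 1
  z / rowSums(z)
}

#' Fit a Gaussian finite mixture with a constrained covariance model
#'
#' EM algorithm for `G` multivariate normal sources under the uneven-volume
#' covariance parameterizations VVV, VEV or VVE. The first start is
#' deterministic (Ward hierarchical agglomeration); `n_restarts` further random
#' starts guard against local maxima, and the best start by log-likelihood is
#' returned. Components are canonicalized by descending mixing proportion.
#' A start whose components collapse is retried with jittered assignments; the
#' fit errors only if every start degenerates.
#'
#' @param X numeric matrix of per-fish signatures (rows = fish); transform
#'   beforehand with [transform_signatures()] if desired.
#' @param G number of sources.
#' @param model covariance model (`"VVV"`, `"VEV"` or `"VVE"`).
#' @param n_restarts number of random restarts after the hierarchical start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed optional RNG seed.
#' @param init_z optional starting responsibility matrix (overrides the
#'   built-in initialization; used for warm starts).
#' @return object of class `mixture_fit`.
#' @export
em_fit <- function(X, G, model = c("VVV", "VEV", "VVE"), n_restarts = 20,
                   tol = 1e-8, max_iter = 1000, seed = NULL, init_z = NULL) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= G) stop("need more observations than sources")
  if (!is.null(seed)) set.seed(seed)

  starts <- list()
  if (!is.null(init_z)) {
    starts[[1]] <- init_z
  } else if (G == 1) {
    starts[[1]] <- matrix(1, n, 1)
  } else {
    hc <- hclust(dist(X), method = "ward.D2")
    starts[[1]] <- hard_z(cutree(hc, G), G, n)
    for (r in seq_len(n_restarts)) {
      centers <- X[sample.int(n, G), , drop = FALSE]
      cl <- max.col(-as.matrix(dist(rbind(centers, X)))[-(1:G), 1:G, drop = FALSE])
      starts[[r + 1]] <- hard_z(cl, G, n)
    }
  }

  best <- NULL
  for (s in seq_along(starts)) {
    z <- starts[[s]]
    fit <- NULL
    for (attempt in 1:3) {
      fit <- tryCatch(em_run(X, G, model, z, tol, max_iter),
                      error = function(e) {
                        if (grepl("degenerate", conditionMessage(e))) NULL else stop(e)
                      })
      if (!is.null(fit)) break
      # jitter the assignment and retry
      z <- z + matrix(runif(n * G, 0, 0.3), n, G)
      z <- z / rowSums(z)
    }
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("all EM starts degenerated; consider fewer sources")

  ord <- order(best$prop, decreasing = TRUE)
  m <- npar_mixture(G, d, model)
  structure(list(G = G, covariance_model = model,
                 proportions = best$prop[ord],
                 means = best$mu[, ord, drop = FALSE],
                 covariances = best$Sigma[, , ord, drop = FALSE],
                 z = best$z[, ord, drop = FALSE],
                 classification = max.col(best$z[, ord, drop = FALSE]),
                 loglik = best$loglik, df = m,
                 bic = 2 * best$loglik - m * log(n),
                 n = n, d = d, converged = best$converged,
                 n_restarts = if (is.null(init_z)) n_restarts else 0L,
                 seed = seed,
                 colnames = colnames(X)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: G = %d (%s), n = %d, d = %d\n",
              x$G, x$covariance_model, x$n, x$d))
  cat(sprintf("  loglik = %.3f, df = %d, BIC = %.1f\n", x$loglik, x$df, x$bic))
  cat("  proportions:", paste(sprintf("%.3f", x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' Fit and rank mixtures over source counts and covariance models by BIC
#'
#' Fits every `(G, model)` pair and ranks by BIC (higher is better under the
#' `2*loglik - m*log(n)` convention). `delta_bic = BIC_best - BIC_model >= 0`.
#'
#' Selection uses the deterministic hierarchical-agglomeration start only
#' (`n_restarts = 0`): random restarts readily land on spurious tiny-volume
#' local maxima of the mixture likelihood, which inflates the apparent
#' log-likelihood of over-fitted source counts and biases selection toward too
#' many sources on unstructured data. Restarts remain available (and default
#' on) in [em_fit()] for refining a chosen model.
#'
#' @param X signature matrix (rows = fish).
#' @param G_range source counts to try (default 1--5).
#' @param models covariance models to try.
#' @param n_restarts random restarts per fit (default 0; see Details).
#' @param ... passed to [em_fit()].
#' @return object of class `bic_grid`: data.frame of ranked fits with the
#'   fitted objects in `attr(, "fits")` and the winner in `attr(, "best")`.
#' @export
bic_select <- function(X, G_range = 1:5, models = c("VVV", "VEV", "VVE"),
                       n_restarts = 0, ...) {
  grid <- expand.grid(G = G_range, model = models, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[i] <- list(tryCatch(em_fit(X, grid$G[i], grid$model[i],
                                    n_restarts = n_restarts, ...),
                             error = function(e) NULL))
  }
  if (all(vapply(fits, is.null, TRUE))) stop("every mixture fit failed")
  ok <- !vapply(fits, is.null, TRUE)
  grid <- grid[ok, , drop = FALSE]; fits <- fits[ok]
  tab <- data.frame(G = grid$G, model = grid$model,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    df = vapply(fits, `[[`, 0L, "df"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  ord <- order(tab$bic, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]; fits <- fits[ord]
  tab$delta_bic <- tab$bic[1] - tab$bic
  rownames(tab) <- NULL
  class(tab) <- c("bic_grid", "data.frame")
  attr(tab, "fits") <- fits
  attr(tab, "best") <- fits[[1]]
  tab
}

# Match bootstrap components to reference components by closest means
# (minimises total squared distance over permutations; G is small).
match_components <- function(mu_ref, mu_new) {
  G <- ncol(mu_ref)
  perms <- perms_of(G)
  costs <- vapply(seq_len(nrow(perms)), function(i)
    sum((mu_ref - mu_new[, perms[i, ], drop = FALSE])^2), 0)
  perms[which.min(costs), ]
}

perms_of <- function(G) {
  if (G == 1) return(matrix(1, 1, 1))
  sub <- perms_of(G - 1)
  out <- NULL
  for (pos in seq_len(G)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], G,
                            sub[, seq(pos, G - 1)[seq_len(G - pos)], drop = FALSE]))
  }
  out
}

#' Standard errors of mixing proportions by nonparametric bootstrap
#'
#' Resamples fish with replacement, refits the mixture (warm-started from the
#' original responsibilities) and matches components back to the original fit
#' by closest means before summarising. `G = 1` returns SE 0 without
#' resampling.
#'
#' @param fit a [mixture_fit][em_fit()].
#' @param X the signature matrix the fit used.
#' @param B bootstrap replicates (default 999; < 50 warns).
#' @param seed optional RNG seed.
#' @return numeric vector of SEs, one per source (in the fit's source order).
#' @export
proportion_se <- function(fit, X, B = 999, seed = NULL) {
  if (B < 50) warning("fewer than 50 bootstrap replicates: SEs will be noisy")
  if (fit$G == 1) return(0)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  props <- matrix(NA_real_, B, fit$G)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(
      em_fit(X[idx, , drop = FALSE], fit$G, fit$covariance_model,
             tol = 1e-6, max_iter = 200, init_z = fit$z[idx, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(bf)) next
    perm <- match_components(fit$means, bf$means)
    props[b, ] <- bf$proportions[perm]
  }
  apply(props, 2, sd, na.rm = TRUE)
}
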