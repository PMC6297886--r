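#' Split-chain potential scale reduction (Rhat)
#'
#' Gelman-Rubin statistic computed on split chains: each chain is halved,
#' and Rhat = sqrt(((n-1)/n * W + B/n) / W) over the resulting 2m
#' sequences.  Values near 1 indicate convergence; below 1.1 is the usual
#' operational criterion.  Chains with zero within- and between-chain
#' variance (constant draws) return 1 with attribute `degenerate = TRUE`.
#'
#' @param x iterations-by-chains matrix of draws for one parameter, or a
#'   list of equal-length numeric vectors.
#' @return scalar Rhat.
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 chains", call. = FALSE)
  if (nrow(x) < 4L) stop("need >= 4 draws per chain", call. = FALSE)
  n2 <- floor(nrow(x) / 2L)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n2), j], x[n2 + seq_len(n2), j])))
  n <- nrow(halves); m <- ncol(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2L, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) {
    if (!is.finite(B) || B == 0)
      return(structure(1, degenerate = TRUE))
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Multivariate potential scale reduction (Brooks-Gelman)
#'
#' The multivariate generalization: `(n-1)/n + (m+1)/m * lambda1`, where
#' `lambda1` is the largest eigenvalue of `W^{-1} B / n`.  Offered as an
#' additional diagnostic; the operational criterion remains the
#' per-parameter split [rhat()].
#'
#' @param chains list of iterations-by-parameters draw matrices, one per
#'   chain.
#' @return scalar multivariate Rhat.
#' @export
rhat_multivariate <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  m <- length(chains); n <- nrow(chains[[1L]])
  keep <- apply(do.call(rbind, chains), 2L, stats::sd) > 1e-10
  chains <- lapply(chains, function(x) x[, keep, drop = FALSE])
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mu <- t(vapply(chains, colMeans, numeric(ncol(chains[[1L]]))))
  B <- n * stats::cov(mu)
  W <- W + diag(1e-10, ncol(W))
  lambda1 <- max(Re(eigen(solve(W, B / n), only.values = TRUE)$values))
  (n - 1) / n + (m + 1) / m * lambda1
}

# Generalized Pareto fit (Zhang & Stephens 2009 profile posterior mean,
# with the weak prior regularization toward k = 0.5 used in PSIS practice).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(t) -mean(log1p(-t * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), 0)
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  k <- (n * k + 5) / (n + 10)   # regularize khat toward 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance sampling of one vector of log ratios.
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5L || stats::sd(lr) < 1e-12)
    return(list(lw = lr, k = 0))
  ord <- order(lr)
  tail_ids <- ord[(S - tail_len + 1L):S]
  cutoff <- lr[ord[S - tail_len]]
  exceed <- exp(lr[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(lw = lr, k = 0))
  fit <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fit$k) || !is.finite(fit$sigma) || fit$sigma <= 0)
    return(list(lw = lr, k = if (is.finite(fit$k)) fit$k else Inf))
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- suppressWarnings(log(exp(cutoff) + qgpd(p, fit$k, fit$sigma)))
  smoothed <- pmin(smoothed, 0)   # truncate at the raw maximum
  if (!all(is.finite(smoothed))) return(list(lw = lr, k = fit$k))
  lw <- lr
  lw[tail_ids[order(lr[tail_ids])]] <- smoothed
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Pareto-smoothed importance-sampling estimate of leave-one-out
#' cross-validation from pointwise log-likelihood draws: per respondent,
#' the importance ratios `1/p(y_e | theta_s)` are tail-smoothed by a
#' generalized Pareto fit and the LOO predictive density is the weighted
#' average of the likelihood draws.  `LOOIC = -2 * ELPD` exactly.
#'
#' @param pointwise respondents-by-draws matrix of log-likelihood values
#'   (e.g. `fit(...)$pointwise_loglik`).
#' @return a `fit_indices` list: `elpd`, `elpd_se`, `looic`, `looic_se`,
#'   `pointwise` (per-respondent ELPD contributions) and `pareto_k`
#'   diagnostics.  Respondents with `pareto_k > 0.7` trigger a warning.
#' @export
elpd_loo <- function(pointwise) {
  ll <- as.matrix(pointwise)
  if (!all(is.finite(ll)))
    stop("pointwise log-likelihood draws must be finite", call. = FALSE)
  N <- nrow(ll)
  res <- lapply(seq_len(N), function(e) psis_smooth(-ll[e, ]))
  elpd_i <- vapply(seq_len(N), function(e) {
    lw <- res[[e]]$lw
    lw <- lw - log_sum_exp(lw)
    log_sum_exp(lw + ll[e, ])
  }, 0)
  k <- vapply(res, `[[`, 0, "k")
  if (any(k > 0.7))
    warning(sum(k > 0.7), " respondent(s) with Pareto k > 0.7; ",
            "PSIS-LOO estimate may be unstable", call. = FALSE)
  elpd <- sum(elpd_i)
  se <- sqrt(N * stats::var(elpd_i))
  structure(list(elpd = elpd, elpd_se = se, looic = -2 * elpd,
                 looic_se = 2 * se, pointwise = elpd_i, pareto_k = k),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("ELPD  %8.1f (SE %.1f)\nLOOIC %8.1f (SE %.1f)\n",
              x$elpd, x$elpd_se, x$looic, x$looic_se))
  invisible(x)
}
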