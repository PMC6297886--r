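test_that("split-chain Rhat behaves at and away from convergence", {
  set.seed(1)
  # two halves of one long stream: converged
  x <- matrix(rnorm(4000), 2000, 2)
  expect_gt(rhat(x), 0.97)
  expect_lt(rhat(x), 1.03)
  # separated chains
  y <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(rhat(y), 1.1)
  # constant chains: 1 by convention, flagged
  z <- matrix(1, 100, 2)
  expect_equal(as.numeric(rhat(z)), 1)
  expect_true(attr(rhat(z), "degenerate"))
  expect_error(rhat(matrix(1, 100, 1)), ">= 2 chains")
  # multivariate version agrees on converged draws
  ch <- list(matrix(rnorm(2000), 1000, 2), matrix(rnorm(2000), 1000, 2))
  expect_lt(rhat_multivariate(ch), 1.1)
})

test_that("analytic gradients match finite differences (all models)", {
  d <- tiny_design(K = 2, I = 3, M = 3)
  set.seed(4)
  dat <- generate_dataset(rand_params("ordm", d, 2), d,
                          c(0.4, 0.2, 0.1, 0.3), 40, seed = 2)
  for (model in c("nrdm", "ordm", "mordm")) {
    lp <- ordinalDCM:::make_logpost(model, d, dat$responses)
    D <- lp$map$P + lp$C - 1L
    theta <- ordinalDCM:::default_start(lp$map$index, lp$C) +
      rnorm(D, 0, 0.2)
    g <- lp$gr(theta)
    gn <- vapply(seq_len(D), function(j) {
      e <- numeric(D); e[j] <- 1e-6
      (lp$fn(theta + e) - lp$fn(theta - e)) / 2e-6
    }, 0)
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("MAP estimation is deterministic and recovers the truth", {
  d <- example_design()
  truth <- example_truth("ordm")
  dat <- generate_dataset(truth, d, example_prevalence(), 500, seed = 31)
  cfg <- sampler_config(seed = 5)
  f1 <- suppressWarnings(fit("ordm", dat, d, cfg, method = "map"))
  f2 <- suppressWarnings(fit("ordm", dat, d, cfg, method = "map"))
  expect_identical(f1$estimates, f2$estimates)
  expect_true(f1$converged)
  # prevalence recovery
  expect_lt(max(abs(f1$prevalence - example_prevalence())), 0.05)
  # estimates respect constraints and match the truth's sign structure
  expect_true(all(validate_constraints(f1$params, d)$pass))
  idx <- parameter_index("ordm", d)
  truth_psi <- ordinalDCM:::params_to_vector(
    natural_to_pseudo(truth, d), idx, d)
  est_psi <- f1$estimates[idx$name]
  # effect parameters are identified by every dataset; intercept
  # increments of near-unobserved options are not, so judge the former
  # strictly and the rest in aggregate
  eff <- idx$name[idx$family == "effect" & idx$item != 8L]
  expect_lt(max(abs(est_psi[eff] - truth_psi[eff])), 1.0)
  expect_gt(mean(abs(est_psi - truth_psi) < 1.0), 0.7)
})

test_that("posteriors are data-dominated under the default diffuse prior", {
  d <- example_design()
  truth <- example_truth("mordm")
  dat <- generate_dataset(truth, d, example_prevalence(), 500, seed = 13)
  f20 <- suppressWarnings(fit("mordm", dat, d,
                              sampler_config(prior_sd = 20),
                              method = "map"))
  f10 <- suppressWarnings(fit("mordm", dat, d,
                              sampler_config(prior_sd = 10),
                              method = "map"))
  idx <- parameter_index("mordm", d)
  # effect parameters are well populated in every dataset; halving the
  # prior sd barely moves them
  eff <- idx$name[idx$family == "effect"]
  expect_lt(max(abs(f20$estimates[eff] - f10$estimates[eff])), 0.25)
})

test_that("short MCMC runs are deterministic and respect constraints", {
  d <- tiny_design(K = 1, I = 3, M = 3)
  truth <- rand_params("ordm", d, 8)
  dat <- generate_dataset(truth, d, c(0.45, 0.55), 150, seed = 17)
  cfg <- sampler_config(iter = 400, burnin = 200, seed = 23,
                        loglik_draws = 100)
  f1 <- suppressWarnings(fit("ordm", dat, d, cfg, method = "mcmc"))
  f2 <- suppressWarnings(fit("ordm", dat, d, cfg, method = "mcmc"))
  expect_identical(f1$estimates, f2$estimates)
  # every retained draw satisfies the sign constraints (no label
  # switching is possible under the confirmatory design)
  idx <- parameter_index("ordm", d)
  for (ch in f1$draws) {
    psi <- ch[, idx$name, drop = FALSE]
    expect_true(all(psi[, idx$sign == "nonpos"] <= 0))
    expect_true(all(psi[, idx$sign %in% c("pos", "nonneg")] >= 0))
    pi_draws <- ch[, grep("^pi", colnames(ch)), drop = FALSE]
    expect_equal(rowSums(pi_draws), rep(1, nrow(pi_draws)),
                 tolerance = 1e-12)
  }
  expect_equal(dim(f1$pointwise_loglik)[1], 150)
})

test_that("degenerate data (unchosen option) warns but proceeds", {
  d <- tiny_design(K = 1, I = 2, M = 3)
  # option 2 of item 1 never chosen; item 2 fully populated
  X <- cbind(rep(0:1, 25), rep(c(0L, 1L, 2L), length.out = 50))
  expect_warning(fit("ordm", X, d, sampler_config(seed = 2),
                     method = "map"),
                 "item 1: option\\(s\\) 2 never chosen")
})

test_that("LOOIC identities and degenerate-draw behaviour hold", {
  set.seed(6)
  ll <- matrix(rnorm(20 * 50, -2), 20, 50)
  fi <- elpd_loo(ll)
  expect_equal(fi$looic, -2 * fi$elpd, tolerance = 1e-12)
  expect_equal(fi$looic_se, 2 * fi$elpd_se, tolerance = 1e-12)
  # all draws identical per respondent: ELPD is the sum of pointwise
  # values and the SE reflects only between-respondent spread
  ll0 <- matrix(rep(c(-1, -2, -3), each = 40), 3, 40, byrow = TRUE)
  fi0 <- elpd_loo(ll0)
  expect_equal(fi0$elpd, -6, tolerance = 1e-10)
  expect_equal(fi0$elpd_se, sqrt(3 * var(c(-1, -2, -3))),
               tolerance = 1e-10)
})

test_that("PSIS-LOO matches the exact conjugate leave-one-out oracle", {
  # normal mean model with known variance: y ~ N(mu, 1), mu ~ N(0, 10^2)
  set.seed(12)
  y <- c(-0.8, 0.3, 1.2, 0.5, -0.2, 0.9)
  n <- length(y); prior_var <- 100
  post_var <- 1 / (n + 1 / prior_var)
  post_mean <- sum(y) * post_var
  S <- 8000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- t(vapply(y, function(yj) dnorm(yj, mu_draws, 1, log = TRUE),
                 numeric(S)))
  # exact LOO predictive: refit without observation j
  exact <- vapply(seq_len(n), function(j) {
    v <- 1 / (n - 1 + 1 / prior_var)
    m <- sum(y[-j]) * v
    dnorm(y[j], m, sqrt(1 + v), log = TRUE)
  }, 0)
  fi <- elpd_loo(ll)
  expect_equal(fi$elpd, sum(exact), tolerance = 0.02)
  expect_true(all(fi$pareto_k < 0.7))
})
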