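test_that("pseudo/natural transforms are exact inverses", {
  d <- tiny_design(K = 1, I = 1, M = 4)
  p <- dcm_pseudo_params("ordm", d,
                         list(list(intercepts = c(1, 0.5, 0.25) *
                                     c(1, -1, -1),
                                   effects = 1)))
  # cumulative-sum oracle by hand: base 1.0, increments (-0.5, -0.25)
  nat <- pseudo_to_natural(p, d)
  expect_equal(nat$items[[1]]$intercepts, c(1, 0.5, 0.25))
  back <- natural_to_pseudo(nat, d)
  expect_equal(back$items[[1]]$intercepts, c(1, -0.5, -0.25))
  # zeros map to zeros (with zero-effect tolerance at the boundary)
  p0 <- dcm_pseudo_params("ordm", d,
                          list(list(intercepts = c(0, 0, 0), effects = 0)))
  expect_equal(pseudo_to_natural(p0, d)$items[[1]]$intercepts, c(0, 0, 0))
  # round-trip on random valid draws, all models
  for (model in c("nrdm", "ordm", "mordm")) {
    dd <- tiny_design(K = 2, I = 3, M = 4)
    nat <- rand_params(model, dd, seed = 11)
    rt <- pseudo_to_natural(natural_to_pseudo(nat, dd), dd)
    expect_equal(rt, nat, tolerance = 1e-12)
  }
})

test_that("constraint validation reports violations by family", {
  d <- tiny_design(K = 1, I = 1, M = 3)
  bad_int <- dcm_params("ordm", d,
                        list(list(intercepts = c(0.5, 1.0), effects = 1)))
  v <- validate_constraints(bad_int, d)
  expect_false(all(v$pass))
  expect_match(v$constraint[!v$pass], "non-increasing")
  expect_error(natural_to_pseudo(bad_int, d), "constraint violation")
  bad_eff <- dcm_params("ordm", d,
                        list(list(intercepts = c(0.5, 0.2),
                                  effects = -0.2)))
  v2 <- validate_constraints(bad_eff, d)
  expect_match(v2$constraint[!v2$pass], "positive")
  # shipped generating values satisfy all constraints
  ref <- example_design()
  for (model in c("nrdm", "ordm", "mordm"))
    expect_true(all(validate_constraints(example_truth(model),
                                         ref)$pass))
})

test_that("option probabilities match closed forms", {
  d <- tiny_design(K = 1, I = 1, M = 4)
  # null parameters: uniform (the zero-effect boundary is allowed)
  for (model in c("ordm", "nrdm")) {
    p0 <- if (model == "ordm")
      dcm_params(model, d, list(list(intercepts = c(0, 0, 0),
                                     effects = 0)))
    else
      dcm_params(model, d, list(list(intercepts = c(0, 0, 0),
                                     effects = matrix(0, 1, 3))))
    expect_equal(option_probabilities(p0, d, 1, 1), rep(0.25, 4))
  }
  # binary logistic closed form
  d2 <- tiny_design(K = 1, I = 1, M = 2)
  p2 <- dcm_params("ordm", d2, list(list(intercepts = 0, effects = 1)))
  expect_equal(option_probabilities(p2, d2, 1, 1)[2], exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  # hand evaluation of the adjacent-category numerators (1, e, e, 1)
  p3 <- dcm_params("ordm", d,
                   list(list(intercepts = c(1, 0, -1), effects = 0.5)))
  expect_equal(option_probabilities(p3, d, 1, 0),
               c(1, exp(1), exp(1), 1) / (2 + 2 * exp(1)),
               tolerance = 1e-12)
  expect_error(option_probabilities(p3, d, 1, c(1, 0)), "profile length")
})

test_that("class-conditional tables normalize and agree with the kernel", {
  d <- example_design()
  for (model in c("nrdm", "ordm", "mordm")) {
    params <- example_truth(model)
    tab <- class_conditional_table(params, d)
    expect_lt(max(abs(apply(tab, c(1, 2), sum) - 1)), 1e-12)
    # brute-force cross-check on random (item, class) pairs
    set.seed(5)
    for (rep in 1:25) {
      i <- sample(d$I, 1); c <- sample(4, 1)
      expect_equal(as.numeric(tab[i, c, ]),
                   option_probabilities(params, d, i,
                                        d$profile_space$profiles[c, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("ORDM nests in the NRDM and MORDM nests in the ORDM", {
  d <- tiny_design(K = 2, I = 4, M = 4)
  for (seed in 1:5) {
    o <- rand_params("ordm", d, seed)
    # embed: NRDM option-m intercept is the cumulated ORDM intercept,
    # NRDM option-m effect is m * the ORDM effect
    n_items <- lapply(seq_len(d$I), function(i) {
      it <- o$items[[i]]
      list(intercepts = cumsum(it$intercepts),
           effects = outer(unname(it$effects), seq_len(d$M[i] - 1L)))
    })
    n <- dcm_params("nrdm", d, n_items)
    expect_equal(class_conditional_table(n, d),
                 class_conditional_table(o, d), tolerance = 1e-12,
                 ignore_attr = TRUE)
    m <- rand_params("mordm", d, seed + 100)
    # recompose: ORDM intercepts are item + shared option intercepts
    o_items <- lapply(seq_len(d$I), function(i) {
      v <- d$item_set[i]
      list(intercepts = m$items[[i]]$intercept +
             m$shared[[v]]$intercepts,
           effects = m$items[[i]]$effects)
    })
    o2 <- dcm_params("ordm", d, o_items)
    expect_equal(class_conditional_table(o2, d),
                 class_conditional_table(m, d), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("positivity constraints imply stochastic ordering", {
  d <- tiny_design(K = 2, I = 4, M = 5)
  profiles <- d$profile_space$profiles
  for (seed in 1:6) for (model in c("nrdm", "ordm", "mordm")) {
    params <- rand_params(model, d, seed)
    for (i in seq_len(d$I)) {
      q <- d$Q[i, ]
      master <- profiles[apply(profiles, 1, function(p)
        all(p[q == 1] == 1)), , drop = FALSE][1, ]
      non <- profiles[apply(profiles, 1, function(p)
        all(p[q == 1] == 0)), , drop = FALSE][1, ]
      cdf_m <- cumsum(option_probabilities(params, d, i, master))
      cdf_n <- cumsum(option_probabilities(params, d, i, non))
      expect_true(all(cdf_m <= cdf_n + 1e-12))
    }
  }
})

test_that("marginal likelihood matches a full-enumeration oracle", {
  # uniform table: every respondent contributes log(1/M)
  d <- tiny_design(K = 1, I = 1, M = 4)
  p0 <- dcm_params("ordm", d, list(list(intercepts = c(0, 0, 0),
                                        effects = 0)))
  tab <- class_conditional_table(p0, d)
  res <- marginal_log_likelihood(matrix(c(0L, 3L), 2, 1), tab,
                                 c(0.3, 0.7))
  expect_equal(res$pointwise, rep(log(0.25), 2), tolerance = 1e-12)
  # degenerate prevalence: single-class product
  d2 <- tiny_design(K = 1, I = 2, M = 3)
  p <- rand_params("ordm", d2, 3)
  tab2 <- class_conditional_table(p, d2)
  X <- rbind(c(0L, 2L), c(1L, 1L))
  res2 <- marginal_log_likelihood(X, tab2, c(1, 0))
  expect_equal(res2$pointwise,
               log(tab2[1, 1, X[, 1] + 1] * tab2[2, 1, X[, 2] + 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # brute-force oracle: explicit sum over classes, small designs
  for (seed in 1:4) {
    set.seed(seed + 50)
    K <- sample(1:3, 1); I <- sample(K:4, 1)
    dd <- tiny_design(K = K, I = I, M = 3)
    pp <- rand_params("ordm", dd, seed)
    tt <- class_conditional_table(pp, dd)
    set.seed(seed)
    C <- 2^K
    prev <- as.numeric(rmultinom(1, 50, rep(1, C))) / 50
    X <- matrix(sample(0:2, 10 * I, replace = TRUE), 10, I)
    got <- marginal_log_likelihood(X, tt, prev)
    oracle <- vapply(seq_len(10), function(e) {
      s <- 0
      for (c in seq_len(C)) {
        pr <- prev[c]
        for (i in seq_len(I)) pr <- pr * tt[i, c, X[e, i] + 1]
        s <- s + pr
      }
      log(s)
    }, 0)
    expect_equal(got$pointwise, oracle, tolerance = 1e-10)
    expect_equal(got$total, sum(oracle), tolerance = 1e-10)
  }
  expect_error(marginal_log_likelihood(matrix(5L, 1, 1), tab, rep(0.5, 2)),
               "outside 0..3")
})
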