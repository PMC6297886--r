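test_that("profile enumeration uses the fixed reporting order", {
  ps <- enumerate_profiles(2)
  expect_equal(ps$labels, c("(0,0)", "(1,0)", "(0,1)", "(1,1)"))
  expect_equal(enumerate_profiles(1)$profiles, cbind(A1 = 0:1),
               ignore_attr = TRUE)
  # exhaustive-enumeration oracle: 2^K distinct rows, all binary
  for (K in 1:4) {
    ps <- enumerate_profiles(K)
    expect_equal(nrow(ps$profiles), 2^K)
    expect_equal(nrow(unique(ps$profiles)), 2^K)
    expect_true(all(ps$profiles %in% 0:1))
    expect_equal(ps$profiles[1, ], rep(0L, K), ignore_attr = TRUE)
    # grouped by number of possessed attributes
    expect_true(!is.unsorted(rowSums(ps$profiles)))
  }
  expect_error(enumerate_profiles(0), "K must be")
})

test_that("Q-matrix validation catches malformed designs", {
  expect_error(q_matrix(matrix(c(1, 0, 2, 1), 2)), "0 or 1")
  expect_error(q_matrix(rbind(c(1, 0), c(1, 0))), "measured by no item")
  expect_error(q_matrix(rbind(c(0, 0), c(1, 1))), "measure no attribute")
  Q <- example_qmatrix()
  expect_equal(dim(Q), c(8L, 2L))
  expect_equal(unname(colSums(Q)), c(4, 4))
})

test_that("W-matrix groups items by distinct measured attribute sets", {
  W1 <- derive_w_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(W1$entries),
               rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(W1$set_definitions, list(1L, 2L))
  # pattern grouping by hand: rows (1,0) and (1,1) are two sets
  W2 <- derive_w_matrix(rbind(c(1, 0), c(1, 1)))
  expect_equal(ncol(W2$entries), 2L)
  expect_equal(W2$set_definitions, list(1L, 1:2))
  # reference design: two sets of four items
  W3 <- derive_w_matrix(example_qmatrix())
  expect_equal(unname(colSums(W3$entries)), c(4, 4))
  # every row has exactly one 1
  expect_true(all(rowSums(W3$entries) == 1))
})

test_that("W-matrix derivation is stable under row permutation", {
  set.seed(42)
  Q <- example_qmatrix()
  perm <- sample(nrow(Q))
  Wp <- derive_w_matrix(q_matrix(unclass(Q)[perm, ]))
  W <- derive_w_matrix(Q)
  norm_sets <- function(w) lapply(w$set_definitions, sort)
  expect_setequal(norm_sets(Wp), norm_sets(W))
  expect_true(all(rowSums(Wp$entries) == 1))
})

test_that("effect vectors gate unmeasured attributes to zero", {
  expect_equal(unname(effect_vector(c(0, 0), c(1, 1))), c(0, 0, 0))
  expect_equal(unname(effect_vector(c(1, 1), c(1, 0))), c(1, 0, 0))
  expect_equal(unname(effect_vector(c(1, 1), c(1, 1))), c(1, 1, 1))
  expect_error(effect_vector(c(1, 0, 1), c(1, 1)), "lengths differ")
  # gating property: h(alpha, q) == h(alpha & q, q), exhaustively for K <= 4
  for (K in 2:4) {
    profs <- enumerate_profiles(K)$profiles
    set.seed(K)
    for (rep in 1:5) {
      q <- rbinom(K, 1, 0.6); if (all(q == 0)) q[1] <- 1L
      for (c in seq_len(nrow(profs))) {
        p <- profs[c, ]
        expect_identical(effect_vector(p, q), effect_vector(p * q, q))
      }
    }
  }
})

test_that("parameter counts match the structural formulas", {
  d <- example_design()
  expect_identical(count_item_parameters("nrdm", d), 48L)
  expect_identical(count_item_parameters("ordm", d), 32L)
  expect_identical(count_item_parameters("mordm", d), 22L)
  expect_identical(count_item_parameters("ordm", example_design(7)), 56L)
  # trivial binary item: NRDM and ORDM coincide
  d1 <- dcm_design(q_matrix(matrix(1, 1, 1)), M = 2)
  expect_identical(count_item_parameters("nrdm", d1), 2L)
  expect_identical(count_item_parameters("ordm", d1), 2L)
  # structural enumeration: 1 item, q = (1,1), M = 3, full expansion
  d2 <- dcm_design(q_matrix(matrix(1, 1, 2)), M = 3)
  expect_identical(count_item_parameters("ordm", d2), 5L)
  expect_error(dcm_design(example_qmatrix(), M = 1), "at least 2")
})

test_that("count invariants: ORDM <= NRDM with equality iff binary", {
  # closed-formula oracle recomputed independently of parameter_index()
  formula_count <- function(model, design) {
    ne <- lengths(design$active)
    switch(model,
      nrdm = sum((design$M - 1) * (1 + ne)),
      ordm = sum((design$M - 1) + ne),
      mordm = sum(1 + ne) +
        sum(vapply(seq_along(design$W$set_definitions), function(v)
          ordinalDCM:::shared_option_count(design, v) - 1L, 1L)))
  }
  set.seed(9)
  for (rep in 1:8) {
    K <- sample(1:3, 1); I <- sample(2:6, 1); M <- sample(2:5, 1)
    Q <- matrix(0L, I, K)
    Q[cbind(seq_len(I), rep_len(seq_len(K), I))] <- 1L
    extra <- matrix(rbinom(I * K, 1, 0.3), I, K)
    d <- dcm_design(q_matrix(pmin(Q + extra, 1L)), M = M)
    for (model in c("nrdm", "ordm", "mordm"))
      expect_identical(count_item_parameters(model, d),
                       as.integer(formula_count(model, d)))
    expect_lte(count_item_parameters("ordm", d),
               count_item_parameters("nrdm", d))
    if (M == 2)
      expect_identical(count_item_parameters("ordm", d),
                       count_item_parameters("nrdm", d))
    else
      expect_lt(count_item_parameters("ordm", d),
                count_item_parameters("nrdm", d))
  }
})

test_that("parameter index names are unique and counts are item-additive", {
  d <- example_design()
  for (model in c("nrdm", "ordm")) {
    idx <- parameter_index(model, d)
    expect_false(anyDuplicated(idx$name) > 0)
    per_item <- table(idx$item)
    expect_equal(sum(per_item), count_item_parameters(model, d))
  }
})
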