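# Shared fixtures: small designs and random valid parameter draws used by
# the property-style tests.

tiny_design <- function(K = 1L, I = 2L, M = 3L) {
  Q <- matrix(0L, I, K)
  Q[cbind(seq_len(I), rep_len(seq_len(K), I))] <- 1L
  dcm_design(q_matrix(Q), M = M)
}

# Random parameters satisfying all model constraints.
rand_params <- function(model, design, seed = 1L) {
  set.seed(seed)
  items <- lapply(seq_len(design$I), function(i) {
    Mi <- design$M[i]
    nact <- length(design$active[[i]])
    labs <- design$term_labels[design$active[[i]]]
    if (model == "nrdm") {
      list(intercepts = c(rnorm(1), -abs(rnorm(Mi - 2L, 1, 0.5))),
           effects = matrix(abs(rnorm(nact * (Mi - 1L), 1, 0.5)) + 0.05,
                            nact, Mi - 1L, dimnames = list(labs, NULL)))
    } else if (model == "ordm") {
      list(intercepts = c(rnorm(1), -abs(rnorm(Mi - 2L, 1, 0.5))),
           effects = setNames(abs(rnorm(nact, 1, 0.5)) + 0.05, labs))
    } else {
      list(intercept = rnorm(1),
           effects = setNames(abs(rnorm(nact, 1, 0.5)) + 0.05, labs))
    }
  })
  shared <- if (model == "mordm")
    lapply(seq_along(design$W$set_definitions), function(v) {
      Mv <- ordinalDCM:::shared_option_count(design, v)
      list(intercepts = c(rnorm(1), -abs(rnorm(Mv - 2L, 1, 0.5))))
    })
  pseudo_to_natural(dcm_pseudo_params(model, design, items, shared),
                    design)
}
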