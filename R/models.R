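# Numerically stable helpers; values near +/-18 in real estimates overflow
# a naive exp() once cumulated, so everything is normalized in log space.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

row_log_sum_exp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# Linear predictors for options 1..M-1 of one item under one profile;
# option 0 always has predictor 0.
item_predictors <- function(params, design, item, profile) {
  model <- params$model
  it <- params$items[[item]]
  h <- effect_vector(profile, design$Q[item, ], design$max_order)
  hact <- h[design$active[[item]]]
  if (model == "nrdm") {
    it$intercepts + as.numeric(crossprod(it$effects, hact))
  } else if (model == "ordm") {
    cumsum(it$intercepts + sum(it$effects * hact))
  } else {
    v <- design$item_set[item]
    cumsum(it$intercept + params$shared[[v]]$intercepts +
             sum(it$effects * hact))
  }
}

#' Response option probabilities for one item and profile
#'
#' Evaluates the model's option-probability kernel.  The NRDM is a softmax
#' over per-option predictors `l0[i, m] + lambda[i, m]' h(alpha, q_i)`; the
#' ORDM uses the adjacent-category cumulative predictor
#' `sum_{j<=m} (l0[i, j] + lambda[i]' h)`; the MORDM replaces `l0[i, j]`
#' with `l0[i] + l0s[v(i), j]`.  Option 0 always has predictor 0.
#'
#' @param params natural-form [dcm_params()].
#' @param design the matching [dcm_design()].
#' @param item item index.
#' @param profile binary attribute profile of length `K`.
#' @return probability vector of length `M_i` (sums to 1).
#' @export
option_probabilities <- function(params, design, item, profile) {
  if (length(profile) != design$K)
    stop("invalid design: profile length ", length(profile),
         " does not match K = ", design$K, call. = FALSE)
  softmax(c(0, item_predictors(params, design, item, profile)))
}

#' Class-conditional response probability table
#'
#' Evaluates [option_probabilities()] for every item and latent class:
#' entry `[i, c, m]` is `P(X_i = m - 1 | alpha_c)`.  For designs with
#' unequal option counts the third dimension is `max(M)`; cells beyond an
#' item's `M_i` are 0.
#'
#' @inheritParams option_probabilities
#' @return numeric array `items x classes x max(M)` of class
#'   `class_conditional_table`, with the per-item option counts in
#'   `attr(, "M")`.
#' @export
class_conditional_table <- function(params, design) {
  C <- nrow(design$profile_space$profiles)
  maxM <- max(design$M)
  tab <- array(0, dim = c(design$I, C, maxM),
               dimnames = list(rownames(design$Q),
                               design$profile_space$labels,
                               paste0("m", seq_len(maxM) - 1L)))
  for (i in seq_len(design$I))
    for (c in seq_len(C))
      tab[i, c, seq_len(design$M[i])] <-
        option_probabilities(params, design, i,
                             design$profile_space$profiles[c, ])
  attr(tab, "M") <- design$M
  class(tab) <- c("class_conditional_table", class(tab))
  tab
}

# N x C matrix of per-respondent, per-class log-likelihoods.
class_loglik_matrix <- function(responses, table) {
  M <- attr(table, "M")
  X <- as_response_matrix(responses)
  I <- dim(table)[1L]; C <- dim(table)[2L]
  if (ncol(X) != I)
    stop("data validation: responses have ", ncol(X), " items, table has ",
         I, call. = FALSE)
  L <- matrix(0, nrow(X), C)
  for (i in seq_len(I)) {
    xi <- X[, i]
    bad <- which(is.na(xi) | xi < 0 | xi >= M[i] | xi != round(xi))
    if (length(bad))
      stop("data validation: respondent ", bad[1L], ", item ", i,
           ": response code ", xi[bad[1L]], " outside 0..", M[i] - 1L,
           call. = FALSE)
    logp <- log(matrix(table[i, , ], C, dim(table)[3L]))
    L <- L + t(logp)[xi + 1L, , drop = FALSE]
  }
  L
}

as_response_matrix <- function(responses) {
  if (inherits(responses, "response_data")) responses$responses
  else as.matrix(responses)
}

#' Marginal log-likelihood of a latent class model
#'
#' For respondent `e`, `log sum_c pi_c prod_i P(X_ei | alpha_c)`, computed
#' stably in log space.  The pointwise vector is returned for use in
#' LOO-based model comparison.
#'
#' @param responses respondent-by-item matrix of codes `0..M_i-1` (or a
#'   `response_data` object).
#' @param table a [class_conditional_table()].
#' @param prevalence probability vector over latent classes (sums to 1).
#' @return list with `total` (scalar log-likelihood) and `pointwise`
#'   (per-respondent log-likelihood vector).
#' @export
marginal_log_likelihood <- function(responses, table, prevalence) {
  C <- dim(table)[2L]
  prevalence <- validate_prevalence(prevalence, C)
  L <- class_loglik_matrix(responses, table)
  pointwise <- row_log_sum_exp(sweep(L, 2L, log(prevalence), `+`))
  list(total = sum(pointwise), pointwise = pointwise)
}

validate_prevalence <- function(prevalence, C) {
  prevalence <- as.numeric(prevalence)
  if (length(prevalence) != C)
    stop("prevalence must have one entry per latent class (", C, ")",
         call. = FALSE)
  if (any(prevalence < 0))
    stop("prevalence entries must be >= 0", call. = FALSE)
  if (abs(sum(prevalence) - 1) > 1e-8)
    stop("prevalence must sum to 1 (got ", format(sum(prevalence)), ")",
         call. = FALSE)
  prevalence
}
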