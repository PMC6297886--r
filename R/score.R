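#' Classify respondents into attribute profiles
#'
#' Posterior class probability of respondent `e` is proportional to
#' `pi_c * prod_i P(X_ei | alpha_c)`.  From it: the MAP profile (ties
#' broken toward the lowest class index in the fixed profile order), the
#' per-attribute marginal possession probability (the "continuous score",
#' the sum of posterior probabilities of classes possessing the
#' attribute), and a binary attribute call thresholding the marginal.
#'
#' @param responses respondent-by-item code matrix or `response_data`.
#' @param params natural-form [dcm_params()] (typically point estimates).
#' @param prevalence profile prevalence vector.
#' @param design the matching [dcm_design()].
#' @param threshold marginal-probability cutoff for the binary attribute
#'   call (default 0.5).
#' @return a `classification` object: `posterior` (N x C), `map_class`,
#'   `map_profile` (labels), `marginals` (N x K), `calls` (N x K binary).
#' @export
classify <- function(responses, params, prevalence, design,
                     threshold = 0.5) {
  tab <- class_conditional_table(params, design)
  C <- dim(tab)[2L]
  prevalence <- validate_prevalence(prevalence, C)
  L <- class_loglik_matrix(responses, tab)
  Lw <- sweep(L, 2L, log(prevalence), `+`)
  post <- exp(Lw - row_log_sum_exp(Lw))
  if (any(!is.finite(post)))
    stop("internal error: non-finite posterior probabilities", call. = FALSE)
  map_class <- max.col(post, ties.method = "first")
  profiles <- design$profile_space$profiles
  marginals <- post %*% profiles
  calls <- (marginals >= threshold) * 1L
  colnames(marginals) <- colnames(calls) <- colnames(profiles)
  structure(list(posterior = post, map_class = map_class,
                 map_profile = design$profile_space$labels[map_class],
                 marginals = marginals, calls = calls,
                 threshold = threshold,
                 profile_space = design$profile_space),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("Classification of", nrow(x$posterior), "respondents into",
      ncol(x$posterior), "profiles\n")
  print(table(x$map_profile))
  invisible(x)
}

#' Cohen's kappa from a contingency table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement the diagonal
#' proportion and expected agreement the product of the marginals.
#'
#' @param tab square crosstab matrix (counts).
#' @return scalar kappa in `[-1, 1]`.
#' @export
kappa_from_table <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Agreement between two classification vectors
#'
#' Cross-tabulates two equal-length categorical vectors (binary attribute
#' calls or profile labels), and reports percent agreement and Cohen's
#' kappa.
#'
#' @param a,b equal-length vectors (coerced to factors over the union of
#'   observed levels, or over `levels` when given).
#' @param levels optional explicit level set (e.g. all profile labels,
#'   so empty rows/columns are kept).
#' @return an `agreement_report`: `crosstab`, `n`, `agreement` (count),
#'   `percent_agreement`, `kappa`.
#' @export
agreement <- function(a, b, levels = NULL) {
  if (length(a) != length(b))
    stop("classification vectors differ in length", call. = FALSE)
  levels <- levels %||% sort(unique(c(a, b)))
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  structure(list(crosstab = unclass(as.matrix(tab)), n = length(a),
                 agreement = sum(diag(tab)),
                 percent_agreement = 100 * sum(diag(tab)) / length(a),
                 kappa = kappa_from_table(tab)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement: %d/%d (%.1f%%), Cohen's kappa = %.2f\n",
              x$agreement, x$n, x$percent_agreement, x$kappa))
  print(x$crosstab)
  invisible(x)
}

#' Root-mean-square deviation between two score vectors
#'
#' @param a,b equal-length numeric vectors (e.g. continuous attribute
#'   scores under two models).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmsd_scores <- function(a, b) {
  if (length(a) == 0L) stop("empty input", call. = FALSE)
  if (length(a) != length(b))
    stop("score vectors differ in length", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Response option curves for one item
#'
#' Tabulates `P(option | profile)` for every profile and option of an
#' item — the tabular form of a response-option-curve plot.  The attached
#' `crossover_option` attribute gives, for the comparison between the
#' profile possessing all measured attributes and the one possessing none,
#' the minimum option from which the masters' probability exceeds the
#' non-masters'.
#'
#' @param params natural-form [dcm_params()].
#' @param design the matching [dcm_design()].
#' @param item item index.
#' @return long data frame (`profile`, `option`, `probability`) with
#'   attribute `crossover_option`.
#' @export
response_option_curves <- function(params, design, item) {
  profiles <- design$profile_space$profiles
  Mi <- design$M[item]
  probs <- t(vapply(seq_len(nrow(profiles)), function(c)
    option_probabilities(params, design, item, profiles[c, ]),
    numeric(Mi)))
  out <- data.frame(
    profile = rep(design$profile_space$labels, each = Mi),
    option = rep(seq_len(Mi) - 1L, times = nrow(profiles)),
    probability = as.vector(t(probs)))
  q <- design$Q[item, ]
  master <- which(apply(profiles, 1L, function(p) all(p[q == 1] == 1)))[1L]
  nonmaster <- which(apply(profiles, 1L, function(p) all(p[q == 1] == 0)))[1L]
  higher <- which(probs[master, ] > probs[nonmaster, ]) - 1L
  attr(out, "crossover_option") <- if (length(higher)) min(higher) else NA
  out
}
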