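# Deterministic sub-seed derivation: one master seed, independent streams
# per stage, all below 2^31.  Linear congruential mixing is enough here —
# the streams only need to be decoupled, not cryptographic.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + as.double(stream) * 2654435) %% 2147483647)
}

#' Draw latent class memberships
#'
#' I.i.d. multinomial draws of attribute-profile indices from a prevalence
#' vector, reproducible from a seed.
#'
#' @param prevalence probability vector over latent classes (must sum to 1
#'   within 1e-8).
#' @param N number of respondents.
#' @param seed integer seed.
#' @return integer vector of class indices (1-based, profile-space order).
#' @export
draw_profiles <- function(prevalence, N, seed) {
  prevalence <- validate_prevalence(prevalence, length(prevalence))
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  set.seed(seed)
  sample.int(length(prevalence), size = N, replace = TRUE,
             prob = prevalence)
}

#' Draw ordinal item responses
#'
#' Given class memberships and a class-conditional probability table, draws
#' each response from the categorical distribution of its (item, class)
#' cell.
#'
#' @param table a [class_conditional_table()].
#' @param profiles integer class indices (from [draw_profiles()]).
#' @param seed integer seed (independent of the profile-draw seed).
#' @return a `response_data` object: `responses` (N x I integer matrix of
#'   codes `0..M_i-1`), `M`, `item_ids`, `true_class`, and generation
#'   metadata in `meta`.
#' @export
draw_responses <- function(table, profiles, seed) {
  C <- dim(table)[2L]
  if (any(profiles < 1 | profiles > C))
    stop("class indices outside 1..", C, call. = FALSE)
  M <- attr(table, "M")
  I <- dim(table)[1L]
  N <- length(profiles)
  set.seed(seed)
  X <- matrix(0L, N, I, dimnames = list(NULL, dimnames(table)[[1L]]))
  for (i in seq_len(I)) {
    P <- matrix(table[i, , seq_len(M[i])], C, M[i])
    cp <- t(apply(P, 1L, cumsum))[profiles, , drop = FALSE]
    u <- stats::runif(N)
    X[, i] <- as.integer(rowSums(u > cp))
  }
  structure(list(responses = X, M = M, item_ids = colnames(X),
                 true_class = profiles,
                 meta = list(seed = seed)),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat("Response data:", nrow(x$responses), "respondents x",
      ncol(x$responses), "items; options per item:",
      paste(x$M, collapse = " "), "\n")
  if (!is.null(x$true_class)) cat("(true latent classes attached)\n")
  invisible(x)
}

#' Generate a synthetic dataset from a model
#'
#' Composes [draw_profiles()] and [draw_responses()] with independent,
#' seed-derived streams (so changing the item side never perturbs the
#' profile assignment), and optionally writes the responses CSV, the truth
#' sidecar and the exact generating parameter file.
#'
#' @param params natural-form generating [dcm_params()].
#' @param design the matching [dcm_design()].
#' @param prevalence generating profile prevalence.
#' @param N number of respondents (>= 1).
#' @param seed master seed.
#' @param out_dir optional directory; when given, writes `responses.csv`,
#'   `truth.csv` and `params.json` there.
#' @return a `response_data` object with `true_class` and metadata.
#' @export
generate_dataset <- function(params, design, prevalence, N, seed,
                             out_dir = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("config error: N must be a positive integer", call. = FALSE)
  prevalence <- validate_prevalence(prevalence,
                                    nrow(design$profile_space$profiles))
  tab <- class_conditional_table(params, design)
  profiles <- draw_profiles(prevalence, N, derive_seed(seed, 1L))
  dat <- draw_responses(tab, profiles, derive_seed(seed, 2L))
  dat$meta <- list(model = params$model, seed = seed, N = N,
                   prevalence = prevalence)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_responses(dat, file.path(out_dir, "responses.csv"))
    truth <- data.frame(respondent = seq_len(N), class = profiles,
                        design$profile_space$profiles[profiles, ,
                                                      drop = FALSE])
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    write_params(params, design, file.path(out_dir, "params.json"))
  }
  dat
}
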