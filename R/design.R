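#' Construct and validate a Q-matrix
#'
#' The Q-matrix is the item-by-attribute incidence matrix of a diagnostic
#' classification model: `q[i, k] = 1` when item `i` measures attribute `k`.
#' Every entry must be 0 or 1, every item must measure at least one
#' attribute, and every attribute must be measured by at least one item.
#'
#' @param x a binary matrix or data frame (items in rows, attributes in
#'   columns).
#' @param item_ids,attribute_ids optional character labels; defaults are
#'   taken from dimnames or generated (`Item1..`, `A1..`).
#' @return an object of class `qmatrix`: the validated integer matrix with
#'   row/column names.
#' @export
q_matrix <- function(x, item_ids = NULL, attribute_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) storage.mode(x) <- "numeric"
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("invalid design: Q-matrix entries must all be 0 or 1", call. = FALSE)
  storage.mode(x) <- "integer"
  if (any(rowSums(x) < 1))
    stop("invalid design: Q-matrix row(s) ",
         paste(which(rowSums(x) < 1), collapse = ", "),
         " measure no attribute", call. = FALSE)
  if (any(colSums(x) < 1))
    stop("invalid design: Q-matrix column(s) ",
         paste(which(colSums(x) < 1), collapse = ", "),
         " are measured by no item", call. = FALSE)
  rownames(x) <- item_ids %||% rownames(x) %||% paste0("Item", seq_len(nrow(x)))
  colnames(x) <- attribute_ids %||% colnames(x) %||% paste0("A", seq_len(ncol(x)))
  structure(x, class = c("qmatrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the attribute profile space
#'
#' Lists all `2^K` binary attribute profiles in a fixed order: grouped by
#' the number of possessed attributes, ties broken by attribute index
#' (lower-indexed attributes first).  For `K = 2` this gives
#' `(0,0), (1,0), (0,1), (1,1)` — the conventional reporting order.
#'
#' @param K number of attributes (>= 1).
#' @return a `profile_space` object: list with `K`, `profiles`
#'   (`2^K x K` integer matrix, one profile per row) and `labels`
#'   (e.g. `"(1,0)"`).
#' @export
enumerate_profiles <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1 || K != round(K))
    stop("invalid design: K must be a single integer >= 1", call. = FALSE)
  K <- as.integer(K)
  grid <- as.matrix(rev(expand.grid(rev(replicate(K, 0:1, simplify = FALSE)))))
  # order: by count of possessed attributes, then attribute 1 as the most
  # significant bit descending (so (1,0) precedes (0,1))
  msb <- as.vector(grid %*% 2^((K - 1):0))
  ord <- order(rowSums(grid), -msb)
  profiles <- grid[ord, , drop = FALSE]
  storage.mode(profiles) <- "integer"
  dimnames(profiles) <- list(NULL, paste0("A", seq_len(K)))
  labels <- apply(profiles, 1L, function(p) paste0("(", paste(p, collapse = ","), ")"))
  structure(list(K = K, profiles = profiles, labels = labels),
            class = "profile_space")
}

#' @export
print.profile_space <- function(x, ...) {
  cat("Attribute profile space: K =", x$K, "(", nrow(x$profiles), "classes )\n")
  cat(paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Derive the W-matrix from a Q-matrix
#'
#' The W-matrix is the item-by-attribute-set incidence matrix used by the
#' MORDM to share response option intercepts: `w[i, v] = 1` when item `i`
#' measures attribute set `v`.  Columns are the distinct Q-matrix row
#' patterns in order of first appearance, so each row has exactly one 1.
#'
#' @param Q a [q_matrix()] (or coercible matrix).
#' @return a `wmatrix` object: list with `entries` (items x sets binary
#'   matrix), `set_definitions` (list of attribute-index vectors) and
#'   `set_labels`.
#' @export
derive_w_matrix <- function(Q) {
  Q <- as_qmatrix(Q)
  keys <- apply(Q, 1L, paste, collapse = "")
  uk <- unique(keys)
  entries <- matrix(0L, nrow(Q), length(uk),
                    dimnames = list(rownames(Q), paste0("Set", seq_along(uk))))
  entries[cbind(seq_len(nrow(Q)), match(keys, uk))] <- 1L
  set_definitions <- lapply(uk, function(k)
    which(as.integer(strsplit(k, "")[[1]]) == 1L))
  set_labels <- vapply(set_definitions, function(s)
    paste0("{", paste(colnames(Q)[s], collapse = ","), "}"), "")
  colnames(entries) <- set_labels
  structure(list(entries = entries, set_definitions = set_definitions,
                 set_labels = set_labels),
            class = "wmatrix")
}

as_qmatrix <- function(Q) {
  if (inherits(Q, "qmatrix")) Q else q_matrix(Q)
}

#' @export
print.wmatrix <- function(x, ...) {
  cat("W-matrix:", nrow(x$entries), "items x", ncol(x$entries),
      "attribute sets\n")
  print(x$entries)
  invisible(x)
}

# All effect terms (attribute subsets) for K attributes up to max_order:
# mains by attribute index, then interactions of increasing order, each
# order in lexicographic subset order.  Returns a list of integer vectors.
effect_terms <- function(K, max_order = K) {
  stopifnot(max_order >= 1, max_order <= K)
  out <- list()
  for (ord in seq_len(max_order)) {
    cmb <- utils::combn(K, ord, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

term_label <- function(term) {
  if (length(term) == 1L) paste0("a", term)
  else paste0("a", paste(term, collapse = "a"))
}

#' Effect (attribute interaction) vector of a profile for one item
#'
#' Computes the vector `h(alpha, q)` multiplying the item's main-effect and
#' interaction coefficients in the linear predictor: for each attribute
#' subset `S` (mains first, then interactions up to `max_order` in
#' lexicographic order), the entry is `prod_{k in S} alpha_k * q_k`.
#' Attributes the item does not measure are gated to zero.
#'
#' @param profile binary attribute profile (length `K`).
#' @param q_row binary Q-matrix row for the item (length `K`).
#' @param max_order highest interaction order retained (default `K`, the
#'   full LCDM-style expansion).
#' @return numeric vector over all `sum(choose(K, 1:max_order))` terms,
#'   named by term.
#' @export
effect_vector <- function(profile, q_row, max_order = length(q_row)) {
  if (length(profile) != length(q_row))
    stop("invalid design: profile and q_row lengths differ", call. = FALSE)
  terms <- effect_terms(length(q_row), max_order)
  g <- as.numeric(profile) * as.numeric(q_row)
  out <- vapply(terms, function(s) prod(g[s]), 0)
  names(out) <- vapply(terms, term_label, "")
  out
}

# Indices (into effect_terms(K, max_order)) of the terms an item with row
# q_row can carry: subsets fully contained in the measured attributes.
active_terms <- function(q_row, max_order = length(q_row)) {
  terms <- effect_terms(length(q_row), max_order)
  meas <- which(q_row == 1L)
  which(vapply(terms, function(s) all(s %in% meas), TRUE))
}

#' Bundle a measurement design
#'
#' Collects everything the probability kernels need: the Q-matrix, the
#' derived W-matrix, the profile space, per-item option counts and the
#' per-item active effect terms.
#'
#' @param Q a [q_matrix()] or coercible matrix.
#' @param M per-item number of response options (scalar recycled, or one
#'   integer per item; each >= 2).
#' @param max_order highest interaction order (default `K`).
#' @return a `dcm_design` object.
#' @export
dcm_design <- function(Q, M, max_order = ncol(Q)) {
  Q <- as_qmatrix(Q)
  I <- nrow(Q); K <- ncol(Q)
  M <- as.integer(rep_len(M, I))
  if (any(M < 2))
    stop("invalid design: every item needs at least 2 response options",
         call. = FALSE)
  if (max_order < 1 || max_order > K)
    stop("invalid design: max_order must be in 1..K", call. = FALSE)
  W <- derive_w_matrix(Q)
  terms <- effect_terms(K, max_order)
  structure(list(
    Q = Q, W = W, K = K, I = I, M = M, max_order = as.integer(max_order),
    profile_space = enumerate_profiles(K),
    terms = terms,
    term_labels = vapply(terms, term_label, ""),
    active = lapply(seq_len(I), function(i) active_terms(Q[i, ], max_order)),
    item_set = apply(W$entries, 1L, which.max)
  ), class = "dcm_design")
}

#' @export
print.dcm_design <- function(x, ...) {
  cat("DCM design:", x$I, "items,", x$K, "attributes,",
      nrow(x$profile_space$profiles), "latent classes\n")
  cat("Options per item:", paste(x$M, collapse = " "), "\n")
  cat("Attribute sets:", paste(x$W$set_labels, collapse = " "), "\n")
  invisible(x)
}

#' Index of free item parameters
#'
#' Enumerates every free item parameter of a model on a design, in the
#' pseudo-parameterization used for estimation: per family a base value
#' (option 1) plus sign-constrained increments for higher options.
#' Intercept increments are constrained `<= 0`; effect bases and increments
#' `>= 0` (strictly positive bases), which enforces the ordinal constraints
#' by construction.
#'
#' @param model one of `"nrdm"`, `"ordm"`, `"mordm"`.
#' @param design a [dcm_design()].
#' @return data frame with one row per free parameter: `name`, `item`
#'   (`NA` for MORDM shared-set parameters), `set`, `family`
#'   (`"intercept"`/`"effect"`), `term`, `m` (option, `NA` when the
#'   parameter is not option-specific), `role` (`"base"`/`"increment"`),
#'   `sign` (`"free"`, `"nonpos"`, `"pos"`, `"nonneg"`).
#' @export
parameter_index <- function(model, design) {
  model <- match.arg(model, c("nrdm", "ordm", "mordm"))
  stopifnot(inherits(design, "dcm_design"))
  rows <- list()
  add <- function(name, item, set, family, term, m, role, sign) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, item = item, set = set, family = family, term = term,
      m = m, role = role, sign = sign, stringsAsFactors = FALSE)
  }
  for (i in seq_len(design$I)) {
    Mi <- design$M[i]
    acts <- design$active[[i]]
    if (model == "nrdm") {
      add(sprintf("l0_i%d_m1", i), i, NA, "intercept", NA, 1L, "base", "free")
      for (m in seq_len(Mi - 1L)[-1L])
        add(sprintf("l0inc_i%d_m%d", i, m), i, NA, "intercept", NA, m,
            "increment", "nonpos")
      for (t in acts) {
        lab <- design$term_labels[t]
        add(sprintf("le_i%d_%s_m1", i, lab), i, NA, "effect", lab, 1L,
            "base", "pos")
        for (m in seq_len(Mi - 1L)[-1L])
          add(sprintf("leinc_i%d_%s_m%d", i, lab, m), i, NA, "effect", lab,
              m, "increment", "nonneg")
      }
    } else if (model == "ordm") {
      add(sprintf("l0_i%d_m1", i), i, NA, "intercept", NA, 1L, "base", "free")
      for (m in seq_len(Mi - 1L)[-1L])
        add(sprintf("l0inc_i%d_m%d", i, m), i, NA, "intercept", NA, m,
            "increment", "nonpos")
      for (t in acts)
        add(sprintf("le_i%d_%s", i, design$term_labels[t]), i, NA, "effect",
            design$term_labels[t], NA, "base", "pos")
    } else { # mordm: item-general intercept + effects; shared below
      add(sprintf("l0_i%d", i), i, NA, "intercept", NA, NA, "base", "free")
      for (t in acts)
        add(sprintf("le_i%d_%s", i, design$term_labels[t]), i, NA, "effect",
            design$term_labels[t], NA, "base", "pos")
    }
  }
  if (model == "mordm") {
    for (v in seq_along(design$W$set_definitions)) {
      Mv <- shared_option_count(design, v)
      add(sprintf("l0s_v%d_m1", v), NA, v, "intercept", NA, 1L, "base", "free")
      for (m in seq_len(Mv - 1L)[-1L])
        add(sprintf("l0sinc_v%d_m%d", v, m), NA, v, "intercept", NA, m,
            "increment", "nonpos")
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$name))
  rownames(out) <- out$name
  out
}

# Shared option count of attribute set v: the common M of its items.
shared_option_count <- function(design, v) {
  items <- which(design$item_set == v)
  Ms <- unique(design$M[items])
  if (length(Ms) != 1L)
    stop("invalid design: items sharing attribute set ",
         design$W$set_labels[v], " have differing option counts (",
         paste(Ms, collapse = ", "), "); the MORDM shares option ",
         "intercepts within a set", call. = FALSE)
  Ms
}

#' Count free item parameters of a model on a design
#'
#' Structural parameter count: the NRDM carries an intercept and a full
#' effect vector per non-baseline option of every item; the ORDM one
#' intercept per non-baseline option plus a single effect vector per item;
#' the MORDM one item-general intercept and effect vector per item plus one
#' set of shared option intercepts per attribute set.
#'
#' @param model `"nrdm"`, `"ordm"` or `"mordm"`.
#' @param Q Q-matrix (or a [dcm_design()], in which case `options` and
#'   `max_order` are ignored).
#' @param options per-item option counts `M_i` (scalar or vector).
#' @param max_order highest interaction order (default `K`).
#' @return integer count of free item parameters.
#' @export
count_item_parameters <- function(model, Q, options = NULL,
                                  max_order = NULL) {
  design <- if (inherits(Q, "dcm_design")) Q else {
    Qm <- as_qmatrix(Q)
    dcm_design(Qm, options, max_order %||% ncol(Qm))
  }
  nrow(parameter_index(model, design))
}
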