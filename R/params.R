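#' Item parameter containers
#'
#' Item parameters exist in two equivalent forms.  The *natural* form holds
#' the per-option values entering the linear predictors: per-option
#' intercepts `l0[i, m]` and, for the NRDM, per-option effect vectors; the
#' ORDM/MORDM carry a single positive effect vector per item, and the MORDM
#' decomposes intercepts into an item-general `l0[i]` plus option
#' intercepts shared within an attribute set.  The *pseudo* form stores,
#' for each option-indexed family, the option-1 base followed by
#' sign-constrained increments (intercept increments `<= 0`, effect
#' increments `>= 0`), so the ordinal constraints hold by construction once
#' the increments are cumulated.
#'
#' `dcm_params()` builds a natural-form object; `dcm_pseudo_params()` a
#' pseudo-form object.  Both validate shapes against the design.
#'
#' @param model `"nrdm"`, `"ordm"` or `"mordm"`.
#' @param design a [dcm_design()].
#' @param items list with one element per item.  For NRDM:
#'   `list(intercepts = <numeric M-1>, effects = <terms x (M-1) matrix>)`;
#'   for ORDM: `list(intercepts = <numeric M-1>, effects = <named numeric>)`;
#'   for MORDM: `list(intercept = <scalar>, effects = <named numeric>)`.
#' @param shared MORDM only: list per attribute set,
#'   `list(intercepts = <numeric M_v - 1>)`.
#' @return object of class `dcm_params` (natural) or `dcm_pseudo_params`.
#' @name dcm_params
NULL

#' @rdname dcm_params
#' @export
dcm_params <- function(model, design, items, shared = NULL) {
  new_param_obj(model, design, items, shared, pseudo = FALSE)
}

#' @rdname dcm_params
#' @export
dcm_pseudo_params <- function(model, design, items, shared = NULL) {
  new_param_obj(model, design, items, shared, pseudo = TRUE)
}

new_param_obj <- function(model, design, items, shared, pseudo) {
  model <- match.arg(model, c("nrdm", "ordm", "mordm"))
  stopifnot(inherits(design, "dcm_design"))
  if (length(items) != design$I)
    stop("params must have one item block per design item", call. = FALSE)
  items <- lapply(seq_len(design$I), function(i) {
    it <- items[[i]]
    Mi <- design$M[i]
    nact <- length(design$active[[i]])
    labs <- design$term_labels[design$active[[i]]]
    if (model == "mordm") {
      stopifnot(length(it$intercept) == 1L)
      it$effects <- named_vec(it$effects, labs)
    } else {
      if (length(it$intercepts) != Mi - 1L)
        stop("item ", i, ": expected ", Mi - 1L, " intercept values",
             call. = FALSE)
      if (model == "nrdm") {
        eff <- as.matrix(it$effects)
        if (nrow(eff) != nact || ncol(eff) != Mi - 1L)
          stop("item ", i, ": NRDM effects must be ", nact, " x ", Mi - 1L,
               call. = FALSE)
        rownames(eff) <- labs
        it$effects <- eff
      } else {
        it$effects <- named_vec(it$effects, labs)
      }
    }
    it
  })
  if (model == "mordm") {
    V <- length(design$W$set_definitions)
    if (is.null(shared) || length(shared) != V)
      stop("MORDM params need one shared block per attribute set",
           call. = FALSE)
    shared <- lapply(seq_len(V), function(v) {
      Mv <- shared_option_count(design, v)
      if (length(shared[[v]]$intercepts) != Mv - 1L)
        stop("shared set ", v, ": expected ", Mv - 1L, " intercepts",
             call. = FALSE)
      shared[[v]]
    })
  } else shared <- NULL
  structure(list(model = model, items = items, shared = shared),
            class = if (pseudo) "dcm_pseudo_params" else "dcm_params")
}

named_vec <- function(x, labs) {
  x <- unlist(x, use.names = FALSE)
  if (length(x) != length(labs))
    stop("expected ", length(labs), " effect values", call. = FALSE)
  names(x) <- labs
  x
}

#' Cumulate pseudo parameters into natural parameters
#'
#' Natural option-`m` values are the option-1 base plus the increments up
#' to `m` (`l[z, m] = l[z, 1] + l'[z, 2] + ... + l'[z, m]`).  Sign
#' constraints on the pseudo form are checked first: intercept increments
#' must be `<= 0`, effect bases and increments `>= 0` (the base strictly
#' `> 0` when `strict`).
#'
#' @param pseudo a [dcm_pseudo_params()] object.
#' @param design the matching [dcm_design()].
#' @param strict require strict positivity of effect bases
#'   (default `FALSE`: boundary values from samplers/optimizers pass).
#' @return a natural-form [dcm_params()] object.
#' @export
pseudo_to_natural <- function(pseudo, design, strict = FALSE) {
  stopifnot(inherits(pseudo, "dcm_pseudo_params"))
  v <- validate_constraints(pseudo, design, strict = strict)
  if (!all(v$pass)) {
    bad <- v[!v$pass, , drop = FALSE]
    stop("constraint violation in pseudo parameters: ",
         paste(sprintf("%s (%s)", bad$constraint, bad$offending),
               collapse = "; "), call. = FALSE)
  }
  model <- pseudo$model
  items <- lapply(seq_along(pseudo$items), function(i) {
    it <- pseudo$items[[i]]
    if (model == "nrdm") {
      list(intercepts = cumsum(it$intercepts),
           effects = t(apply(it$effects, 1L, cumsum)))
    } else if (model == "ordm") {
      list(intercepts = cumsum(it$intercepts), effects = it$effects)
    } else {
      list(intercept = it$intercept, effects = it$effects)
    }
  })
  shared <- if (model == "mordm")
    lapply(pseudo$shared, function(s) list(intercepts = cumsum(s$intercepts)))
  dcm_params(model, design, items, shared)
}

#' Decompose natural parameters into pseudo parameters
#'
#' Inverse of [pseudo_to_natural()]: successive differences along options.
#' Fails with a constraint-violation error when the natural values break
#' the ordinal constraints (non-monotone intercepts, negative effects).
#'
#' @inheritParams pseudo_to_natural
#' @param natural a natural-form [dcm_params()] object.
#' @return a [dcm_pseudo_params()] object; round-trips with
#'   [pseudo_to_natural()] to arithmetic tolerance.
#' @export
natural_to_pseudo <- function(natural, design, strict = FALSE) {
  stopifnot(inherits(natural, "dcm_params"))
  v <- validate_constraints(natural, design, strict = strict)
  if (!all(v$pass)) {
    bad <- v[!v$pass, , drop = FALSE]
    stop("constraint violation in natural parameters: ",
         paste(sprintf("%s (%s)", bad$constraint, bad$offending),
               collapse = "; "), call. = FALSE)
  }
  model <- natural$model
  decum <- function(x) if (length(x) > 1L) c(x[1L], diff(x)) else x
  items <- lapply(natural$items, function(it) {
    if (model == "nrdm") {
      list(intercepts = decum(it$intercepts),
           effects = t(apply(it$effects, 1L, decum)))
    } else if (model == "ordm") {
      list(intercepts = decum(it$intercepts), effects = it$effects)
    } else {
      list(intercept = it$intercept, effects = it$effects)
    }
  })
  shared <- if (model == "mordm")
    lapply(natural$shared, function(s) list(intercepts = decum(s$intercepts)))
  dcm_pseudo_params(model, design, items, shared)
}

#' Validate ordinal model constraints
#'
#' Reports, per constraint family, whether a parameter object satisfies the
#' identifiability/order constraints: baseline-option parameters fixed at 0
#' (implicit in the storage), positive effects, non-increasing option
#' intercepts (equivalently non-positive intercept increments), and for the
#' MORDM non-increasing shared option intercept sums.
#'
#' @param params a [dcm_params()] or [dcm_pseudo_params()] object.
#' @param design the matching [dcm_design()].
#' @param strict require strict inequalities (`> 0` on effects).
#' @return data frame with columns `constraint`, `pass`, `offending`
#'   (comma-separated offender labels, `""` when passing).
#' @export
validate_constraints <- function(params, design, strict = FALSE) {
  pseudo <- inherits(params, "dcm_pseudo_params")
  model <- params$model
  tol <- if (strict) 0 else -1e-12
  rows <- list()
  note <- function(constraint, offenders) {
    rows[[length(rows) + 1L]] <<- data.frame(
      constraint = constraint, pass = length(offenders) == 0L,
      offending = paste(offenders, collapse = ","),
      stringsAsFactors = FALSE)
  }
  eff_off <- character(); int_off <- character()
  for (i in seq_along(params$items)) {
    it <- params$items[[i]]
    eff <- it$effects
    if (model == "nrdm") {
      base <- eff[, 1L, drop = TRUE]
      if (any(bad <- !(base > tol)))
        eff_off <- c(eff_off, sprintf("item%d:%s", i, rownames(eff)[bad]))
      inc <- if (pseudo) eff[, -1L, drop = FALSE]
             else t(apply(eff, 1L, function(x) diff(x)))
      if (ncol(eff) > 1L && any(bad <- inc < tol))
        eff_off <- c(eff_off,
                     sprintf("item%d:effect-increment%d", i, which(bad)))
    } else {
      if (any(bad <- !(eff > tol)))
        eff_off <- c(eff_off, sprintf("item%d:%s", i, names(eff)[bad]))
    }
    if (model != "mordm") {
      inc <- if (pseudo) it$intercepts[-1L] else diff(it$intercepts)
      if (length(inc) && any(bad <- inc > -tol))
        int_off <- c(int_off, sprintf("item%d:m%d", i, which(bad) + 1L))
    }
  }
  shr_off <- character()
  if (model == "mordm") {
    for (v in seq_along(params$shared)) {
      s <- params$shared[[v]]$intercepts
      inc <- if (pseudo) s[-1L] else diff(s)
      if (length(inc) && any(bad <- inc > -tol))
        shr_off <- c(shr_off, sprintf("set%d:m%d", v, which(bad) + 1L))
    }
  }
  note("effects > 0 (lambda_1, lambda_2, ... positive)", eff_off)
  if (model != "mordm")
    note("intercepts non-increasing in option (l0[,m] >= l0[,m+1])", int_off)
  if (model == "mordm")
    note("shared option intercepts non-increasing in option", shr_off)
  do.call(rbind, rows)
}

#' Per-option natural intercepts of an item
#'
#' Returns the composed natural intercept for each non-baseline option of
#' one item: the stored intercepts for NRDM/ORDM, and for the MORDM the
#' item-general intercept plus the shared option intercept of the item's
#' attribute set (`l0[i] + l0s[v(i), m]`).
#'
#' @param params natural-form [dcm_params()].
#' @param design the matching [dcm_design()].
#' @param item item index.
#' @return numeric vector of length `M_i - 1` (options `1 .. M_i - 1`).
#' @export
option_intercepts <- function(params, design, item) {
  stopifnot(inherits(params, "dcm_params"))
  it <- params$items[[item]]
  if (params$model == "mordm") {
    v <- design$item_set[item]
    it$intercept + params$shared[[v]]$intercepts
  } else it$intercepts
}

#' Read / write parameter files
#'
#' Parameters are stored as JSON in natural form, with the pseudo form
#' attached for reference.  Numeric values are serialized at full
#' precision so a write/read round trip is bit-exact.
#'
#' @param params natural-form [dcm_params()].
#' @param design the matching [dcm_design()].
#' @param path file path.
#' @return `read_params()` returns the [dcm_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @name params_io
NULL

#' @rdname params_io
#' @export
write_params <- function(params, design, path) {
  stopifnot(inherits(params, "dcm_params"))
  pseudo <- natural_to_pseudo(params, design)
  ser_items <- function(obj) lapply(seq_along(obj$items), function(i) {
    it <- obj$items[[i]]
    out <- list()
    if (params$model == "mordm") out$intercept <- it$intercept
    else out$intercepts <- as.numeric(it$intercepts)
    out$effects <- if (params$model == "nrdm") {
      eff <- it$effects
      stats::setNames(lapply(seq_len(nrow(eff)),
                             function(t) as.numeric(eff[t, ])),
                      rownames(eff))
    } else as.list(it$effects)
    out
  })
  ser_shared <- function(obj) {
    if (is.null(obj$shared)) NULL
    else lapply(seq_along(obj$shared), function(v)
      list(set = design$W$set_labels[v],
           intercepts = as.numeric(obj$shared[[v]]$intercepts)))
  }
  doc <- list(model = params$model,
              natural = list(items = ser_items(params),
                             shared = ser_shared(params)),
              pseudo = list(items = ser_items(pseudo),
                            shared = ser_shared(pseudo)))
  # I(17) significant digits: enough for a bit-exact double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname params_io
#' @export
read_params <- function(path, design) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- doc$model
  items <- lapply(seq_along(doc$natural$items), function(i) {
    it <- doc$natural$items[[i]]
    eff <- it$effects
    out <- list()
    if (model == "mordm") out$intercept <- it$intercept
    else out$intercepts <- unlist(it$intercepts, use.names = FALSE)
    out$effects <- if (model == "nrdm") {
      do.call(rbind, lapply(eff, function(e) unlist(e, use.names = FALSE)))
    } else unlist(eff, use.names = FALSE)
    out
  })
  shared <- if (!is.null(doc$natural$shared) &&
                length(doc$natural$shared) > 0L)
    lapply(doc$natural$shared, function(s)
      list(intercepts = unlist(s$intercepts, use.names = FALSE)))
  dcm_params(model, design, items, shared)
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("Natural", toupper(x$model), "parameters:", length(x$items), "items\n")
  invisible(x)
}

#' @export
print.dcm_pseudo_params <- function(x, ...) {
  cat("Pseudo", toupper(x$model), "parameters:", length(x$items), "items\n")
  invisible(x)
}
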