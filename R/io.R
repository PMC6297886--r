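#' Read and write response data CSV
#'
#' Responses are stored as comma-separated UTF-8 text with a mandatory
#' header of item ids and one respondent per row; cells are integer codes
#' `0..M_i-1`.
#'
#' @param path CSV file path.
#' @param M optional per-item option counts; when omitted they are
#'   inferred as `max(code) + 1` per item (at least 2).
#' @param allow_missing accept `NA` cells (default `FALSE`: missing
#'   responses are rejected with an explicit error).
#' @return `read_responses()` returns a `response_data` object;
#'   `write_responses()` returns `path` invisibly.
#' @name responses_io
NULL

#' @rdname responses_io
#' @export
read_responses <- function(path, M = NULL, allow_missing = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  raw <- as.matrix(df)
  X <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (j in seq_len(ncol(raw))) {
    xj <- raw[, j]
    v <- suppressWarnings(as.numeric(xj))
    bad <- which(!is.na(xj) & (is.na(v) | v != round(v)))
    if (length(bad))
      stop("parse error: non-integer cell at row ", bad[1L], ", column '",
           colnames(raw)[j], "' (value '", xj[bad[1L]], "')",
           call. = FALSE)
    X[, j] <- as.integer(v)
  }
  if (anyNA(X) && !allow_missing) {
    idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("missing response at row ", idx[1L], ", column '",
         colnames(X)[idx[2L]],
         "'; rerun with allow_missing = TRUE to permit", call. = FALSE)
  }
  if (any(X < 0, na.rm = TRUE))
    stop("data validation: negative response code", call. = FALSE)
  M <- as.integer(rep_len(
    M %||% pmax(apply(X, 2L, max, na.rm = TRUE) + 1L, 2L), ncol(X)))
  for (j in seq_len(ncol(X))) {
    bad <- which(!is.na(X[, j]) & X[, j] >= M[j])
    if (length(bad))
      stop("data validation: row ", bad[1L], ", column '",
           colnames(X)[j], "': code ", X[bad[1L], j],
           " outside 0..", M[j] - 1L, call. = FALSE)
  }
  structure(list(responses = X, M = M, item_ids = colnames(X),
                 true_class = NULL, meta = list(source = path)),
            class = "response_data")
}

#' @rdname responses_io
#' @param data a `response_data` object (or bare matrix).
#' @export
write_responses <- function(data, path) {
  X <- as_response_matrix(data)
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

#' Read a Q-matrix CSV
#'
#' Format: header row of attribute ids, first column of item ids, binary
#' cells.
#'
#' @param path CSV file path.
#' @return a [q_matrix()].
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  items <- as.character(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  ok <- matrix(body %in% c(0, 1), nrow(body))  # %in% drops dims
  if (any(!ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop("parse error: non-binary Q-matrix cell at row ", bad[1L, 1L],
         ", column '", colnames(body)[bad[1L, 2L]], "'", call. = FALSE)
  }
  q_matrix(body, item_ids = items, attribute_ids = colnames(body))
}

#' Write a Q-matrix CSV
#' @param Q a [q_matrix()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_qmatrix <- function(Q, path) {
  df <- data.frame(item = rownames(Q), as.data.frame(unclass(Q)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a report object to JSON or CSV
#'
#' JSON output serializes numeric values at full precision with stable
#' field ordering; CSV output is for tabular report components and rounds
#' display values to 3 decimals (the precision of the tables it mirrors).
#'
#' @param report a report object (e.g. `recovery_report`,
#'   `agreement_report`, `fit_indices`) or plain list/data frame.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, null = "null",
                         na = "null")
  } else {
    df <- report_as_df(report)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = 3L)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  if (is.matrix(x)) {
    if (!is.null(rownames(x)))
      return(data.frame(name = rownames(x), as.data.frame(x),
                        check.names = FALSE))
    return(as.data.frame(x))
  }
  unclass(x)
}

report_as_df <- function(report) {
  if (is.data.frame(report)) return(report)
  if (is.matrix(report))
    return(data.frame(name = rownames(report) %||%
                        seq_len(nrow(report)),
                      as.data.frame(report), check.names = FALSE))
  if (inherits(report, "agreement_report")) {
    tab <- report$crosstab
    return(data.frame(level = rownames(tab), as.data.frame(tab),
                      check.names = FALSE))
  }
  if (inherits(report, "recovery_report")) return(report$item_parameters)
  if (inherits(report, "fit_indices"))
    return(data.frame(index = c("ELPD", "LOOIC"),
                      estimate = c(report$elpd, report$looic),
                      se = c(report$elpd_se, report$looic_se)))
  stop("cannot render this report as CSV", call. = FALSE)
}
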