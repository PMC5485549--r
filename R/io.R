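#' Claims-file dialect
#'
#' The claims format is a delimited text table with a header row and one
#' row per admission/operation.  Code lists live in single cells, joined by
#' a within-cell separator, with the procedure cell's order preserved
#' (primary procedure first).  Truth columns are tri-state: `true`,
#' `false`, or empty for unknown.
#'
#' @param delimiter field delimiter (default comma).
#' @param code_sep within-cell code separator (default semicolon); must
#'   differ from the delimiter.
#' @param col_record_id,col_dx,col_px,col_is_case,col_had_excision,col_had_hemorrhage
#'   column names.
#' @return list of class `"claims_dialect"`.
#' @export
claims_dialect <- function(delimiter = ",", code_sep = ";",
                           col_record_id = "record_id",
                           col_dx = "dx_codes", col_px = "px_codes",
                           col_is_case = "is_case",
                           col_had_excision = "had_excision",
                           col_had_hemorrhage = "had_hemorrhage") {
  if (identical(delimiter, code_sep))
    stop("delimiter and within-cell code separator must differ", call. = FALSE)
  structure(list(delimiter = delimiter, code_sep = code_sep,
                 col_record_id = col_record_id, col_dx = col_dx,
                 col_px = col_px, col_is_case = col_is_case,
                 col_had_excision = col_had_excision,
                 col_had_hemorrhage = col_had_hemorrhage),
            class = "claims_dialect")
}

#' Read and write claims files
#'
#' `read_claims()` parses a delimited claims file into a
#' [claims_cohort()], normalizing every code on ingest.  In strict mode
#' (default) the first malformed code aborts the read, reporting the row
#' and offending text; in lenient mode malformed records are kept, flagged,
#' and later classified negative with a warning trace.  `write_claims()`
#' writes a cohort back out; a written cohort reads back identically.
#'
#' @param path file path.
#' @param dialect a [claims_dialect()].
#' @param strict abort on the first malformed code (default) instead of
#'   flagging the record.
#' @param cohort a [claims_cohort()].
#' @return `read_claims()` returns a `claims_cohort` (with a `.malformed`
#'   logical column in lenient mode); `write_claims()` returns `path`
#'   invisibly.
#' @export
read_claims <- function(path, dialect = claims_dialect(), strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("claims file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"")
  need <- c(dialect$col_record_id, dialect$col_dx, dialect$col_px)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("claims file missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  split_cell <- function(x) {
    lapply(strsplit(x, dialect$code_sep, fixed = TRUE),
           function(v) v[nzchar(trimws(v))])
  }
  raw_dx <- split_cell(df[[dialect$col_dx]])
  raw_px <- split_cell(df[[dialect$col_px]])
  n <- nrow(df)
  malformed <- logical(n)
  norm_list <- function(raw, axis) {
    lapply(seq_len(n), function(i) {
      tryCatch(
        if (length(raw[[i]])) icd9_normalize(raw[[i]], axis) else character(),
        error = function(e) {
          if (strict)
            stop(sprintf("row %d (%s): %s", i, df[[dialect$col_record_id]][i],
                         conditionMessage(e)), call. = FALSE)
          malformed[i] <<- TRUE
          message(sprintf("lenient mode: row %d (%s): %s", i,
                          df[[dialect$col_record_id]][i], conditionMessage(e)))
          character()
        })
    })
  }
  dx <- norm_list(raw_dx, "diagnosis")
  px <- norm_list(raw_px, "procedure")
  tri <- function(col) {
    if (!col %in% names(df)) return(rep(NA, n))
    v <- tolower(trimws(df[[col]]))
    out <- rep(NA, n)
    out[v %in% c("true", "t", "1")] <- TRUE
    out[v %in% c("false", "f", "0")] <- FALSE
    out
  }
  coh <- claims_cohort(df[[dialect$col_record_id]], dx, px,
                       is_case = tri(dialect$col_is_case),
                       had_excision = tri(dialect$col_had_excision),
                       had_hemorrhage = tri(dialect$col_had_hemorrhage))
  if (!strict) coh$.malformed <- malformed
  coh
}

#' @rdname read_claims
#' @export
write_claims <- function(cohort, path, dialect = claims_dialect()) {
  join <- function(lst) vapply(lst, paste, character(1), collapse = dialect$code_sep)
  tri <- function(v) ifelse(is.na(v), "", ifelse(v, "true", "false"))
  df <- data.frame(
    record_id = cohort$record_id,
    dx_codes = join(cohort$dx_codes),
    px_codes = join(cohort$px_codes),
    is_case = tri(cohort$is_case),
    had_excision = tri(cohort$had_excision),
    had_hemorrhage = tri(cohort$had_hemorrhage),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(df) <- c(dialect$col_record_id, dialect$col_dx, dialect$col_px,
                 dialect$col_is_case, dialect$col_had_excision,
                 dialect$col_had_hemorrhage)
  utils::write.table(df, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write classification results and metrics tables
#'
#' The per-record results table carries the record id, the phenotype
#' label, the fired inclusion/exclusion pattern traces (pairs collapsed as
#' `pattern->code`, joined by `|`), any warning notes, and the two
#' secondary coding indicators.  The metrics table is the flat
#' [compute_metrics()] layout.  Both are deterministic given their inputs.
#'
#' @param results a [classify_cohort()] result.
#' @param path output path for the results table.
#' @param cohort the classified [claims_cohort()]; if supplied, indicator
#'   columns are included (`excision_coded` is blank for records without
#'   procedure codes).
#' @param metrics optional [compute_metrics()] table.
#' @param metrics_path output path for the metrics table (default:
#'   `path` with a `.metrics` suffix).
#' @param dialect a [claims_dialect()]; only the delimiter is used.
#' @return invisible character vector of the file(s) written.
#' @export
write_results <- function(results, path, cohort = NULL, metrics = NULL,
                          metrics_path = paste0(path, ".metrics"),
                          dialect = claims_dialect()) {
  collapse_trace <- function(tr)
    paste(sprintf("%s->%s", tr$pattern, tr$code), collapse = "|")
  df <- data.frame(
    record_id = results$record_id,
    label = results$label,
    fired_inclusion = vapply(results$fired_inclusion, collapse_trace, character(1)),
    fired_exclusion = vapply(results$fired_exclusion, collapse_trace, character(1)),
    notes = vapply(results$notes, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort)) {
    has_px <- lengths(cohort$px_codes) > 0L
    exc <- rep(NA, nrow(cohort))
    if (any(has_px))
      exc[has_px] <- excision_indicator(cohort[has_px, , drop = FALSE])
    df$excision_coded <- ifelse(is.na(exc), "", ifelse(exc, "true", "false"))
    hem <- hemorrhage_indicator(cohort)
    df$hemorrhage_coded <- ifelse(hem, "true", "false")
  }
  utils::write.table(df, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE)
  written <- path
  if (!is.null(metrics)) {
    m <- as.data.frame(metrics)
    utils::write.table(m, metrics_path, sep = dialect$delimiter,
                       row.names = FALSE, quote = FALSE)
    written <- c(written, metrics_path)
  }
  invisible(written)
}
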