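#' Build a claims cohort
#'
#' A claims cohort holds one row per hospital admission/operation: a unique
#' record id, the record's ICD-9-CM diagnosis codes (unordered), its
#' procedure codes (ordered, first = primary procedure), and optional
#' chart-review gold-standard labels.  Codes are normalized to canonical
#' dotted form on construction.
#'
#' @param record_id character vector of unique record identifiers.
#' @param dx_codes list of character vectors of diagnosis codes (one
#'   element per record; a plain character vector is taken as one code per
#'   record).
#' @param px_codes list of character vectors of procedure codes, primary
#'   first.
#' @param is_case,had_excision,had_hemorrhage optional logical truth labels
#'   (`NA` = unknown).
#' @return A data frame of class `"claims_cohort"` with list columns
#'   `dx_codes` and `px_codes`.
#' @examples
#' claims_cohort(
#'   record_id = c("a", "b"),
#'   dx_codes = list("434.91", c("434.11", "852.21")),
#'   px_codes = list("01.24", "01.25")
#' )
#' @export
claims_cohort <- function(record_id, dx_codes, px_codes,
                          is_case = NA, had_excision = NA,
                          had_hemorrhage = NA) {
  record_id <- as.character(record_id)
  n <- length(record_id)
  if (anyDuplicated(record_id))
    stop(sprintf("duplicate record_id(s): %s",
                 paste(unique(record_id[duplicated(record_id)]), collapse = ", ")),
         call. = FALSE)
  as_code_list <- function(x, axis) {
    if (!is.list(x)) x <- as.list(x)
    stopifnot(length(x) == n)
    lapply(x, function(v) {
      v <- v[!is.na(v) & nzchar(trimws(v))]
      if (!length(v)) character() else icd9_normalize(v, axis)
    })
  }
  out <- data.frame(record_id = record_id, stringsAsFactors = FALSE)
  out$dx_codes <- as_code_list(dx_codes, "diagnosis")
  out$px_codes <- as_code_list(px_codes, "procedure")
  out$is_case <- rep_len(as.logical(is_case), n)
  out$had_excision <- rep_len(as.logical(had_excision), n)
  out$had_hemorrhage <- rep_len(as.logical(had_hemorrhage), n)
  class(out) <- c("claims_cohort", "data.frame")
  out
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf("Claims cohort: %d record(s)\n", nrow(x)))
  if (!all(is.na(x$is_case)))
    cat(sprintf("  gold-standard cases: %d of %d labelled\n",
                sum(x$is_case, na.rm = TRUE), sum(!is.na(x$is_case))))
  df <- data.frame(
    record_id = x$record_id,
    dx_codes = vapply(x$dx_codes, paste, character(1), collapse = ";"),
    px_codes = vapply(x$px_codes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  print(utils::head(df, 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}
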