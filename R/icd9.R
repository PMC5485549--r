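#' ICD-9-CM codes and wildcard patterns
#'
#' ICD-9-CM carries two axes of codes on a billing record: diagnosis codes
#' (3-character root, up to two further characters after the decimal point,
#' e.g. `433.11`, `430`) and procedure codes (2-character root, e.g. `01.25`,
#' `03.09`).  Claims extracts write the same code in a dotted (`433.11`) or
#' undotted (`43311`) dialect; both normalize to the dotted canonical form.
#' Code-family patterns end in wildcard characters (`191.x`, `800.xx`) and
#' denote every subcode of the category by prefix.
#'
#' `icd9()` builds a vector of normalized codes, `icd9_pattern()` a vector of
#' normalized patterns (wildcards permitted).  Both reject malformed input:
#' letters other than the wildcard `x` (so V- and E-codes are refused),
#' multiple dots, and roots of the wrong width.  Leading zeros are
#' significant and preserved (`01.25` never becomes `1.25`).
#'
#' @param x character vector of raw code or pattern strings, dotted or
#'   undotted.
#' @param axis `"diagnosis"` or `"procedure"`; determines the root width.
#' @return A character vector of canonical dotted codes with class
#'   `"icd9"` (or `"icd9_pattern"`) and an `axis` attribute.
#' @examples
#' icd9(c("43311", "430"), "diagnosis")
#' icd9("0125", "procedure")
#' icd9_pattern(c("800.xx", "191.x"), "diagnosis")
#' @seealso [pattern_matches()], [any_match()]
#' @export
icd9 <- function(x, axis = c("diagnosis", "procedure")) {
  axis <- match.arg(axis)
  out <- icd9_normalize(x, axis, wildcard = FALSE)
  structure(out, class = "icd9", axis = axis)
}

#' @rdname icd9
#' @export
icd9_pattern <- function(x, axis = c("diagnosis", "procedure")) {
  axis <- match.arg(axis)
  out <- icd9_normalize(x, axis, wildcard = TRUE)
  structure(out, class = "icd9_pattern", axis = axis)
}

#' Normalize ICD-9-CM code strings to canonical dotted form
#'
#' Vectorized workhorse behind [icd9()] and [icd9_pattern()].  Accepts
#' dotted and undotted dialects and returns the canonical dotted string;
#' normalization is idempotent.
#'
#' @inheritParams icd9
#' @param wildcard allow trailing wildcard `x` characters (patterns).
#' @return plain character vector of canonical dotted strings.
#' @export
icd9_normalize <- function(x, axis = c("diagnosis", "procedure"),
                           wildcard = FALSE) {
  axis <- match.arg(axis)
  rootlen <- if (axis == "diagnosis") 3L else 2L
  x <- trimws(as.character(x))
  # case-insensitivity applies only to the wildcard character
  x <- gsub("X", "x", x, fixed = TRUE)
  bad <- function(txt, why) {
    stop(sprintf("invalid ICD-9-CM %s code '%s': %s", axis, txt, why),
         call. = FALSE)
  }
  vapply(x, function(s) {
    if (!nzchar(s)) bad(s, "empty")
    stripped <- gsub(".", "", s, fixed = TRUE)
    if (nchar(s) - nchar(stripped) > 1L) bad(s, "more than one dot")
    if (grepl("x", stripped, fixed = TRUE) && !wildcard)
      bad(s, "wildcards are not allowed in a code")
    if (!grepl("^[0-9]+x*$", stripped))
      bad(s, "must be digits, an optional dot, and trailing wildcards only in a pattern")
    if (grepl(".", s, fixed = TRUE)) {
      parts <- strsplit(s, ".", fixed = TRUE)[[1]]
      root <- parts[1]
      frac <- if (length(parts) > 1L) parts[2] else ""
    } else {
      if (nchar(s) < rootlen) bad(s, sprintf("root shorter than %d characters", rootlen))
      root <- substr(s, 1L, rootlen)
      frac <- substring(s, rootlen + 1L)
    }
    if (nchar(root) != rootlen)
      bad(s, sprintf("root must be exactly %d characters", rootlen))
    if (!grepl("^[0-9]+$", root))
      bad(s, "root must be all digits")
    if (nchar(frac) > 2L)
      bad(s, "more than two characters after the root")
    if (nzchar(frac)) paste0(root, ".", frac) else root
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.icd9 <- function(x, ...) {
  cat(sprintf("<icd9 %s codes>\n", attr(x, "axis")))
  print(unclass(structure(as.character(x), axis = NULL)))
  invisible(x)
}

#' @export
print.icd9_pattern <- function(x, ...) {
  cat(sprintf("<icd9 %s patterns>\n", attr(x, "axis")))
  print(unclass(structure(as.character(x), axis = NULL)))
  invisible(x)
}

#' @export
`[.icd9` <- function(x, i) {
  structure(unclass(x)[i], class = class(x), axis = attr(x, "axis"))
}

#' @export
`[.icd9_pattern` <- `[.icd9`

icd9_axis <- function(x) attr(x, "axis")

check_same_axis <- function(pattern, code) {
  pa <- icd9_axis(pattern)
  ca <- icd9_axis(code)
  if (!is.null(pa) && !is.null(ca) && !identical(pa, ca))
    stop(sprintf("axis mismatch: pattern axis '%s', code axis '%s'", pa, ca),
         call. = FALSE)
}

#' Test whether a code falls in the family a pattern denotes
#'
#' An exact pattern (no wildcard) matches only its own canonical text.  A
#' wildcard pattern matches every code whose canonical text begins with the
#' pattern's non-wildcard prefix -- ICD-9-CM is hierarchical by prefix, so
#' `800.xx` denotes all of category 800 -- and also matches the bare
#' category root itself (`800.xx` matches `800`), since claims sometimes
#' record a category without a subcode and exclusion should err on the side
#' of excluding.  `191.x` and `191.xx` denote the same family.
#'
#' @param pattern a single pattern string (or [icd9_pattern()] element).
#' @param code a vector of canonical code strings (or [icd9()] vector) of
#'   the same axis; an axis mismatch between classed inputs is an error.
#' @return logical vector, one element per code.
#' @examples
#' pattern_matches("800.xx", "800.21")
#' pattern_matches("433.11", c("433.10", "433.11"))
#' @export
pattern_matches <- function(pattern, code) {
  stopifnot(length(pattern) == 1L)
  check_same_axis(pattern, code)
  pattern <- as.character(pattern)
  code <- as.character(code)
  if (!grepl("x", pattern, fixed = TRUE))
    return(code == pattern)
  prefix <- sub("x.*$", "", pattern)
  startsWith(code, prefix) | code == sub("\\.$", "", prefix)
}

#' Match a set of patterns against a collection of codes
#'
#' Set-level convenience used by the rule engine: reports whether any
#' (pattern, code) pair matches, together with the full trace of matching
#' pairs so a classification can be explained.  Duplicate codes within a
#' record collapse to one for matching purposes.
#'
#' @param patterns vector of patterns (possibly empty).
#' @param codes vector of canonical codes (possibly empty).
#' @return list with elements `match` (logical scalar) and `trace` (a
#'   data frame with columns `pattern` and `code`, one row per matching
#'   pair).
#' @export
any_match <- function(patterns, codes) {
  check_same_axis(patterns, codes)
  patterns <- unique(as.character(patterns))
  codes <- unique(as.character(codes))
  if (length(patterns) == 0L || length(codes) == 0L)
    return(list(match = FALSE, trace = empty_trace()))
  hits <- lapply(patterns, function(p) codes[pattern_matches(p, codes)])
  n <- lengths(hits)
  trace <- data.frame(pattern = rep(patterns, n),
                      code = unlist(hits, use.names = FALSE),
                      stringsAsFactors = FALSE)
  list(match = nrow(trace) > 0L, trace = trace)
}

empty_trace <- function() {
  data.frame(pattern = character(), code = character(),
             stringsAsFactors = FALSE)
}
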