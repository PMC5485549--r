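#' Declarative phenotype rule sets
#'
#' A phenotype rule set classifies a claims record positive when at least
#' one inclusion diagnosis pattern matches a diagnosis code AND at least one
#' inclusion procedure pattern matches a procedure code, and no exclusion
#' pattern of either axis matches any code of that axis.  Exclusion strictly
#' overrides inclusion.
#'
#' Invariants enforced at construction: both inclusion sets are non-empty,
#' and no pattern text appears in both an inclusion set and the same-axis
#' exclusion set.
#'
#' @param name short identifier for the rule set.
#' @param inclusion_diagnosis,inclusion_procedure character vectors of
#'   inclusion patterns (dotted ICD-9-CM, wildcards as trailing `x`).
#' @param exclusion_diagnosis,exclusion_procedure character vectors of
#'   exclusion patterns; may be empty.
#' @return An object of class `"phenotype_ruleset"`.
#' @examples
#' rs <- phenotype_ruleset(
#'   name = "toy",
#'   inclusion_diagnosis = "434.91",
#'   inclusion_procedure = "01.25",
#'   exclusion_diagnosis = "800.xx"
#' )
#' rs
#' @seealso [builtin_ruleset()], [load_ruleset()], [classify_record()]
#' @export
phenotype_ruleset <- function(name,
                              inclusion_diagnosis,
                              inclusion_procedure,
                              exclusion_diagnosis = character(),
                              exclusion_procedure = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  rs <- structure(
    list(
      name = name,
      inclusion_diagnosis = icd9_pattern(inclusion_diagnosis, "diagnosis"),
      inclusion_procedure = icd9_pattern(inclusion_procedure, "procedure"),
      exclusion_diagnosis = if (length(exclusion_diagnosis))
        icd9_pattern(exclusion_diagnosis, "diagnosis") else
        icd9_pattern(character(), "diagnosis"),
      exclusion_procedure = if (length(exclusion_procedure))
        icd9_pattern(exclusion_procedure, "procedure") else
        icd9_pattern(character(), "procedure")
    ),
    class = "phenotype_ruleset"
  )
  validate_ruleset(rs)
  rs
}

validate_ruleset <- function(rs) {
  if (length(rs$inclusion_diagnosis) == 0L || length(rs$inclusion_procedure) == 0L)
    stop("a usable rule set needs non-empty inclusion diagnosis and procedure sets",
         call. = FALSE)
  for (ax in c("diagnosis", "procedure")) {
    inc <- as.character(rs[[paste0("inclusion_", ax)]])
    exc <- as.character(rs[[paste0("exclusion_", ax)]])
    both <- intersect(inc, exc)
    if (length(both))
      stop(sprintf("pattern(s) %s appear in both inclusion and exclusion %s sets",
                   paste(sQuote(both), collapse = ", "), ax), call. = FALSE)
    dup <- unique(c(inc[duplicated(inc)], exc[duplicated(exc)]))
    if (length(dup))
      stop(sprintf("duplicate %s pattern(s): %s", ax,
                   paste(sQuote(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(rs)
}

#' @export
print.phenotype_ruleset <- function(x, ...) {
  cat(sprintf("Phenotype rule set '%s'\n", x$name))
  show <- function(label, v) {
    cat(sprintf("  %-21s (%2d): %s\n", label, length(v),
                if (length(v)) paste(as.character(v), collapse = ", ") else "-"))
  }
  cat("Inclusion (diagnosis AND procedure must both match):\n")
  show("diagnosis patterns", x$inclusion_diagnosis)
  show("procedure patterns", x$inclusion_procedure)
  cat("Exclusion (any match on either axis overrides):\n")
  show("diagnosis patterns", x$exclusion_diagnosis)
  show("procedure patterns", x$exclusion_procedure)
  invisible(x)
}

#' Read and write rule sets as YAML
#'
#' The on-disk format is a small YAML document with fields `name`,
#' `inclusion: {diagnosis: [...], procedure: [...]}` and
#' `exclusion: {diagnosis: [...], procedure: [...]}`.  Pattern strings must
#' be quoted in the file so that codes such as `"433.11"` or `"324.0"`
#' survive as text; a pattern that parses as a YAML number is rejected with
#' the offending value, since an unquoted `324.0` would silently lose its
#' trailing zero.  `load_ruleset(save_ruleset(rs, f))` reproduces `rs`
#' exactly.
#'
#' @param path file path of the YAML rule-set document.
#' @param rules a [phenotype_ruleset()].
#' @return `load_ruleset()` returns a `phenotype_ruleset`; `save_ruleset()`
#'   returns `path` invisibly.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop(sprintf("rule-set file not found: %s", path),
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  need <- c("name", "inclusion", "exclusion")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop(sprintf("rule-set file missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  grab <- function(section, ax) {
    unknown <- setdiff(names(doc[[section]]), c("diagnosis", "procedure"))
    if (length(unknown))
      stop(sprintf("unknown axis in %s: %s", section,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    v <- doc[[section]][[ax]]
    if (is.null(v)) return(character())
    bad <- vapply(v, is.numeric, logical(1))
    if (any(bad))
      stop(sprintf("unquoted numeric pattern(s) in %s %s: %s (quote all patterns)",
                   section, ax,
                   paste(vapply(v[bad], format, character(1)), collapse = ", ")),
           call. = FALSE)
    vapply(v, as.character, character(1))
  }
  phenotype_ruleset(
    name = as.character(doc$name),
    inclusion_diagnosis = grab("inclusion", "diagnosis"),
    inclusion_procedure = grab("inclusion", "procedure"),
    exclusion_diagnosis = grab("exclusion", "diagnosis"),
    exclusion_procedure = grab("exclusion", "procedure")
  )
}

#' @rdname load_ruleset
#' @export
save_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "phenotype_ruleset"))
  doc <- list(
    name = rules$name,
    inclusion = list(
      diagnosis = as.character(rules$inclusion_diagnosis),
      procedure = as.character(rules$inclusion_procedure)
    ),
    exclusion = list(
      diagnosis = as.character(rules$exclusion_diagnosis),
      procedure = as.character(rules$exclusion_procedure)
    )
  )
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}
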