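#' The bundled craniectomy-for-stroke rule set
#'
#' Returns the validated ICD-9-CM phenotype for decompressive craniectomy
#' for space-occupying supratentorial infarction.  Inclusion requires one
#' of four acute ischemic stroke diagnosis codes (433.11, 434.01, 434.11,
#' 434.91) and one of five neurosurgical procedure codes (01.24, 01.25,
#' 01.39, 01.53, 01.59).  Records are excluded on diagnosis codes for brain
#' tumor, intracranial abscess, subarachnoid hemorrhage, vertebrobasilar
#' infarction, unruptured aneurysm, Moyamoya disease, venous sinus
#' thrombosis, vertebral artery dissection, congenital cerebrovascular
#' anomaly or head trauma (191.x, 198.3, 324.0, 430, 433.01, 433.21, 437.3,
#' 437.5, 437.6, 443.24, 747.81, 800.xx-854.xx) or the laminectomy
#' procedure code 03.09, which removes posterior fossa craniectomies.
#'
#' The intracerebral hemorrhage code 431 is deliberately NOT an exclusion
#' criterion: it also encodes hemorrhagic conversion of an infarct, so
#' excluding on it would drop true cases.
#'
#' The same rule set ships as a YAML document at
#' `system.file("extdata", "craniectomy_stroke.yaml", package =
#' "icd9phenotype")` and `builtin_ruleset()` simply loads it.
#'
#' @param name name of a bundled rule set; only `"craniectomy_stroke"` is
#'   shipped.
#' @return A [phenotype_ruleset()].
#' @examples
#' builtin_ruleset()
#' @export
builtin_ruleset <- function(name = "craniectomy_stroke") {
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "icd9phenotype")
  if (!nzchar(path))
    stop(sprintf("no bundled rule set named '%s'", name), call. = FALSE)
  load_ruleset(path)
}

excision_primary_codes <- c("01.39", "01.53", "01.59")

#' Secondary coding indicators for craniectomy cases
#'
#' Two binary indicators whose coding accuracy is assessed among confirmed
#' craniectomy-for-stroke cases (they are well defined for any record):
#'
#' * `excision_indicator()` -- was excision of infarcted tissue coded?
#'   TRUE iff the primary (first-listed) procedure code is an excision-type
#'   code: 01.39 (other incision of brain), 01.53 (lobectomy) or 01.59
#'   (other excision of lesion of brain).  Only the primary position
#'   counts.
#' * `hemorrhage_indicator()` -- was hemorrhagic conversion coded?  TRUE
#'   iff diagnosis code 431 (intracerebral hemorrhage) appears anywhere in
#'   the record's diagnosis codes.
#'
#' @param x a [claims_cohort()] (vectorized over rows) or a single record
#'   accepted by [classify_record()].
#' @return logical vector, one element per record.
#' @examples
#' coh <- claims_cohort(c("a", "b"),
#'                      dx_codes = list(c("434.11", "431"), "434.91"),
#'                      px_codes = list("01.53", c("01.25", "01.53")))
#' excision_indicator(coh)    # TRUE, FALSE (primary position only)
#' hemorrhage_indicator(coh)  # TRUE, FALSE
#' @export
excision_indicator <- function(x) {
  px <- record_px_lists(x)
  if (any(lengths(px) == 0L))
    stop("missing primary procedure code: record has no procedure codes",
         call. = FALSE)
  vapply(px, function(p) p[1] %in% excision_primary_codes, logical(1))
}

#' @rdname excision_indicator
#' @export
hemorrhage_indicator <- function(x) {
  dx <- record_dx_lists(x)
  vapply(dx, function(d) "431" %in% d, logical(1))
}

record_px_lists <- function(x) {
  if (is.data.frame(x)) x$px_codes
  else list(as_record(x)$px_codes)
}

record_dx_lists <- function(x) {
  if (is.data.frame(x)) x$dx_codes
  else list(as_record(x)$dx_codes)
}
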