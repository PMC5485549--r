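#' Classify a single claims record against a phenotype rule set
#'
#' A record is labelled `positive` when an inclusion diagnosis pattern
#' matches at least one of its diagnosis codes AND an inclusion procedure
#' pattern matches at least one of its procedure codes, and no exclusion
#' pattern (either axis) matches any code of that axis.  Exclusion is
#' evaluated on all of a record's codes and strictly overrides inclusion.
#'
#' By default inclusion procedure matching also considers every recorded
#' procedure code; with `strict_primary = TRUE` only the first-listed
#' (primary) procedure code can satisfy the inclusion procedure criterion,
#' mirroring extracts that carry a single primary procedure code per
#' operation.
#'
#' @param record a one-row [claims_cohort()] or a list with elements
#'   `record_id`, `dx_codes` and `px_codes`.
#' @param rules a [phenotype_ruleset()].
#' @param strict_primary restrict inclusion procedure matching to the
#'   primary procedure code.
#' @return A list of class `"classification_result"` with elements
#'   `record_id`, `label` (`"positive"` or `"negative"`),
#'   `fired_inclusion` and `fired_exclusion` (data frames with columns
#'   `axis`, `pattern`, `code`) and `notes` (character).
#' @examples
#' rec <- list(record_id = "r1", dx_codes = "434.91", px_codes = "01.24")
#' classify_record(rec, builtin_ruleset())$label
#' @export
classify_record <- function(record, rules, strict_primary = FALSE) {
  stopifnot(inherits(rules, "phenotype_ruleset"))
  rec <- as_record(record)
  notes <- character()
  if (isTRUE(rec$malformed)) {
    return(classification_result(rec$record_id, "negative",
                                 axis_trace(), axis_trace(),
                                 "record carries malformed codes; classified negative (lenient mode)"))
  }
  if (length(rec$dx_codes) == 0L && length(rec$px_codes) == 0L)
    notes <- "record has no diagnosis or procedure codes"
  inc_px_codes <- if (strict_primary && length(rec$px_codes))
    rec$px_codes[1] else rec$px_codes
  inc_dx <- any_match(rules$inclusion_diagnosis, rec$dx_codes)
  inc_px <- any_match(rules$inclusion_procedure, inc_px_codes)
  exc_dx <- any_match(rules$exclusion_diagnosis, rec$dx_codes)
  exc_px <- any_match(rules$exclusion_procedure, rec$px_codes)
  fired_inclusion <- rbind(with_axis(inc_dx$trace, "diagnosis"),
                           with_axis(inc_px$trace, "procedure"))
  fired_exclusion <- rbind(with_axis(exc_dx$trace, "diagnosis"),
                           with_axis(exc_px$trace, "procedure"))
  excluded <- exc_dx$match || exc_px$match
  label <- if (inc_dx$match && inc_px$match && !excluded) "positive" else "negative"
  classification_result(rec$record_id, label, fired_inclusion,
                        fired_exclusion, notes)
}

classification_result <- function(record_id, label, fired_inclusion,
                                  fired_exclusion, notes = character()) {
  structure(
    list(record_id = record_id, label = label,
         fired_inclusion = fired_inclusion,
         fired_exclusion = fired_exclusion, notes = notes),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Record %s: %s\n", x$record_id, toupper(x$label)))
  if (nrow(x$fired_inclusion)) {
    cat("  inclusion matches:\n")
    print_trace(x$fired_inclusion)
  }
  if (nrow(x$fired_exclusion)) {
    cat("  exclusion matches:\n")
    print_trace(x$fired_exclusion)
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

print_trace <- function(tr) {
  apply(tr, 1L, function(r)
    cat(sprintf("    %-9s %s -> %s\n", r[["axis"]], r[["pattern"]], r[["code"]])))
  invisible(tr)
}

as_record <- function(record) {
  if (inherits(record, "claims_cohort") ||
      (is.data.frame(record) && all(c("record_id", "dx_codes", "px_codes") %in%
                                    names(record)))) {
    stopifnot(nrow(record) == 1L)
    list(record_id = record$record_id[[1]],
         dx_codes = record$dx_codes[[1]],
         px_codes = record$px_codes[[1]],
         malformed = isTRUE(record$.malformed[[1]]))
  } else if (is.list(record)) {
    list(record_id = as.character(record$record_id %||% "<unnamed>"),
         dx_codes = icd9_normalize(as.character(record$dx_codes %||% character()),
                                   "diagnosis"),
         px_codes = icd9_normalize(as.character(record$px_codes %||% character()),
                                   "procedure"),
         malformed = isTRUE(record$malformed))
  } else {
    stop("record must be a one-row claims cohort or a list", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_axis <- function(trace, axis) {
  if (nrow(trace) == 0L) return(axis_trace())
  cbind(data.frame(axis = axis, stringsAsFactors = FALSE), trace)
}

axis_trace <- function() {
  data.frame(axis = character(), pattern = character(), code = character(),
             stringsAsFactors = FALSE)
}

#' Classify every record of a cohort
#'
#' Element-wise application of [classify_record()] over a cohort, using a
#' vectorized matching path (each distinct code is matched against the
#' pattern sets once) so that cohorts of tens of thousands of records
#' classify in well under a second.  Output order matches input order.
#'
#' @param cohort a [claims_cohort()] (or data frame with the same columns).
#' @param rules a [phenotype_ruleset()].
#' @inheritParams classify_record
#' @return A data frame of class `"phenotype_classification"` with columns
#'   `record_id`, `label`, list columns `fired_inclusion`,
#'   `fired_exclusion`, and `notes`; attributes `n_positive` and
#'   `n_negative` carry the summary counts.
#' @examples
#' coh <- claims_cohort("a", list("434.91"), list("01.24"))
#' summary(classify_cohort(coh, builtin_ruleset()))
#' @export
classify_cohort <- function(cohort, rules, strict_primary = FALSE) {
  stopifnot(inherits(rules, "phenotype_ruleset"))
  if (!inherits(cohort, "claims_cohort"))
    cohort <- claims_cohort(cohort$record_id, cohort$dx_codes, cohort$px_codes)
  if (anyDuplicated(cohort$record_id))
    stop("cohort integrity error: duplicate record_id", call. = FALSE)
  n <- nrow(cohort)
  if (n == 0L) {
    out <- data.frame(record_id = character(), label = character(),
                      stringsAsFactors = FALSE)
    out$fired_inclusion <- list()
    out$fired_exclusion <- list()
    out$notes <- list()
    return(as_classification(out, 0L, 0L))
  }

  malformed <- if (!is.null(cohort$.malformed)) isTRUE_vec(cohort$.malformed)
               else logical(n)

  dx_idx <- rep.int(seq_len(n), lengths(cohort$dx_codes))
  dx_code <- unlist(cohort$dx_codes, use.names = FALSE) %||% character()
  px_idx <- rep.int(seq_len(n), lengths(cohort$px_codes))
  px_code <- unlist(cohort$px_codes, use.names = FALSE) %||% character()
  px_primary <- rep(FALSE, length(px_code))
  if (length(px_code))
    px_primary[c(1L, which(diff(px_idx) > 0L) + 1L)] <- TRUE

  pairs_inc_dx <- match_pairs(rules$inclusion_diagnosis, dx_code)
  pairs_exc_dx <- match_pairs(rules$exclusion_diagnosis, dx_code)
  pairs_inc_px <- match_pairs(rules$inclusion_procedure, px_code)
  pairs_exc_px <- match_pairs(rules$exclusion_procedure, px_code)

  hit_by_record <- function(idx, code, pairs, keep = TRUE) {
    h <- code %in% pairs$code & keep
    tabulate(idx[h], nbins = n) > 0L
  }
  inc_px_keep <- if (strict_primary) px_primary else TRUE
  rec_inc_dx <- hit_by_record(dx_idx, dx_code, pairs_inc_dx)
  rec_inc_px <- hit_by_record(px_idx, px_code, pairs_inc_px, inc_px_keep)
  rec_exc_dx <- hit_by_record(dx_idx, dx_code, pairs_exc_dx)
  rec_exc_px <- hit_by_record(px_idx, px_code, pairs_exc_px)

  label <- ifelse(rec_inc_dx & rec_inc_px & !rec_exc_dx & !rec_exc_px &
                    !malformed, "positive", "negative")

  empty_rec <- lengths(cohort$dx_codes) == 0L & lengths(cohort$px_codes) == 0L
  notes <- vector("list", n)
  notes[empty_rec] <- list("record has no diagnosis or procedure codes")
  notes[malformed] <- list("record carries malformed codes; classified negative (lenient mode)")
  notes[!(empty_rec | malformed)] <- list(character())

  fired_inclusion <- rep(list(axis_trace()), n)
  fired_exclusion <- rep(list(axis_trace()), n)
  any_hit <- rec_inc_dx | rec_inc_px | rec_exc_dx | rec_exc_px
  for (i in which(any_hit & !malformed)) {
    dxs <- unique(cohort$dx_codes[[i]])
    pxs <- unique(cohort$px_codes[[i]])
    inc_pxs <- if (strict_primary && length(pxs)) cohort$px_codes[[i]][1] else pxs
    fired_inclusion[[i]] <- rbind(
      with_axis(pairs_inc_dx[pairs_inc_dx$code %in% dxs, , drop = FALSE], "diagnosis"),
      with_axis(pairs_inc_px[pairs_inc_px$code %in% inc_pxs, , drop = FALSE], "procedure"))
    fired_exclusion[[i]] <- rbind(
      with_axis(pairs_exc_dx[pairs_exc_dx$code %in% dxs, , drop = FALSE], "diagnosis"),
      with_axis(pairs_exc_px[pairs_exc_px$code %in% pxs, , drop = FALSE], "procedure"))
  }

  out <- data.frame(record_id = cohort$record_id, label = label,
                    stringsAsFactors = FALSE)
  out$fired_inclusion <- fired_inclusion
  out$fired_exclusion <- fired_exclusion
  out$notes <- notes
  as_classification(out, sum(label == "positive"), sum(label == "negative"))
}

match_pairs <- function(patterns, codes) {
  codes <- unique(codes)
  patterns <- as.character(patterns)
  if (!length(patterns) || !length(codes)) return(empty_trace())
  hits <- lapply(patterns, function(p) codes[pattern_matches(p, codes)])
  data.frame(pattern = rep(patterns, lengths(hits)),
             code = unlist(hits, use.names = FALSE),
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

as_classification <- function(df, n_positive, n_negative) {
  structure(df, class = c("phenotype_classification", "data.frame"),
            n_positive = as.integer(n_positive),
            n_negative = as.integer(n_negative))
}

#' @export
print.phenotype_classification <- function(x, ...) {
  cat(sprintf("Phenotype classification: %d record(s), %d positive, %d negative\n",
              nrow(x), attr(x, "n_positive"), attr(x, "n_negative")))
  pos <- x$record_id[x$label == "positive"]
  if (length(pos))
    cat("  positive:", paste(utils::head(pos, 12), collapse = ", "),
        if (length(pos) > 12) sprintf("... (+%d)", length(pos) - 12) else "", "\n")
  invisible(x)
}

#' @export
summary.phenotype_classification <- function(object, ...) {
  c(n = nrow(object),
    n_positive = attr(object, "n_positive"),
    n_negative = attr(object, "n_negative"))
}
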