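#' Deterministic reconstruction of the validation cohort
#'
#' Rebuilds, from published marginal counts, the 10,925-operation single-
#' institution cohort on which the craniectomy-for-stroke phenotype was
#' validated.  The cohort is synthetic in the sense that record-level
#' linkage is reconstructed, but every count that the validation depends on
#' is reproduced exactly:
#'
#' * 46 gold-standard cases, with diagnosis codes distributed as
#'   433.11 x12, 434.01 x1, 434.11 x19, 434.91 x13, plus one case miscoded
#'   433.01 (basilar occlusion -- the algorithm's one false negative), and
#'   primary procedure codes 01.25 x31, 01.24 x9, 01.39 x1, 01.53 x4,
#'   01.59 x1.  Truth labels for concomitant excision of infarcted tissue
#'   (8 cases; 5 coded with an excision-type primary, 1 non-excision case
#'   so coded) and hemorrhagic conversion (15 cases; 10 carrying diagnosis
#'   431, plus 2 non-conversion cases carrying 431) are pinned so the
#'   secondary-indicator confusion matrices come out (5, 1, 3, 37) and
#'   (10, 2, 5, 29).
#' * The 6 false-positive records (intracerebral hemorrhage evacuations
#'   that satisfy the phenotype), codes as published.
#' * 33 posterior fossa craniectomies, all excluded by the algorithm via a
#'   vertebrobasilar diagnosis or the laminectomy code: 17 x 433.01,
#'   8 x 433.21, 4 x 443.24 (each with procedure 01.25), and 4 x diagnosis
#'   434.91 with procedures `[01.25, 03.09]`.
#' * 10,840 background operations carrying a fixed non-neurovascular code
#'   pair (722.10 lumbar disc displacement / 80.51 excision of
#'   intervertebral disc) that matches no pattern.
#'
#' Which particular case carries which co-code is not published; the
#' assignment here is fixed and lexicographic and cannot affect any
#' classification or metric.  Two calls return byte-identical cohorts.
#'
#' @return A [claims_cohort()] of 10,925 records with truth labels
#'   (`is_case` everywhere; `had_excision`, `had_hemorrhage` among cases).
#' @examples
#' coh <- build_paper_cohort()
#' nrow(coh)          # 10925
#' sum(coh$is_case)   # 46
#' @export
build_paper_cohort <- function() {
  # -- 46 gold-standard cases -------------------------------------------
  # record 1 is the miscoded (433.01) case; the remaining 45 pair the
  # sorted diagnosis distribution with the sorted primary-procedure
  # distribution index-wise.
  case_dx <- c("433.01",
               rep("433.11", 12), rep("434.01", 1),
               rep("434.11", 19), rep("434.91", 13))
  case_px <- c("01.25",
               rep("01.24", 9), rep("01.25", 30),
               rep("01.39", 1), rep("01.53", 4), rep("01.59", 1))
  n_case <- length(case_dx)  # 46
  # excision: coded-positive primaries are records 41:46; truth 8 cases
  had_excision <- rep(FALSE, n_case)
  had_excision[c(2, 3, 4, 41, 42, 43, 44, 45)] <- TRUE  # 3 FN + 5 TP; 46 is the FP
  # hemorrhagic conversion: truth 15 cases; 431 carried by 10 of them and
  # by 2 non-conversion cases
  had_hemorrhage <- rep(FALSE, n_case)
  had_hemorrhage[5:19] <- TRUE
  carries_431 <- seq_len(n_case) %in% c(5:14, 20, 21)
  case_dx_codes <- lapply(seq_len(n_case), function(i)
    if (carries_431[i]) c(case_dx[i], "431") else case_dx[i])

  # -- 6 false positives (published record for record) ------------------
  fp_px <- c("01.24", "01.39", "01.24", "01.39", "01.25", "01.39")
  fp_dx <- c("434.91", "434.11", "434.11", "434.91", "434.11", "434.91")

  # -- 33 posterior fossa craniectomies ---------------------------------
  pf_dx <- c(rep("433.01", 17), rep("433.21", 8), rep("443.24", 4),
             rep("434.91", 4))
  pf_px <- c(rep(list("01.25"), 29), rep(list(c("01.25", "03.09")), 4))

  # -- 10,840 background operations -------------------------------------
  n_bg <- 10840L

  claims_cohort(
    record_id = c(sprintf("case-%02d", seq_len(n_case)),
                  sprintf("fp-%d", seq_along(fp_dx)),
                  sprintf("pf-%02d", seq_along(pf_dx)),
                  sprintf("bg-%05d", seq_len(n_bg))),
    dx_codes = c(case_dx_codes, as.list(fp_dx), as.list(pf_dx),
                 rep(list("722.10"), n_bg)),
    px_codes = c(as.list(case_px), as.list(fp_px), pf_px,
                 rep(list("80.51"), n_bg)),
    is_case = c(rep(TRUE, n_case), rep(FALSE, length(fp_dx)),
                rep(FALSE, length(pf_dx)), rep(FALSE, n_bg)),
    had_excision = c(had_excision, rep(NA, length(fp_dx) + length(pf_dx) + n_bg)),
    had_hemorrhage = c(had_hemorrhage, rep(NA, length(fp_dx) + length(pf_dx) + n_bg))
  )
}

#' Seeded random claims-cohort generator
#'
#' Generates a reproducible synthetic cohort for property testing and
#' power exploration.  Each record is a true case with probability
#' `case_prevalence`.  A true case receives an inclusion-satisfying
#' diagnosis/procedure pair, except with probability `miscoding_rate` it
#' receives a near-miss diagnosis (433.01 or 433.10) and so escapes the
#' phenotype -- the generator's model of the miscoding that produced the
#' real cohort's false negative.  A non-case receives inclusion-satisfying
#' codes (a contaminant, the model of hematoma-evacuation false positives)
#' with probability `contamination_rate`; otherwise it is either a plain
#' background record or carries an exclusion code alongside stroke-like
#' codes, so exclusion logic is exercised.
#'
#' Consequently the expected sensitivity of the bundled phenotype on such a
#' cohort is `1 - miscoding_rate` and the expected false-positive count is
#' `n_records * (1 - case_prevalence) * contamination_rate`.
#'
#' @param n_records number of records (positive integer).
#' @param case_prevalence,miscoding_rate,contamination_rate proportions in
#'   `[0, 1]`.
#' @param seed integer seed; the caller's random-number state is left
#'   untouched.
#' @return A [claims_cohort()] with `is_case` truth labels.
#' @examples
#' coh <- generate_random_cohort(500, case_prevalence = 0.1, seed = 1)
#' summary(classify_cohort(coh, builtin_ruleset()))
#' @export
generate_random_cohort <- function(n_records, case_prevalence,
                                   miscoding_rate = 0,
                                   contamination_rate = 0, seed = 1L) {
  if (!is.numeric(n_records) || length(n_records) != 1L || n_records < 1 ||
      n_records != round(n_records))
    stop("n_records must be a positive integer", call. = FALSE)
  for (p in c(case_prevalence = case_prevalence,
              miscoding_rate = miscoding_rate,
              contamination_rate = contamination_rate))
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("case_prevalence, miscoding_rate and contamination_rate must lie in [0, 1]",
           call. = FALSE)
  n <- as.integer(n_records)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  rules <- builtin_ruleset()
  inc_dx <- as.character(rules$inclusion_diagnosis)
  inc_px <- as.character(rules$inclusion_procedure)
  near_miss_dx <- c("433.01", "433.10")
  exclusion_dx <- c("430", "852.21", "191.9", "801.20")

  is_case <- stats::runif(n) < case_prevalence
  dx <- rep(list("722.10"), n)
  px <- rep(list("80.51"), n)

  ci <- which(is_case)
  if (length(ci)) {
    miscoded <- stats::runif(length(ci)) < miscoding_rate
    good_dx <- sample(inc_dx, length(ci), replace = TRUE)
    miss_dx <- sample(near_miss_dx, length(ci), replace = TRUE)
    dx[ci] <- as.list(ifelse(miscoded, miss_dx, good_dx))
    px[ci] <- as.list(sample(inc_px, length(ci), replace = TRUE))
  }
  ni <- which(!is_case)
  if (length(ni)) {
    u <- stats::runif(length(ni))
    contaminated <- u < contamination_rate
    # a fifth of the remaining non-cases carry stroke-like codes plus an
    # exclusion code, so the exclusion arm of the rule set is exercised
    excluded_neg <- !contaminated & u < contamination_rate +
      0.2 * (1 - contamination_rate)
    ki <- ni[contaminated]
    if (length(ki)) {
      dx[ki] <- as.list(sample(inc_dx, length(ki), replace = TRUE))
      px[ki] <- as.list(sample(inc_px, length(ki), replace = TRUE))
    }
    ei <- ni[excluded_neg]
    if (length(ei)) {
      dx[ei] <- Map(c, sample(inc_dx, length(ei), replace = TRUE),
                    sample(exclusion_dx, length(ei), replace = TRUE))
      px[ei] <- as.list(sample(inc_px, length(ei), replace = TRUE))
    }
  }

  claims_cohort(record_id = sprintf("r%07d", seq_len(n)),
                dx_codes = dx, px_codes = px, is_case = is_case)
}
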