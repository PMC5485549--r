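rules <- builtin_ruleset()

rec <- function(dx, px) list(record_id = "r", dx_codes = dx, px_codes = px)

test_that("published single-record classifications reproduce", {
  # hematoma evacuation satisfying the phenotype (a known false positive)
  expect_identical(classify_record(rec("434.91", "01.24"), rules)$label, "positive")
  # the study's one false negative: stroke miscoded as basilar occlusion
  expect_identical(classify_record(rec("433.01", "01.25"), rules)$label, "negative")
  # traumatic subdural family overrides an otherwise-qualifying record
  expect_identical(classify_record(rec(c("434.11", "852.21"), "01.25"), rules)$label,
                   "negative")
  # laminectomy procedure code excludes a posterior fossa decompression
  expect_identical(classify_record(rec("434.91", c("01.25", "03.09")), rules)$label,
                   "negative")
})

test_that("a positive result explains itself and exclusions trace", {
  r <- classify_record(rec(c("434.91", "431"), "01.24"), rules)
  expect_identical(r$label, "positive")
  expect_true(any(r$fired_inclusion$axis == "diagnosis"))
  expect_true(any(r$fired_inclusion$axis == "procedure"))
  expect_identical(nrow(r$fired_exclusion), 0L)
  r2 <- classify_record(rec(c("434.11", "852.21"), "01.25"), rules)
  expect_identical(r2$fired_exclusion$pattern, "852.xx")
  expect_identical(r2$fired_exclusion$code, "852.21")
})

test_that("a record with no codes classifies negative with a warning note", {
  r <- classify_record(rec(character(), character()), rules)
  expect_identical(r$label, "negative")
  expect_match(r$notes, "no diagnosis or procedure codes")
})

test_that("strict-primary mode restricts inclusion procedure matching to position 1", {
  r <- rec("434.91", c("80.51", "01.25"))
  expect_identical(classify_record(r, rules)$label, "positive")
  expect_identical(classify_record(r, rules, strict_primary = TRUE)$label, "negative")
  # exclusion still sees every procedure position
  r2 <- rec("434.91", c("01.25", "03.09"))
  expect_identical(classify_record(r2, rules, strict_primary = TRUE)$label, "negative")
})

test_that("cohort classification is element-wise, order-preserving, and counts add up", {
  coh <- claims_cohort(
    record_id = c("a", "b", "c"),
    dx_codes = list("434.91", "433.01", "722.10"),
    px_codes = list("01.24", "01.25", "80.51"),
    is_case = c(TRUE, TRUE, FALSE)
  )
  res <- classify_cohort(coh, rules)
  expect_identical(res$record_id, c("a", "b", "c"))
  expect_identical(res$label, c("positive", "negative", "negative"))
  expect_identical(attr(res, "n_positive") + attr(res, "n_negative"), nrow(coh))
  # empty cohort
  empty <- claims_cohort(character(), list(), list())
  res0 <- classify_cohort(empty, rules)
  expect_identical(nrow(res0), 0L)
  expect_identical(unname(summary(res0)[c("n_positive", "n_negative")]), c(0L, 0L))
  # no inclusion diagnosis anywhere -> no positives
  coh10 <- claims_cohort(sprintf("n%02d", 1:10),
                         dx_codes = rep(list("722.10"), 10),
                         px_codes = rep(list("01.25"), 10))
  expect_identical(attr(classify_cohort(coh10, rules), "n_positive"), 0L)
})

test_that("duplicate record ids are a cohort-integrity error", {
  expect_error(claims_cohort(c("a", "a"), list("434.91", "434.91"),
                             list("01.24", "01.24")),
               "duplicate record_id")
  df <- data.frame(record_id = c("a", "a"), stringsAsFactors = FALSE)
  df$dx_codes <- list("434.91", "434.91")
  df$px_codes <- list("01.24", "01.24")
  expect_error(classify_cohort(df, rules), "duplicate record_id")
})

test_that("labels are invariant to diagnosis order and non-primary procedure order", {
  set.seed(41)
  universe <- random_record_universe()
  for (i in 1:40) {
    r <- random_record(universe)
    if (length(r$dx) < 2 && length(r$px) < 3) next
    base <- classify_record(rec(r$dx, r$px), rules)$label
    perm_dx <- classify_record(rec(sample(r$dx), r$px), rules)$label
    expect_identical(perm_dx, base)
    if (length(r$px) >= 3) {
      perm_px <- c(r$px[1], sample(r$px[-1]))
      expect_identical(classify_record(rec(r$dx, perm_px), rules)$label, base)
    }
  }
})

test_that("adding an exclusion code flips a positive; adding a non-matching code never changes the label", {
  set.seed(42)
  universe <- random_record_universe()
  for (i in 1:60) {
    r <- random_record(universe)
    base <- classify_record(rec(r$dx, r$px), rules)$label
    if (base == "positive") {
      flipped <- classify_record(rec(c(r$dx, "430"), r$px), rules)$label
      expect_identical(flipped, "negative")
    }
    with_neutral <- classify_record(rec(c(r$dx, "401.9"), r$px), rules)$label
    expect_identical(with_neutral, base)
  }
})

test_that("classifier agrees with the naive pair-enumeration oracle on random small records", {
  set.seed(20123)
  universe <- random_record_universe()
  coh_dx <- list(); coh_px <- list()
  for (i in 1:250) {
    r <- random_record(universe)
    expect_identical(classify_record(rec(r$dx, r$px), rules)$label,
                     oracle_classify(r$dx, r$px, rules),
                     label = sprintf("record dx={%s} px={%s}",
                                     paste(r$dx, collapse = ","),
                                     paste(r$px, collapse = ",")))
    coh_dx[[i]] <- r$dx; coh_px[[i]] <- r$px
  }
  # and the vectorized cohort path agrees record for record
  coh <- claims_cohort(sprintf("r%03d", 1:250), coh_dx, coh_px)
  res <- classify_cohort(coh, rules)
  expect_identical(res$label,
                   mapply(oracle_classify, coh_dx, coh_px,
                          MoreArgs = list(rules = rules), USE.NAMES = FALSE))
  # strict-primary path too
  res_sp <- classify_cohort(coh, rules, strict_primary = TRUE)
  oracle_sp <- mapply(function(dx, px)
    oracle_classify(dx, if (length(px)) px[1] else character(), rules),
    coh_dx, coh_px, USE.NAMES = FALSE)
  # exclusion procedures still act on all positions under strict-primary
  oracle_sp[vapply(coh_px, function(p) "03.09" %in% p, logical(1))] <- "negative"
  expect_identical(res_sp$label, oracle_sp)
})

test_that("positive results satisfy the trace invariants", {
  set.seed(7)
  universe <- random_record_universe()
  for (i in 1:60) {
    r <- random_record(universe)
    out <- classify_record(rec(r$dx, r$px), rules)
    if (out$label == "positive") {
      expect_true(any(out$fired_inclusion$axis == "diagnosis"))
      expect_true(any(out$fired_inclusion$axis == "procedure"))
      expect_identical(nrow(out$fired_exclusion), 0L)
    }
    if (nrow(out$fired_exclusion) > 0)
      expect_identical(out$label, "negative")
  }
})
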