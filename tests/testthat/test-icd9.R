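test_that("dotted and undotted dialects normalize to the same canonical form", {
  cases <- list(
    list(raw = "43311", axis = "diagnosis", want = "433.11"),
    list(raw = "433.11", axis = "diagnosis", want = "433.11"),
    list(raw = "430", axis = "diagnosis", want = "430"),
    list(raw = "3240", axis = "diagnosis", want = "324.0"),
    list(raw = "324.0", axis = "diagnosis", want = "324.0"),
    list(raw = "0125", axis = "procedure", want = "01.25"),
    list(raw = "01.25", axis = "procedure", want = "01.25"),
    list(raw = " 0309 ", axis = "procedure", want = "03.09")
  )
  for (cs in cases)
    expect_identical(icd9_normalize(cs$raw, cs$axis), cs$want,
                     label = sprintf("normalize(%s, %s)", cs$raw, cs$axis))
  # idempotence on every canonical literal of the bundled rule set
  rs <- builtin_ruleset()
  pats <- unlist(lapply(rs[c("inclusion_diagnosis", "exclusion_diagnosis")],
                        as.character))
  for (p in pats[!grepl("x", pats)]) {
    expect_identical(icd9_normalize(p, "diagnosis"), p)
    expect_identical(icd9_normalize(gsub(".", "", p, fixed = TRUE), "diagnosis"), p,
                     label = sprintf("undotted round-trip of %s", p))
  }
  for (p in as.character(rs$inclusion_procedure)) {
    expect_identical(icd9_normalize(p, "procedure"), p)
    expect_identical(icd9_normalize(gsub(".", "", p, fixed = TRUE), "procedure"), p)
  }
})

test_that("malformed codes are rejected with the offending text", {
  expect_error(icd9_normalize("4.3.1", "diagnosis"), "4\\.3\\.1")
  expect_error(icd9_normalize("", "diagnosis"), "empty")
  expect_error(icd9_normalize("43", "diagnosis"), "root")
  expect_error(icd9_normalize("433.115", "diagnosis"), "two characters")
  expect_error(icd9_normalize("V45.1", "diagnosis"), "V45\\.1")
  expect_error(icd9_normalize("E880.1", "diagnosis"), "E880\\.1")
  expect_error(icd9_normalize("1.25", "procedure"), "root")
  # wildcards are a pattern-only privilege
  expect_error(icd9_normalize("800.xx", "diagnosis"), "wildcard")
  expect_identical(icd9_normalize("800.xx", "diagnosis", wildcard = TRUE), "800.xx")
  expect_identical(icd9_normalize("800XX", "diagnosis", wildcard = TRUE), "800.xx")
  expect_error(icd9_normalize("8x0.01", "diagnosis", wildcard = TRUE), "8x0")
})

test_that("leading zeros in procedure roots are preserved", {
  expect_identical(as.character(icd9("01.25", "procedure")), "01.25")
  expect_identical(as.character(icd9("0125", "procedure")), "01.25")
  expect_false(identical(as.character(icd9("0125", "procedure")), "1.25"))
})

test_that("exact and wildcard patterns match by prefix family semantics", {
  expect_true(pattern_matches("800.xx", "800.21"))
  expect_true(pattern_matches("191.x", "191.9"))
  expect_false(pattern_matches("433.11", "433.10"))
  expect_true(pattern_matches("433.11", "433.11"))
  # the bare category root is part of its own family
  expect_true(pattern_matches("800.xx", "800"))
  # one and two wildcard characters denote the same family
  expect_identical(pattern_matches("191.x", c("191.9", "191.95", "191")),
                   pattern_matches("191.xx", c("191.9", "191.95", "191")))
  # prefix must not leak across the category boundary
  expect_false(pattern_matches("800.xx", "801.21"))
  expect_false(pattern_matches("191.x", "1919"))
})

test_that("axis mismatch between classed pattern and code is an error", {
  p <- icd9_pattern("01.25", "procedure")
  d <- icd9("433.11", "diagnosis")
  expect_error(pattern_matches(p, d), "axis mismatch")
  expect_error(any_match(p, d), "axis mismatch")
})

test_that("matcher agrees with brute-force family enumeration over the trauma and neoplasm universes", {
  universe <- c(trauma_universe(), neoplasm_universe(),
                sprintf("%d", 800:854), "191")
  patterns <- c(sprintf("%d.xx", 800:854), "191.x")
  for (p in patterns) {
    family <- enumerate_family(p)
    expect_identical(pattern_matches(p, universe), universe %in% family,
                     label = sprintf("family of %s", p))
  }
})

test_that("an exact pattern matches exactly one element of a duplicate-free universe", {
  universe <- unique(c(trauma_universe(), neoplasm_universe(), "433.11", "430"))
  for (p in c("800.21", "854.99", "191.9", "433.11", "430"))
    expect_identical(sum(pattern_matches(p, universe)), 1L)
})

test_that("any_match reports the full matching-pair trace", {
  out <- any_match(c("434.11"), c("434.11", "431"))
  expect_true(out$match)
  expect_identical(out$trace,
                   data.frame(pattern = "434.11", code = "434.11",
                              stringsAsFactors = FALSE))
  expect_false(any_match(c("800.xx", "801.xx"), "434.11")$match)
  expect_false(any_match(character(), "434.11")$match)
  expect_false(any_match(c("800.xx"), character())$match)
  # duplicate codes collapse to one trace row
  dup <- any_match("800.xx", c("800.21", "800.21"))
  expect_identical(nrow(dup$trace), 1L)
})
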