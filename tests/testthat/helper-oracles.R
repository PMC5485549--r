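# Independent oracles used by the property tests.  These deliberately share
# no code with the package: families are enumerated member by member, rules
# are evaluated by explicit double loops, and Clopper-Pearson endpoints are
# found by root-finding on binomial tail sums.

# every canonical code a wildcard category pattern denotes, by enumeration
enumerate_family <- function(pattern) {
  root <- sub("\\..*$", "", pattern)
  c(root, paste0(root, ".", 0:9), sprintf("%s.%02d", root, 0:99))
}

# the enumerated diagnosis universes the matcher properties run over
trauma_universe <- function() {
  as.vector(vapply(800:854, function(r) sprintf("%d.%02d", r, 0:99),
                   character(100)))
}
neoplasm_universe <- function() sprintf("191.%d", 0:9)

# brute-force single pattern/code match (substring arithmetic only)
oracle_match <- function(pattern, code) {
  if (!grepl("x", pattern, fixed = TRUE)) return(identical(pattern, code))
  prefix <- substr(pattern, 1, regexpr("x", pattern, fixed = TRUE) - 1)
  identical(substr(code, 1, nchar(prefix)), prefix) ||
    identical(code, sub("\\.$", "", prefix))
}

# naive rule-set evaluator: enumerate every (pattern, code) pair
oracle_classify <- function(dx, px, rules) {
  hit <- function(patterns, codes) {
    for (p in as.character(patterns)) for (cd in codes)
      if (oracle_match(p, cd)) return(TRUE)
    FALSE
  }
  included <- hit(rules$inclusion_diagnosis, dx) &&
    hit(rules$inclusion_procedure, px)
  excluded <- hit(rules$exclusion_diagnosis, dx) ||
    hit(rules$exclusion_procedure, px)
  if (included && !excluded) "positive" else "negative"
}

# Clopper-Pearson by exhaustive binomial-tail summation + root finding
oracle_exact_ci <- function(s, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (s == 0) 0 else
    stats::uniroot(function(p) sum(stats::dbinom(s:n, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (s == n) 1 else
    stats::uniroot(function(p) sum(stats::dbinom(0:s, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# small random records over a mixed 40-code universe
random_record_universe <- function() {
  list(
    dx = c("433.11", "434.01", "434.11", "434.91",      # inclusion
           "433.01", "433.21", "443.24", "430", "431",  # exclusion/near-miss
           "198.3", "324.0", "437.3", "191.9", "800.21", "852.21", "854.00",
           "433.10", "434.00", "436", "722.10", "401.9", "250.00",
           "437.1", "438.11", "997.02", "331.4", "348.5", "348.4",
           "853.01", "801.35"),
    px = c("01.24", "01.25", "01.39", "01.53", "01.59",
           "03.09", "80.51", "02.34", "01.23", "39.28")
  )
}

random_record <- function(universe) {
  list(dx = sample(universe$dx, sample(0:4, 1)),
       px = sample(universe$px, sample(0:2, 1)))
}
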