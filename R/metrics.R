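#' Confusion matrix of a binary classifier against gold-standard truth
#'
#' @param predicted logical vector of classifier calls.
#' @param truth logical vector of gold-standard labels, same length, no
#'   missing values.
#' @return An object of class `"confusion_matrix"`: a list with integer
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_matrix(c(TRUE, FALSE), c(TRUE, TRUE))
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length", call. = FALSE)
  if (anyNA(predicted) || anyNA(truth))
    stop("missing values in predicted or truth labels", call. = FALSE)
  new_confusion(tp = sum(predicted & truth),
                fp = sum(predicted & !truth),
                fn = sum(!predicted & truth),
                tn = sum(!predicted & !truth))
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn non-negative integer counts, for building a confusion
#'   matrix directly from published counts.
#' @export
new_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  counts <- stats::setNames(as.list(as.integer(counts)), names(counts))
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`
#' and correct classification `(tp+tn)/total`.  A metric whose denominator
#' is zero is *undefined*, never silently zero: its estimate is `NA` and
#' its display string is `"undefined"`.
#'
#' Display percentages are rounded half away from zero to one decimal
#' place (`37/38` displays as `97.4`, `42/46` as `91.3`).  Optional exact
#' (Clopper-Pearson) binomial confidence intervals are attached per metric;
#' the paper-style point estimates need none, but small validation subsets
#' warrant them.
#'
#' @param cm a [confusion_matrix()].
#' @param ci_level two-sided confidence level for exact binomial intervals,
#'   or `NULL` to skip them.
#' @return A data frame of class `"validation_metrics"` with columns
#'   `metric`, `numerator`, `denominator`, `estimate` (proportion in
#'   `[0, 1]` or `NA` when undefined), `pct_display` (character, percent to
#'   one decimal or `"undefined"`), `ci_low`, `ci_high`.
#' @examples
#' compute_metrics(new_confusion(45, 6, 1, 10873))
#' @export
compute_metrics <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  rows <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn),
    correct_classification = c(cm$tp + cm$tn, total)
  )
  out <- data.frame(
    metric = names(rows),
    numerator = vapply(rows, `[`, numeric(1), 1L),
    denominator = vapply(rows, `[`, numeric(1), 2L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$estimate <- ifelse(out$denominator > 0,
                         out$numerator / out$denominator, NA_real_)
  out$pct_display <- ifelse(is.na(out$estimate), "undefined",
                            format_pct(out$estimate))
  if (!is.null(ci_level)) {
    ci <- t(mapply(function(s, t) {
      if (t == 0) c(NA_real_, NA_real_) else exact_binomial_ci(s, t, ci_level)
    }, out$numerator, out$denominator))
    out$ci_low <- ci[, 1]
    out$ci_high <- ci[, 2]
  } else {
    out$ci_low <- out$ci_high <- NA_real_
  }
  class(out) <- c("validation_metrics", "data.frame")
  out
}

#' @export
print.validation_metrics <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 4)
  df$ci_low <- round(df$ci_low, 4)
  df$ci_high <- round(df$ci_high, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical percentages
#' round half away from zero (`91.25` to `91.3`), so display formatting
#' uses this rule.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pct <- function(p) {
  formatC(round_half_up(100 * p, 1), format = "f", digits = 1)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, computed from beta
#' quantiles: lower = `qbeta(alpha/2, s, n - s + 1)`, upper =
#' `qbeta(1 - alpha/2, s + 1, n - s)`, with the standard boundary
#' conventions lower = 0 when `s = 0` and upper = 1 when `s = n`.
#'
#' @param successes,trials non-negative integers, `successes <= trials`.
#' @param level two-sided confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' exact_binomial_ci(45, 46)
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single number in (0, 1)", call. = FALSE)
  if (trials < 0 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop("successes and trials must be integers with 0 <= successes <= trials",
         call. = FALSE)
  if (trials == 0) stop("trials must be positive", call. = FALSE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Validate a phenotype rule set against gold-standard labels
#'
#' Classifies a cohort, compares the phenotype label with a truth column,
#' and returns the confusion matrix and accuracy metrics.
#'
#' @param cohort a [claims_cohort()] carrying the truth column.
#' @param rules a [phenotype_ruleset()].
#' @param truth_column name of the logical truth column (default
#'   `"is_case"`); records with a missing truth label are an error.
#' @inheritParams classify_record
#' @inheritParams compute_metrics
#' @return list with elements `results` (the
#'   [classify_cohort()] output), `confusion` and `metrics`.
#' @export
validate_cohort <- function(cohort, rules, truth_column = "is_case",
                            ci_level = 0.95, strict_primary = FALSE) {
  if (!truth_column %in% names(cohort))
    stop(sprintf("truth column '%s' not present in cohort", truth_column),
         call. = FALSE)
  truth <- cohort[[truth_column]]
  if (anyNA(truth))
    stop(sprintf("truth column '%s' has missing labels", truth_column),
         call. = FALSE)
  results <- classify_cohort(cohort, rules, strict_primary = strict_primary)
  cm <- confusion_matrix(results$label == "positive", truth)
  list(results = results, confusion = cm,
       metrics = compute_metrics(cm, ci_level = ci_level))
}
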