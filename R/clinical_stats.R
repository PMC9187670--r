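# Trial clinical statistics: exact binomial confidence intervals, response
# rates, the RPED association test and RPED event summaries, computed from
# the packaged count-table fixtures.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inversion of the binomial tail probabilities via beta quantiles:
#' lower = qbeta(a/2; x, n - x + 1), upper = qbeta(1 - a/2; x + 1, n - x),
#' with lower = 0 at x = 0 and upper = 100 at x = n. Returned in percent.
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (>= 1).
#' @param level confidence level in (0, 1).
#' @return numeric `c(lower, upper)` in percent.
#' @examples
#' round(clopper_pearson_ci(13, 50), 1)  # 14.6 40.3
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stop_if_not(is_count(n) && n >= 1, "`n` must be a positive integer")
  stop_if_not(is_count(x) && x <= n, "`x` must be an integer in [0, n]")
  stop_if_not(level > 0 && level < 1, "`level` must be in (0, 1)")
  a <- 1 - level
  lower <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  100 * c(lower = lower, upper = upper)
}

#' Pearson chi-square test on a 2x2 table
#'
#' 1 degree of freedom, no continuity correction; p from the chi-square
#' upper tail. Set `fisher = TRUE` for Fisher's exact test instead.
#'
#' @param table 2x2 non-negative integer matrix with positive margins.
#' @param fisher use Fisher's exact test.
#' @return list: `statistic` (chi-square; `NA` for Fisher), `p.value`.
#' @export
chi2_2x2 <- function(table, fisher = FALSE) {
  stop_if_not(is.matrix(table) && all(dim(table) == 2) &&
                all(table >= 0) && all(table == floor(table)),
              "`table` must be a 2x2 non-negative integer matrix")
  stop_if_not(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "table has a zero margin")
  if (fisher) {
    ft <- stats::fisher.test(table)
    return(list(statistic = NA_real_, p.value = ft$p.value))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}

#' Load the packaged tumour-assessment count table
#'
#' Central-review response category counts at weeks 6, 12, 20 and 28 for
#' the 52 enrolled subjects (50 assessable by central review; 5 partial
#' responses confirmed at any time during follow-up).
#'
#' @return list: `counts` (category x timepoint matrix), `n_enrolled`,
#'   `n_assessable`, `pr_any_time`.
#' @export
load_response_counts <- function() {
  path <- system.file("extdata", "response_counts.tsv",
                      package = "tmadtools", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1])
  rownames(counts) <- tab$category
  meta <- readLines(path)
  meta <- meta[startsWith(meta, "#")]
  getm <- function(key) {
    ln <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    as.integer(sub(".*=", "", ln))
  }
  list(counts = counts, n_enrolled = getm("n_enrolled"),
       n_assessable = getm("n_assessable"),
       pr_any_time = getm("pr_any_time"))
}

#' Response rates with exact confidence intervals
#'
#' Computes, per timepoint, the objective response rate (ORR = CR + PR over
#' enrolled) and the clinical benefit rates: at week 12, CBR = CR + PR + SD
#' over enrolled; at week 28, CBR = (PR at any time) + (SD at week 28),
#' reported over assessable subjects and on an intention-to-treat basis
#' over enrolled subjects. All intervals are exact Clopper-Pearson.
#'
#' @param resp output of [load_response_counts()] (or a like-shaped list).
#' @param level confidence level.
#' @return data frame with columns `statistic`, `timepoint`, `x`, `n`,
#'   `rate_pct`, `ci_lower_pct`, `ci_upper_pct`.
#' @export
response_rates <- function(resp = load_response_counts(), level = 0.95) {
  counts <- resp$counts
  n_enr <- resp$n_enrolled
  stop_if_not(all(colSums(counts) == n_enr),
              "category counts must sum to n_enrolled at every timepoint")
  rows <- list()
  add <- function(statistic, timepoint, x, n) {
    stop_if_not(x <= n, "numerator %d exceeds denominator %d", x, n)
    ci <- clopper_pearson_ci(x, n, level)
    rows[[length(rows) + 1]] <<- data.frame(
      statistic = statistic, timepoint = timepoint, x = x, n = n,
      rate_pct = 100 * x / n, ci_lower_pct = ci[[1]],
      ci_upper_pct = ci[[2]], stringsAsFactors = FALSE)
  }
  for (tp in colnames(counts)) {
    orr <- counts["CR", tp] + counts["PR", tp]
    add("ORR", tp, orr, n_enr)
  }
  add("CBR", "wk12", counts["CR", "wk12"] + counts["PR", "wk12"] +
        counts["SD", "wk12"], n_enr)
  cbr28 <- resp$pr_any_time + counts["SD", "wk28"]
  add("CBR", "wk28", cbr28, resp$n_assessable)
  add("CBR_ITT", "wk28", cbr28, n_enr)
  do.call(rbind, rows)
}

#' Load the packaged RPED event records
#'
#' Per-eye retinal pigment epithelial detachment records (time to
#' diagnosis and duration in months, outcome) for the 11 affected
#' subjects.
#'
#' @return data frame, one row per affected eye.
#' @export
load_rped_records <- function() {
  path <- system.file("extdata", "rped_records.tsv",
                      package = "tmadtools", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Summarise RPED onset and duration
#'
#' Reduces per-eye records to one value per subject first (the
#' earliest-onset eye supplies that subject's time to diagnosis and
#' duration), then reports the median and min-max range across subjects.
#'
#' @param records data frame with columns `subject`,
#'   `time_to_diagnosis_months`, `duration_months` (one row per eye).
#' @return list: `time_to_diagnosis` and `duration`, each with `median` and
#'   `range` (months).
#' @export
rped_summary <- function(records = load_rped_records()) {
  stop_if_not(nrow(records) >= 1, "need at least one record")
  per_subject <- lapply(split(records, records$subject), function(d) {
    k <- which.min(d$time_to_diagnosis_months)
    c(time = d$time_to_diagnosis_months[k], duration = d$duration_months[k])
  })
  m <- do.call(rbind, per_subject)
  stop_if_not(all(m > 0), "times and durations must be positive")
  list(time_to_diagnosis = list(median = median(m[, "time"]),
                                range = range(m[, "time"])),
       duration = list(median = median(m[, "duration"]),
                       range = range(m[, "duration"])))
}

#' Load the packaged RPED x clinical-benefit subject table
#' @return data frame with columns `subject`, `benefit`
#'   (benefit/no_benefit/unassessable), `rped` (logical).
#' @export
load_rped_benefit <- function() {
  path <- system.file("extdata", "rped_benefit.tsv",
                      package = "tmadtools", mustWork = TRUE)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  d$rped <- as.logical(d$rped)
  d
}

#' Cross-tabulate RPED occurrence against clinical benefit
#'
#' Builds the 2x2 table (rows: RPED yes/no; columns: benefit / no benefit);
#' subjects with unassessable benefit are excluded.
#'
#' @param subjects data frame with `benefit` and `rped` columns, see
#'   [load_rped_benefit()].
#' @return 2x2 integer matrix.
#' @export
rped_benefit_table <- function(subjects = load_rped_benefit()) {
  stop_if_not(nrow(subjects) >= 1, "empty subject table")
  stop_if_not(all(subjects$benefit %in%
                    c("benefit", "no_benefit", "unassessable")),
              "unknown benefit label: %s",
              paste(setdiff(subjects$benefit,
                            c("benefit", "no_benefit", "unassessable")),
                    collapse = ", "))
  d <- subjects[subjects$benefit != "unassessable", ]
  tab <- matrix(c(sum(d$rped & d$benefit == "benefit"),
                  sum(d$rped & d$benefit == "no_benefit"),
                  sum(!d$rped & d$benefit == "benefit"),
                  sum(!d$rped & d$benefit == "no_benefit")),
                nrow = 2,
                dimnames = list(benefit = c("benefit", "no_benefit"),
                                rped = c("rped", "no_rped")))
  tab
}

#' Full clinical report
#'
#' Recomputes every packaged clinical statistic: response rates with exact
#' intervals, the RPED-benefit association and the RPED event summaries.
#'
#' @param level confidence level for the intervals.
#' @return list with elements `rates`, `rped_association`, `rped_events`.
#' @export
clinical_report <- function(level = 0.95) {
  rates <- response_rates(level = level)
  tab <- rped_benefit_table()
  assoc <- chi2_2x2(tab)
  events <- rped_summary()
  list(rates = rates,
       rped_association = list(table = tab, chi2 = assoc$statistic,
                               p.value = assoc$p.value),
       rped_events = events)
}
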