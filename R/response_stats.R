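# Response-group stratification of t-MAD scores: Wilcoxon rank-sum tests
# and boxplot summary statistics.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with an exact mode by full enumeration of the
#' \eqn{\binom{n_x+n_y}{n_x}} group assignments (midranks, so ties are
#' handled) and a normal-approximation mode with tie correction and
#' continuity correction. `"auto"` uses exact enumeration when
#' `length(x) + length(y) <= 12` and there are no ties, otherwise the
#' normal approximation.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list: `statistic` (U for the first sample), `p.value`, `mode`
#'   actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stop_if_not(length(x) >= 1 && length(y) >= 1,
              "both groups must be non-empty")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "inputs must be finite")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  has_ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  used <- mode
  if (mode == "auto") used <- if (n <= 12 && !has_ties) "exact" else "normal"

  if (used == "exact") {
    stop_if_not(choose(n, nx) <= 5e5,
                "exact enumeration infeasible for these group sizes")
    mu <- nx * ny / 2
    obs_dev <- abs(U - mu)
    sets <- combn(n, nx)
    rs <- colSums(matrix(r[sets], nrow = nx))
    Us <- rs - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= obs_dev - 1e-9)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(statistic = U, p.value = p, mode = used)
}

#' Pairwise group comparisons of t-MAD at one timepoint
#'
#' Wilcoxon rank-sum tests for PD vs SD, PD vs PR and SD vs PR on the
#' per-sample scores at the requested timepoint, plus group medians and
#' sizes. P-values are reported raw (no multiplicity adjustment). A group
#' absent at the timepoint makes its comparisons unavailable (`NA`) rather
#' than an error.
#'
#' @param table a response-cohort data frame with columns `group`,
#'   `timepoint`, `tmad`.
#' @param timepoint the timepoint label to analyse.
#' @param mode test mode, see [wilcoxon_rank_sum()].
#' @return list: `comparisons` (data frame of pair, U, p), `medians`, `n`.
#' @export
compare_groups <- function(table, timepoint, mode = "auto") {
  stop_if_not(all(c("group", "timepoint", "tmad") %in% names(table)),
              "table needs group, timepoint, tmad columns")
  sub <- table[table$timepoint == timepoint, ]
  groups <- c("PR", "SD", "PD")
  vals <- lapply(groups, function(g) sub$tmad[sub$group == g])
  names(vals) <- groups
  pairs <- list(c("PD", "SD"), c("PD", "PR"), c("SD", "PR"))
  res <- lapply(pairs, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    if (length(a) == 0 || length(b) == 0)
      return(c(U = NA_real_, p = NA_real_))
    w <- wilcoxon_rank_sum(a, b, mode = mode)
    c(U = w$statistic, p = w$p.value)
  })
  comparisons <- data.frame(
    pair = vapply(pairs, paste, "", collapse = "_vs_"),
    U = vapply(res, `[[`, 0.0, "U"),
    p = vapply(res, `[[`, 0.0, "p"), stringsAsFactors = FALSE)
  list(comparisons = comparisons,
       medians = vapply(vals, function(v)
         if (length(v)) median(v) else NA_real_, 0.0),
       n = vapply(vals, length, 0L))
}

#' Boxplot summary statistics per response group
#'
#' Median, quartiles and 10th/90th percentiles per group, using the
#' linear-interpolation percentile definition (R quantile type 7) so plots
#' are exactly reproducible.
#'
#' @param table data frame with `group` and `tmad` columns.
#' @return data frame, one row per group present, columns `group`, `n`,
#'   `p10`, `q1`, `median`, `q3`, `p90`.
#' @export
summarize_boxplot_stats <- function(table) {
  stop_if_not(all(c("group", "tmad") %in% names(table)),
              "table needs group and tmad columns")
  groups <- unique(table$group)
  out <- lapply(groups, function(g) {
    v <- table$tmad[table$group == g]
    q <- quantile(v, probs = c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                  names = FALSE)
    data.frame(group = g, n = length(v), p10 = q[1], q1 = q[2],
               median = q[3], q3 = q[4], p90 = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
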