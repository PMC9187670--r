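# Preprocessing chain: downsampling, GC/mappability correction, static
# blacklist masking, control normalisation and log2 ratios.

#' Downsample a sample's bin counts to a target total
#'
#' Without-replacement thinning: the retained reads follow a multivariate
#' hypergeometric distribution over bins (drawn exactly via sequential
#' hypergeometric sampling), so the returned total equals `target_total`
#' exactly and no bin count ever increases.
#'
#' @param sample a `sample_counts` object.
#' @param target_total reads to retain.
#' @param seed RNG seed.
#' @param allow_smaller if `TRUE`, a `target_total` above the available total
#'   returns the sample unchanged (with a warning) instead of erroring.
#' @return a `sample_counts` object with `total_reads == target_total`.
#' @export
downsample_counts <- function(sample, target_total, seed = NULL,
                              allow_smaller = FALSE) {
  stop_if_not(inherits(sample, "sample_counts"),
              "`sample` must be a sample_counts object")
  stop_if_not(is_count(target_total), "`target_total` must be a count")
  total <- sum(sample$counts)
  if (target_total > total) {
    if (!allow_smaller)
      stop(sprintf(paste0("target_total (%d) exceeds available reads (%d); ",
                          "set allow_smaller = TRUE to keep the sample as is"),
                   as.integer(target_total), as.integer(total)), call. = FALSE)
    warning("fewer reads than target; returning sample unchanged")
    return(sample)
  }
  if (target_total == total) return(sample)
  set_seed_if(seed)
  counts <- sample$counts
  kept <- integer(length(counts))
  remaining <- total
  need <- as.integer(target_total)
  for (i in seq_along(counts)) {
    if (need == 0L) break
    ci <- counts[i]
    if (ci == 0L) next
    k <- rhyper(1, ci, remaining - ci, need)
    kept[i] <- k
    need <- need - k
    remaining <- remaining - ci
  }
  out <- sample
  out$counts <- kept
  out$total_reads <- sum(kept)
  out
}

# Fit a strictly positive expected-count surface over (gc, mappability).
# Returns fitted values; falls back from 2D LOESS to mappability-only LOESS
# (degenerate GC) to a stratified-median surface.
fit_bias_surface <- function(y, gc, mappability, method = "loess_2d",
                             span = 0.3, degree = 2) {
  usable <- is.finite(y) & is.finite(gc) & is.finite(mappability)
  fitted <- rep(NA_real_, length(y))
  strat_fit <- function() {
    # deciles of GC x binary mappability split; cell medians as the surface
    gq <- unique(quantile(gc[usable], probs = seq(0, 1, 0.1), names = FALSE))
    gcut <- cut(gc, breaks = gq, include.lowest = TRUE)
    msplit <- mappability >= median(mappability[usable])
    cell <- interaction(gcut, msplit, drop = TRUE)
    med <- tapply(y[usable], cell[usable], median)
    out <- as.numeric(med[as.character(cell)])
    out[is.na(out)] <- median(y[usable])
    out
  }
  if (method == "stratified_median") {
    fitted <- strat_fit()
  } else {
    dat <- data.frame(y = y, gc = gc, map = mappability)[usable, ]
    fml <- if (sd(dat$gc) < 1e-8) {
      warning("degenerate GC distribution; falling back to mappability-only correction")
      if (sd(dat$map) < 1e-8) NULL else y ~ map
    } else if (sd(dat$map) < 1e-8) y ~ gc else y ~ gc + map
    if (is.null(fml)) {
      fitted[usable] <- mean(dat$y)
    } else {
      fit <- tryCatch(
        loess(fml, data = dat, span = span, degree = degree,
              family = "symmetric"),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("LOESS fit failed; using stratified-median surface")
        fitted <- strat_fit()
      } else {
        fitted[usable] <- predict(fit, newdata = dat)
      }
    }
  }
  # strictly positive surface
  floor_val <- 1e-3 * max(mean(y[usable]), 1e-8)
  pmax(fitted, floor_val)
}

#' Correct bin counts for GC content and mappability
#'
#' Divides raw counts by a fitted expected-count surface over
#' (GC, mappability) and rescales so the mean over usable bins equals the
#' raw mean. The default surface is a robust 2D LOESS (span 0.3, degree 2);
#' a stratified-median surface (GC deciles x binary mappability split) is
#' available and also serves as the fallback when LOESS fails.
#'
#' @param sample a `sample_counts` object or a numeric vector of counts.
#' @param grid the matching bin grid.
#' @param method `"loess_2d"` or `"stratified_median"`.
#' @param span,degree LOESS parameters.
#' @return numeric vector of corrected counts (same length as the grid).
#' @export
correct_gc_mappability <- function(sample, grid,
                                   method = c("loess_2d", "stratified_median"),
                                   span = 0.3, degree = 2) {
  method <- match.arg(method)
  y <- if (inherits(sample, "sample_counts")) as.numeric(sample$counts)
       else as.numeric(sample)
  stop_if_not(length(y) == nrow(grid), "counts and grid differ in length")
  usable <- is.finite(y)
  stop_if_not(sum(usable) >= 50, "need >= 50 usable bins, got %d", sum(usable))
  fitted <- fit_bias_surface(y, grid$gc, grid$mappability, method = method,
                             span = span, degree = degree)
  corrected <- y / fitted
  ok <- is.finite(corrected)
  scale <- mean(y[usable & ok]) / mean(corrected[ok], na.rm = TRUE)
  corrected * scale
}

#' Mask static-blacklisted bins
#'
#' Sets values at bins flagged in the grid's static blacklist (the public
#' exclusion-list analogue) to `NA`. The number of newly masked bins is
#' attached as attribute `n_masked`.
#'
#' @param values numeric vector (counts or corrected counts) per bin.
#' @param grid the bin grid carrying `static_blacklist` flags.
#' @return the masked vector.
#' @export
apply_static_blacklist <- function(values, grid) {
  stop_if_not(length(values) == nrow(grid), "values and grid differ in length")
  out <- values
  out[grid$static_blacklist] <- NA_real_
  if (all(is.na(out))) stop("no usable bins remain after static blacklist",
                            call. = FALSE)
  attr(out, "n_masked") <- sum(grid$static_blacklist)
  out
}

#' Median-normalise a healthy control
#'
#' Scales the control so its median over usable (non-`NA`) bins equals 1.
#'
#' @param control numeric vector of (corrected) control counts.
#' @return normalised numeric vector.
#' @export
median_normalise_control <- function(control) {
  m <- median(control, na.rm = TRUE)
  stop_if_not(is.finite(m) && m > 0, "control median must be positive")
  control / m
}

#' Construct a log2-ratio profile from per-bin values
#'
#' Builds the profile object consumed by the segmentation functions from
#' raw per-bin log2 ratios (e.g. externally computed or synthetic values).
#' `NA` values are masked.
#'
#' @param log2r numeric per-bin log2 ratios.
#' @param chrom chromosome label per bin (default: one chromosome).
#' @param sample_id sample label.
#' @return a `log2r_profile`.
#' @export
log2r_profile <- function(log2r, chrom = rep("chr1", length(log2r)),
                          sample_id = "sample") {
  stop_if_not(length(chrom) == length(log2r),
              "`chrom` must match `log2r` in length")
  structure(list(sample_id = sample_id, log2r = as.numeric(log2r),
                 mask = !is.finite(log2r), chrom = chrom),
            class = "log2r_profile")
}

#' Per-bin log2 copy-number ratios against a healthy control
#'
#' `log2(sample / control)` per bin, re-centred so the median over usable
#' bins is 0 (the genome-wide depth scale is unidentifiable; the
#' copy-neutral majority anchors the zero). Bins where the control is
#' non-positive or the sample count is zero are masked rather than
#' pseudocounted, so no artificial extreme ratios are created; set
#' `pseudocount > 0` to keep them.
#'
#' @param sample_corrected corrected sample values per bin (`NA` = masked).
#' @param control_normalised corrected, median-normalised control values.
#' @param grid the shared bin grid.
#' @param sample_id label carried into the profile.
#' @param pseudocount added to both numerator and denominator when > 0.
#' @param min_usable minimum usable bins required (default 50).
#' @return list of class `log2r_profile`: `sample_id`, `log2r` (`NA` at
#'   masked bins), `mask`, `chrom`.
#' @export
log2_ratio <- function(sample_corrected, control_normalised, grid,
                       sample_id = "sample", pseudocount = 0,
                       min_usable = 50) {
  stop_if_not(length(sample_corrected) == length(control_normalised) &&
                length(sample_corrected) == nrow(grid),
              "sample, control and grid must be on the same bin grid")
  s <- as.numeric(sample_corrected) + pseudocount
  cc <- as.numeric(control_normalised) + pseudocount
  mask <- !is.finite(s) | !is.finite(cc) | cc <= 0 | s <= 0
  n_usable <- sum(!mask)
  if (n_usable < min_usable)
    stop(sprintf("only %d usable bins remain (< %d required)", n_usable,
                 min_usable), call. = FALSE)
  l <- rep(NA_real_, length(s))
  l[!mask] <- log2(s[!mask] / cc[!mask])
  l[!mask] <- l[!mask] - median(l[!mask])
  structure(list(sample_id = sample_id, log2r = l, mask = mask,
                 chrom = grid$chrom),
            class = "log2r_profile")
}
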