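# Empirical healthy-panel blacklist and the t-MAD score.

#' Build an empirical blacklist from a healthy-control panel
#'
#' Each median-normalised control is fitted by a 2D LOESS over
#' (GC, mappability); per bin, the median of (actual - fitted) residuals
#' across controls is taken, and bins whose |median residual| exceeds
#' `n_sd` standard deviations (SD computed over the per-bin median
#' residuals) are flagged. The cut is two-sided: systematically depleted
#' bins are as untrustworthy as inflated ones. A `pooled` mode fits one
#' LOESS to the per-bin median counts instead of one per control.
#'
#' @param panel a `healthy_panel` or a bins x controls count matrix.
#' @param grid the bin grid.
#' @param n_sd SD multiple for the cut (default 4; `Inf` flags nothing).
#' @param method `"per_control"` (default) or `"pooled"`.
#' @param sd_method how the standard deviation of the per-bin median
#'   residuals is estimated: `"mad"` (default; 1.4826 x median absolute
#'   deviation, so the aberrant bins being hunted do not inflate their own
#'   threshold) or the plain `"sd"`.
#' @param span,degree LOESS parameters (fallback to a stratified-median
#'   surface on failure, with a warning).
#' @return list of class `empirical_blacklist`: `flagged_bins`,
#'   `median_residual`, `sd_threshold` (the absolute cut applied), `n_sd`.
#' @export
build_empirical_blacklist <- function(panel, grid, n_sd = 4,
                                      method = c("per_control", "pooled"),
                                      sd_method = c("mad", "sd"),
                                      span = 0.3, degree = 2) {
  method <- match.arg(method)
  sd_method <- match.arg(sd_method)
  counts <- if (inherits(panel, "healthy_panel")) panel$counts else panel
  stop_if_not(is.matrix(counts) && nrow(counts) == nrow(grid),
              "panel must be a bins x controls matrix on the grid")
  stop_if_not(ncol(counts) >= 5, "need >= 5 healthy controls, got %d",
              ncol(counts))
  norm <- apply(counts, 2, function(col) col / median(col))
  if (method == "per_control") {
    resid <- matrix(NA_real_, nrow(grid), ncol(counts))
    for (j in seq_len(ncol(counts))) {
      fitted <- fit_bias_surface(norm[, j], grid$gc, grid$mappability,
                                 span = span, degree = degree)
      resid[, j] <- norm[, j] - fitted
    }
    med_resid <- apply(resid, 1, median)
  } else {
    pooled <- apply(norm, 1, median)
    fitted <- fit_bias_surface(pooled, grid$gc, grid$mappability,
                               span = span, degree = degree)
    med_resid <- pooled - fitted
  }
  s <- switch(sd_method,
              mad = stats::mad(med_resid, na.rm = TRUE),
              sd = sd(med_resid, na.rm = TRUE))
  thr <- n_sd * s
  flagged <- which(is.finite(med_resid) & abs(med_resid) > thr)
  structure(list(flagged_bins = flagged, median_residual = med_resid,
                 sd_threshold = thr, n_sd = n_sd),
            class = "empirical_blacklist")
}

#' t-MAD: trimmed median absolute deviation from log2R = 0
#'
#' The ctDNA tumour-fraction proxy: the median absolute value of the
#' per-bin averaged segmental log2 ratios, after trimming bins on the
#' empirical blacklist. The deviation is from 0 (the copy-neutral level),
#' not from the sample median.
#'
#' @param averaged an `averaged_profile` from [average_segmentations()].
#' @param blacklist an `empirical_blacklist`, or `NULL` for no trimming.
#' @param min_bins minimum retained bins required (default 30).
#' @return list of class `tmad_result`: `sample_id`, `tmad`, `n_bins_used`,
#'   `n_trimmed`.
#' @export
tmad <- function(averaged, blacklist = NULL, min_bins = 30) {
  stop_if_not(inherits(averaged, "averaged_profile"),
              "`averaged` must be an averaged_profile")
  keep <- !averaged$mask
  n_unmasked <- sum(keep)
  if (!is.null(blacklist)) {
    stop_if_not(inherits(blacklist, "empirical_blacklist"),
                "`blacklist` must be an empirical_blacklist")
    keep[blacklist$flagged_bins] <- FALSE
  }
  n_used <- sum(keep)
  if (n_used < min_bins)
    stop(sprintf("only %d bins retained after trimming (< %d required)",
                 n_used, min_bins), call. = FALSE)
  structure(list(sample_id = averaged$sample_id,
                 tmad = median(abs(averaged$per_bin_avg[keep])),
                 n_bins_used = n_used, n_trimmed = n_unmasked - n_used),
            class = "tmad_result")
}

#' Preprocess a healthy control for repeated use
#'
#' Correction, static-blacklist masking and median-normalisation of a
#' control sample; the result can be passed to [tmad_score()] in place of
#' the raw control.
#'
#' @param control a `sample_counts` object.
#' @param grid the bin grid.
#' @param correction method for [correct_gc_mappability()].
#' @return numeric per-bin normalised control (`NA` at masked bins).
#' @export
prepare_control <- function(control, grid, correction = "loess_2d") {
  c_corr <- correct_gc_mappability(control, grid, method = correction)
  c_corr <- apply_static_blacklist(c_corr, grid)
  median_normalise_control(c_corr)
}

#' Build a median-of-panel reference control
#'
#' Alternative to a single healthy control: each panel control is
#' median-normalised, the per-bin median across controls is taken, and the
#' pooled profile is then corrected, masked and normalised like a control
#' sample. Averaging across controls shrinks the reference's sampling noise
#' and so tightens low-fraction log2 ratios.
#'
#' @param panel a `healthy_panel` or bins x controls count matrix.
#' @param grid the bin grid.
#' @param correction method for [correct_gc_mappability()].
#' @return numeric per-bin normalised reference (`NA` at masked bins).
#' @export
prepare_panel_reference <- function(panel, grid, correction = "loess_2d") {
  counts <- if (inherits(panel, "healthy_panel")) panel$counts else panel
  stop_if_not(is.matrix(counts) && nrow(counts) == nrow(grid),
              "panel must be a bins x controls matrix on the grid")
  norm <- apply(counts, 2, function(col) col / median(col))
  pooled <- apply(norm, 1, median)
  c_corr <- correct_gc_mappability(pooled, grid, method = correction)
  c_corr <- apply_static_blacklist(c_corr, grid)
  median_normalise_control(c_corr)
}

#' Score one sample end to end
#'
#' Convenience wrapper running the full chain: optional downsampling,
#' GC/mappability correction of sample and control, static-blacklist
#' masking, control median-normalisation, log2 ratio, CBS and HMM
#' segmentation, per-bin averaging and t-MAD.
#'
#' @param sample a `sample_counts` object.
#' @param control a `sample_counts` healthy control on the same grid, or a
#'   numeric vector from [prepare_control()] (avoids refitting the control
#'   surface when scoring many samples).
#' @param grid the bin grid.
#' @param blacklist optional `empirical_blacklist`.
#' @param downsample_to optional read target applied to both sample and
#'   control (skipped for whichever already has fewer reads).
#' @param correction correction method, see [correct_gc_mappability()].
#' @param cbs,hmm named lists of overrides for [cbs_segment()] /
#'   [hmm_segment()].
#' @param min_bins passed to [tmad()].
#' @param seed RNG seed (downsampling, permutations, restarts).
#' @return a `tmad_result` with the `averaged_profile` attached as
#'   `$averaged`.
#' @export
tmad_score <- function(sample, control, grid, blacklist = NULL,
                       downsample_to = NULL, correction = "loess_2d",
                       cbs = list(), hmm = list(), min_bins = 30,
                       seed = NULL) {
  set_seed_if(seed)
  if (!is.null(downsample_to)) {
    sample <- downsample_counts(sample, min(downsample_to,
                                            sum(sample$counts)))
    if (inherits(control, "sample_counts"))
      control <- downsample_counts(control, min(downsample_to,
                                                sum(control$counts)))
  }
  s_corr <- correct_gc_mappability(sample, grid, method = correction)
  s_corr <- apply_static_blacklist(s_corr, grid)
  c_norm <- if (is.numeric(control)) control
            else prepare_control(control, grid, correction)
  prof <- log2_ratio(s_corr, c_norm, grid, sample_id = sample$sample_id)
  seg_cbs <- do.call(cbs_segment, c(list(profile = prof), cbs))
  seg_hmm <- do.call(hmm_segment, c(list(profile = prof), hmm))
  avg <- average_segmentations(seg_cbs, seg_hmm)
  res <- tmad(avg, blacklist, min_bins = min_bins)
  res$averaged <- avg
  res
}

#' Score every sample of a simulated cohort
#'
#' Runs [tmad_score()] on each cohort sample against a shared healthy
#' control and returns the response-cohort table used by the group
#' comparisons.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param control a healthy `sample_counts` on the same grid.
#' @param grid bin grid.
#' @param blacklist optional `empirical_blacklist`.
#' @param ... passed to [tmad_score()].
#' @return `data.frame` with columns `sample_id`, `subject`, `group`,
#'   `timepoint`, `tumour_fraction`, `tmad`.
#' @export
score_cohort <- function(cohort, control, grid, blacklist = NULL, ...) {
  stop_if_not(inherits(cohort, "cohort"), "`cohort` must be a cohort")
  if (inherits(control, "sample_counts"))
    control <- prepare_control(control, grid)
  scores <- vapply(cohort$samples, function(s)
    tmad_score(s, control, grid, blacklist = blacklist, ...)$tmad, 0.0)
  out <- cohort$truth
  out$tmad <- scores
  out
}
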