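# Segmentation of log2 ratio profiles: circular binary segmentation (CBS)
# and a Gaussian-emission hidden Markov model, plus per-bin averaging of the
# two segmental values. Segmentation is per chromosome; a segment's reported
# mean is always the empirical mean of its member bins.

new_segmentation <- function(algorithm, segments, per_bin, profile) {
  structure(list(algorithm = algorithm, segments = segments,
                 per_bin = per_bin, mask = is.na(per_bin),
                 chrom = profile$chrom, sample_id = profile$sample_id),
            class = "segmentation_result")
}

segments_from_runs <- function(run_id, usable_idx, x, chrom) {
  # run_id: one id per usable bin; contiguous equal ids form segments
  r <- rle(paste(chrom[usable_idx], run_id, sep = "|"))
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(chrom = chrom[usable_idx][starts],
             first_bin = usable_idx[starts], last_bin = usable_idx[ends],
             n_bins = r$lengths,
             mean_log2r = vapply(seq_along(starts), function(k)
               mean(x[starts[k]:ends[k]]), 0.0),
            stringsAsFactors = FALSE)
}

# Recursive CBS on one chromosome's usable values. Returns an integer
# segment id per value.
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  ids <- rep(1L, n)
  if (n < 4L) return(ids)
  res <- cbs_split_cpp(x, n_perm, alpha)
  if (res$n_perm_done == 0L) return(ids)
  p <- (1 + res$n_ge) / (1 + res$n_perm_done)
  if (p >= alpha) return(ids)
  i <- res$i; j <- res$j            # arc is positions (i, j] in 1-based terms
  bounds <- unique(c(0L, i, j, n))
  bounds <- bounds[bounds >= 0L & bounds <= n]
  bounds <- sort(bounds)
  out <- integer(n)
  nxt <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, n_perm, min_width)
    out[lo:hi] <- sub + nxt
    nxt <- nxt + max(sub)
  }
  out
}

# Merge segments shorter than min_width into the neighbour with the nearer
# mean; operates on per-value segment ids.
merge_short_segments <- function(ids, x, min_width) {
  repeat {
    r <- rle(ids)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_width)
    if (length(short) == 0L) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    means <- vapply(seq_along(starts), function(q)
      mean(x[starts[q]:ends[q]]), 0.0)
    nb <- if (k == 1L) 2L
          else if (k == length(r$lengths)) k - 1L
          else if (abs(means[k - 1L] - means[k]) <= abs(means[k + 1L] - means[k]))
            k - 1L else k + 1L
    r$values[k] <- r$values[nb]
    ids <- inverse.rle(r)
    # renumber contiguous runs
    ids <- cumsum(c(1L, diff(ids) != 0L))
  }
  ids
}

#' Circular binary segmentation
#'
#' Recursive binary splitting on the maximal circular two-sample
#' t-statistic; a candidate split is kept when its permutation p-value falls
#' below `alpha` (`n_perm` seeded within-segment permutations, with early
#' stopping once significance is impossible). Segments narrower than
#' `min_width` are merged into the neighbour with the nearer mean.
#' Chromosomes are segmented independently; an all-masked chromosome yields
#' no segments (with a message).
#'
#' @param profile a `log2r_profile`.
#' @param alpha split acceptance level.
#' @param n_perm permutations per split test.
#' @param min_width minimum segment width in bins.
#' @param seed RNG seed for the permutations.
#' @return a `segmentation_result`: `segments` (chrom, first_bin, last_bin,
#'   n_bins, mean_log2r) and `per_bin` segmental means (NA at masked bins).
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_perm = 1000L, min_width = 3L,
                        seed = NULL) {
  stop_if_not(inherits(profile, "log2r_profile"),
              "`profile` must be a log2r_profile")
  stop_if_not(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  set_seed_if(seed)
  per_bin <- rep(NA_real_, length(profile$log2r))
  seg_list <- list()
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch & !profile$mask)
    if (length(idx) == 0L) {
      message("chromosome ", ch, " is fully masked; no segments")
      next
    }
    x <- profile$log2r[idx]
    ids <- cbs_recurse(x, alpha, n_perm, min_width)
    ids <- merge_short_segments(ids, x, min_width)
    segs <- segments_from_runs(ids, idx, x, profile$chrom)
    seg_list[[ch]] <- segs
    run <- rle(ids)
    ends <- cumsum(run$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_along(starts))
      per_bin[idx[starts[k]:ends[k]]] <- mean(x[starts[k]:ends[k]])
  }
  segments <- if (length(seg_list)) do.call(rbind, c(seg_list,
                                                     make.row.names = FALSE))
              else data.frame(chrom = character(0), first_bin = integer(0),
                              last_bin = integer(0), n_bins = integer(0),
                              mean_log2r = numeric(0))
  new_segmentation("cbs", segments, per_bin, profile)
}

#' Gaussian hidden Markov model segmentation
#'
#' Fits a Gaussian-emission HMM with shared variance by EM (means
#' initialised at quantiles of the data; additional seeded restarts jitter
#' the initial means) and decodes by Viterbi. Chromosomes are independent
#' sequences (no transitions across boundaries). Runs of constant decoded
#' state become segments; each segment's `mean_log2r` is the empirical mean
#' of its member bins, not the state mean. Non-convergence within
#' `max_iter` returns the best iterate with a warning; the emission
#' variance is floored at `var_floor`.
#'
#' @param profile a `log2r_profile`.
#' @param n_states number of hidden states (>= 2; default 5 covers loss /
#'   neutral / gain levels).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param n_restarts EM restarts with jittered initial means.
#' @param sticky initial self-transition probability.
#' @param sticky_prior Dirichlet pseudo-count added to the self-transition
#'   counts in each M step; keeps the chain from decoding bin-level noise
#'   as rapid state toggles on flat profiles (0 disables).
#' @param var_floor lower bound on the shared emission variance.
#' @param seed RNG seed for the restarts.
#' @return a `segmentation_result`.
#' @export
hmm_segment <- function(profile, n_states = 5L, max_iter = 200L, tol = 1e-5,
                        n_restarts = 3L, sticky = 0.99, sticky_prior = 20,
                        var_floor = 1e-4, seed = NULL) {
  stop_if_not(inherits(profile, "log2r_profile"),
              "`profile` must be a log2r_profile")
  stop_if_not(is_count(n_states) && n_states >= 2, "`n_states` must be >= 2")
  usable <- !profile$mask
  stop_if_not(sum(usable) >= 10 * n_states,
              "need >= %d usable bins for %d states, got %d", 10 * n_states,
              n_states, sum(usable))
  set_seed_if(seed)
  idx <- which(usable)
  x <- profile$log2r[idx]
  chrom_runs <- rle(as.character(profile$chrom[idx]))
  seq_lens <- chrom_runs$lengths

  q0 <- quantile(x, probs = seq(0.1, 0.9, length.out = n_states),
                 names = FALSE)
  v0 <- max(var(x), var_floor)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    means0 <- if (r == 1L) q0 else sort(q0 + rnorm(n_states, 0, 0.1 * sqrt(v0)))
    fit <- hmm_em_cpp(x, seq_lens, means0, v0, sticky, max_iter, tol,
                      var_floor, sticky_prior)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning(sprintf("HMM EM did not converge in %d iterations; using best iterate",
                    max_iter))
  states <- hmm_viterbi_cpp(x, seq_lens, best$means, best$variance,
                            best$trans, best$init)
  segs <- segments_from_runs(states, idx, x, profile$chrom)
  per_bin <- rep(NA_real_, length(profile$log2r))
  run <- rle(paste(profile$chrom[idx], states, sep = "|"))
  ends <- cumsum(run$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (k in seq_along(starts)) {
    sel <- idx[starts[k]:ends[k]]
    per_bin[sel] <- mean(x[starts[k]:ends[k]])
  }
  out <- new_segmentation("hmm", segs, per_bin, profile)
  out$model <- list(means = best$means, variance = best$variance,
                    loglik = best$loglik, converged = best$converged,
                    n_iter = best$n_iter)
  out
}

#' Average two segmentations per bin
#'
#' The pipeline's consensus profile: the arithmetic mean of the CBS and HMM
#' per-bin segmental values. A bin masked in either input stays masked.
#'
#' @param a,b two `segmentation_result`s on the same grid.
#' @return list of class `averaged_profile`: `per_bin_avg`, `mask`, `chrom`,
#'   `sample_id`.
#' @export
average_segmentations <- function(a, b) {
  stop_if_not(inherits(a, "segmentation_result") &&
                inherits(b, "segmentation_result"),
              "inputs must be segmentation_result objects")
  stop_if_not(length(a$per_bin) == length(b$per_bin) &&
                identical(as.character(a$chrom), as.character(b$chrom)),
              "segmentations are not on the same bin grid")
  avg <- (a$per_bin + b$per_bin) / 2
  structure(list(per_bin_avg = avg, mask = is.na(avg), chrom = a$chrom,
                 sample_id = a$sample_id),
            class = "averaged_profile")
}
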