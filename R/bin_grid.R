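# Genomic bin grid and the bias model used by the simulator.

#' Build a synthetic genomic bin grid
#'
#' Creates the coordinate frame used by the whole copy-number pipeline: fixed
#' width, non-overlapping bins partitioned over chromosomes, each annotated
#' with a GC fraction, a mappability score and a static-blacklist flag
#' (emulating the public ENCODE/1000 Genomes exclusion lists applied to real
#' data). GC is drawn from a smooth autocorrelated process so that
#' neighbouring bins have similar composition, as along a real genome;
#' mappability sits near 1 with a configurable low-mappability tail.
#'
#' @param n_bins total number of bins (>= 10).
#' @param bin_size bin width in bp (default 30000, i.e. 30 kb).
#' @param n_chroms number of chromosome labels; bins are split near-equally
#'   and coordinates restart at 0 on each chromosome.
#' @param seed RNG seed; the grid is a pure function of the arguments and
#'   this seed.
#' @param gc_range range the GC fraction is squashed into.
#' @param low_map_frac fraction of bins given a low mappability score.
#' @param static_blacklist_frac fraction of bins flagged in the static
#'   blacklist.
#' @return a `data.frame` of class `bin_grid` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappability`, `static_blacklist` and attribute `bin_size`.
#' @examples
#' grid <- make_bin_grid(n_bins = 100, seed = 1)
#' all(grid$end - grid$start == 30000)
#' @export
make_bin_grid <- function(n_bins, bin_size = 30000L, n_chroms = 2L, seed = 1L,
                          gc_range = c(0.3, 0.6), low_map_frac = 0.05,
                          static_blacklist_frac = 0.02) {
  stop_if_not(is_count(n_bins) && n_bins >= 10, "`n_bins` must be >= 10")
  stop_if_not(is_count(bin_size) && bin_size > 0, "`bin_size` must be positive")
  stop_if_not(is_count(n_chroms) && n_chroms >= 1 && n_chroms <= n_bins,
              "`n_chroms` must be in [1, n_bins]")
  set_seed_if(seed)

  # near-equal split of bins over chromosomes
  cuts <- floor(seq(0, n_bins, length.out = n_chroms + 1))
  sizes <- diff(cuts)
  chrom <- rep(paste0("chr", seq_len(n_chroms)), times = sizes)
  start <- unlist(lapply(sizes, function(k) (seq_len(k) - 1) * bin_size),
                  use.names = FALSE)

  # GC: AR(1) latent process squashed into gc_range
  z <- as.numeric(stats::filter(rnorm(n_bins), 0.97, method = "recursive"))
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  gc <- gc_range[1] + diff(gc_range) * pnorm(z)

  # mappability: mostly ~1 with a low tail
  mappability <- 1 - rbeta(n_bins, 0.5, 30)
  n_low <- round(low_map_frac * n_bins)
  if (n_low > 0) {
    low <- sample.int(n_bins, n_low)
    mappability[low] <- runif(n_low, 0.3, 0.8)
  }

  static_blacklist <- rep(FALSE, n_bins)
  n_bl <- round(static_blacklist_frac * n_bins)
  if (n_bl > 0) static_blacklist[sample.int(n_bins, n_bl)] <- TRUE

  grid <- data.frame(chrom = chrom, start = start, end = start + bin_size,
                     gc = gc, mappability = mappability,
                     static_blacklist = static_blacklist,
                     stringsAsFactors = FALSE)
  attr(grid, "bin_size") <- as.integer(bin_size)
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Default GC/mappability bias parameters
#'
#' The simulator's bias model: a unimodal (quadratic on the log scale) GC
#' response peaking at `gc_peak`, and a monotone power-law mappability
#' response. The preprocessing module must invert exactly this kind of bias.
#'
#' @param gc_curvature quadratic coefficient on the log-rate scale (<= 0 for
#'   a unimodal peak); 0 means no GC bias.
#' @param gc_peak GC fraction at which the rate peaks.
#' @param map_exponent exponent of the mappability response; 0 means none.
#' @return a list of class `bias_params`.
#' @export
bias_params <- function(gc_curvature = -20, gc_peak = 0.45, map_exponent = 1) {
  stop_if_not(is.numeric(gc_curvature) && gc_curvature <= 0,
              "`gc_curvature` must be <= 0 (unimodal peak)")
  stop_if_not(is.numeric(map_exponent) && map_exponent >= 0,
              "`map_exponent` must be >= 0 (monotone response)")
  structure(list(gc_curvature = gc_curvature, gc_peak = gc_peak,
                 map_exponent = map_exponent), class = "bias_params")
}

#' Flat (bias-free) parameter set
#' @return a `bias_params` object with no GC or mappability response.
#' @export
flat_bias <- function() bias_params(gc_curvature = 0, map_exponent = 0)

#' Expected relative rate per bin under the bias model
#'
#' Evaluates the multiplicative GC x mappability bias at each bin and
#' normalises so the grid mean is 1. Two bins with identical (gc,
#' mappability) always receive identical rates.
#'
#' @param grid a [make_bin_grid()] grid.
#' @param params a [bias_params()] object.
#' @return positive numeric vector, one rate per bin, mean 1.
#' @export
expected_bin_rate <- function(grid, params = bias_params()) {
  stop_if_not(inherits(grid, "bin_grid"), "`grid` must be a bin_grid")
  stop_if_not(inherits(params, "bias_params"), "`params` must be bias_params")
  lograte <- params$gc_curvature * (grid$gc - params$gc_peak)^2 +
    params$map_exponent * log(pmax(grid$mappability, 1e-12))
  rate <- exp(lograte)
  rate / mean(rate)
}

#' Construct a ground-truth copy-number profile
#'
#' Segments are given as inclusive bin-index ranges with integer copy
#' numbers; bins not covered by any segment are copy-neutral (CN = 2).
#'
#' @param first_bin,last_bin integer vectors of inclusive 1-based bin bounds.
#' @param copy_number integer copy number >= 0 per segment.
#' @return a `data.frame` of class `cna_profile`.
#' @export
cna_profile <- function(first_bin, last_bin, copy_number) {
  stop_if_not(length(first_bin) == length(last_bin) &&
                length(first_bin) == length(copy_number),
              "segment fields must have equal length")
  stop_if_not(all(copy_number >= 0 & copy_number == floor(copy_number)),
              "`copy_number` must be integer >= 0")
  stop_if_not(all(first_bin >= 1 & last_bin >= first_bin),
              "invalid segment bounds")
  o <- order(first_bin)
  first_bin <- first_bin[o]; last_bin <- last_bin[o]
  copy_number <- copy_number[o]
  if (length(first_bin) > 1)
    stop_if_not(all(first_bin[-1] > last_bin[-length(last_bin)]),
                "segments must not overlap")
  structure(data.frame(first_bin = as.integer(first_bin),
                       last_bin = as.integer(last_bin),
                       copy_number = as.integer(copy_number)),
            class = c("cna_profile", "data.frame"))
}

# Per-bin copy-number vector (base ploidy 2) for a profile on a grid.
profile_cn <- function(grid, profile) {
  cn <- rep(2L, nrow(grid))
  if (is.null(profile) || nrow(profile) == 0) return(cn)
  stop_if_not(max(profile$last_bin) <= nrow(grid),
              "copy-number segment references bin %d outside the %d-bin grid",
              max(profile$last_bin), nrow(grid))
  for (s in seq_len(nrow(profile)))
    cn[profile$first_bin[s]:profile$last_bin[s]] <- profile$copy_number[s]
  cn
}

#' Draw a random ground-truth copy-number profile
#'
#' Places non-overlapping aberrant segments with copy numbers drawn from
#' typical sWGS-visible states (losses and low-level gains).
#'
#' @param grid bin grid.
#' @param n_segments number of aberrant segments.
#' @param aberrant_frac range the genome-wide aberrant fraction is drawn
#'   from (default 0.5-0.7, emulating the high copy-number burden of
#'   advanced metastatic disease).
#' @param cn_states candidate integer copy numbers (2 excluded).
#' @param min_len minimum aberrant segment length in bins.
#' @param seed RNG seed.
#' @return a [cna_profile()].
#' @export
random_cna_profile <- function(grid, n_segments = 6,
                               aberrant_frac = c(0.5, 0.7),
                               cn_states = c(0, 1, 3, 4), min_len = 5,
                               seed = NULL) {
  set_seed_if(seed)
  n <- nrow(grid)
  frac <- runif(1, aberrant_frac[1], aberrant_frac[2])
  A <- round(frac * n)
  k <- n_segments
  stop_if_not(A >= k * min_len && A < n,
              "aberrant fraction incompatible with %d segments of >= %d bins",
              k, min_len)
  rand_split <- function(total, parts, minimum) {
    # split `total` into `parts` integers each >= minimum
    free <- total - parts * minimum
    w <- diff(c(0, sort(runif(parts - 1)), 1))
    lens <- minimum + floor(w * free)
    lens[1] <- lens[1] + (total - sum(lens))
    lens
  }
  seg_lens <- rand_split(A, k, min_len)
  gap_lens <- rand_split(n - A, k + 1, 0)
  fb <- integer(k); lb <- integer(k)
  pos <- 0L
  for (s in seq_len(k)) {
    pos <- pos + gap_lens[s]
    fb[s] <- pos + 1L
    pos <- pos + seg_lens[s]
    lb[s] <- pos
  }
  cn <- sample(cn_states, k, replace = TRUE)
  cna_profile(fb, lb, cn)
}
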