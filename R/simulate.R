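# Synthetic-data generators: binned sWGS samples, healthy panels,
# multi-timepoint cohorts and expression matrices. Every generator is a pure
# function of (configuration, seed) and emits its ground truth alongside the
# data so each downstream stage is testable.

#' Simulate binned read counts for one plasma sample
#'
#' Counts follow the standard ctDNA dilution model: the expected relative
#' depth of bin *i* is `bias_i * (2 (1 - f) + f * CN_i) / 2`, where `f` is
#' the tumour fraction and `CN_i` the integer tumour copy number (base
#' ploidy 2). Noise is negative binomial by default (sWGS bin counts are
#' overdispersed) or Poisson.
#'
#' @param grid bin grid from [make_bin_grid()].
#' @param profile ground-truth [cna_profile()] or `NULL` for copy-neutral.
#' @param tumour_fraction tumour fraction `f` in \[0, 1\].
#' @param total_reads expected total read count.
#' @param noise_model `"negative_binomial"` or `"poisson"`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param params [bias_params()] for the GC/mappability bias.
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return list of class `sample_counts`: `sample_id`, `counts` (integer per
#'   bin), `total_reads`, and `truth` (fraction, profile, expected counts).
#' @export
simulate_sample <- function(grid, profile = NULL, tumour_fraction = 0,
                            total_reads = 1e5,
                            noise_model = c("negative_binomial", "poisson"),
                            dispersion = 0.05, params = bias_params(),
                            sample_id = "sample", seed = NULL) {
  noise_model <- match.arg(noise_model)
  stop_if_not(is.numeric(tumour_fraction) && tumour_fraction >= 0 &&
                tumour_fraction <= 1, "`tumour_fraction` must be in [0, 1]")
  stop_if_not(is_count(total_reads) && total_reads > 0,
              "`total_reads` must be a positive integer")
  set_seed_if(seed)
  cn <- profile_cn(grid, profile)
  f <- tumour_fraction
  depth <- (2 * (1 - f) + f * cn) / 2
  rate <- expected_bin_rate(grid, params) * depth
  mu <- total_reads * rate / sum(rate)
  counts <- switch(noise_model,
                   poisson = rpois(length(mu), mu),
                   negative_binomial = rnbinom(length(mu), mu = mu,
                                               size = 1 / dispersion))
  structure(list(sample_id = sample_id, counts = as.integer(counts),
                 total_reads = sum(counts),
                 truth = list(tumour_fraction = f, profile = profile,
                              expected = mu)),
            class = "sample_counts")
}

#' Simulate a healthy-control panel
#'
#' All controls are copy-neutral genome-wide; an optional set of artifact
#' bins receives a systematic multiplicative count distortion shared across
#' controls, emulating recurrent technical artifacts that the empirical
#' blacklist must discover.
#'
#' @param grid bin grid.
#' @param n_controls number of healthy controls (panel columns).
#' @param total_reads expected reads per control.
#' @param artifact_bins integer bin indices distorted in every control.
#' @param artifact_multiplier multiplicative distortion (> 0; 1 = none).
#' @param noise_model,dispersion,params,seed as in [simulate_sample()].
#' @return list of class `healthy_panel`: `counts` (bins x controls integer
#'   matrix), `artifact_bins`, `artifact_multiplier`.
#' @export
simulate_healthy_panel <- function(grid, n_controls = 20, total_reads = 1e5,
                                   artifact_bins = integer(0),
                                   artifact_multiplier = 3,
                                   noise_model = c("negative_binomial",
                                                   "poisson"),
                                   dispersion = 0.05, params = bias_params(),
                                   seed = NULL) {
  noise_model <- match.arg(noise_model)
  stop_if_not(is.numeric(artifact_multiplier) && artifact_multiplier > 0,
              "`artifact_multiplier` must be > 0")
  stop_if_not(is_count(n_controls) && n_controls >= 1,
              "`n_controls` must be >= 1")
  artifact_bins <- as.integer(artifact_bins)
  stop_if_not(all(artifact_bins >= 1 & artifact_bins <= nrow(grid)),
              "artifact bins outside grid")
  set_seed_if(seed)
  rate <- expected_bin_rate(grid, params)
  rate[artifact_bins] <- rate[artifact_bins] * artifact_multiplier
  mu <- total_reads * rate / sum(rate)
  n <- nrow(grid)
  counts <- matrix(0L, n, n_controls,
                   dimnames = list(NULL, paste0("control", seq_len(n_controls))))
  for (j in seq_len(n_controls)) {
    counts[, j] <- switch(noise_model,
                          poisson = rpois(n, mu),
                          negative_binomial = rnbinom(n, mu = mu,
                                                      size = 1 / dispersion))
  }
  structure(list(counts = counts, artifact_bins = artifact_bins,
                 artifact_multiplier = artifact_multiplier),
            class = "healthy_panel")
}

#' Default response-group tumour-fraction trajectories
#'
#' Per-group tumour fractions at (baseline, wk4, wk6): progressive disease
#' rises, stable disease stays flat, partial responders clear most ctDNA.
#' These defaults reproduce the qualitative on-treatment ordering
#' PR < SD < PD seen in trial cohorts.
#'
#' @return named list of length-3 numeric vectors.
#' @export
default_trajectories <- function() {
  list(PD = c(baseline = 0.10, wk4 = 0.15, wk6 = 0.20),
       SD = c(baseline = 0.08, wk4 = 0.08, wk6 = 0.08),
       PR = c(baseline = 0.10, wk4 = 0.04, wk6 = 0.02))
}

#' Build a cohort sampling plan
#'
#' One row per (subject, timepoint): the subject's RECIST best-response
#' group fixes its tumour-fraction trajectory over timepoints.
#'
#' @param n_subjects named vector of subjects per group, e.g.
#'   `c(PR = 5, SD = 6, PD = 6)`.
#' @param timepoints timepoint labels (order matters; matched to the
#'   trajectory entries positionally).
#' @param trajectories per-group fraction vectors, see
#'   [default_trajectories()].
#' @param total_reads reads per sample.
#' @return `data.frame` with columns `subject`, `group`, `timepoint`,
#'   `tumour_fraction`, `total_reads`.
#' @export
cohort_plan <- function(n_subjects = c(PR = 5, SD = 6, PD = 6),
                        timepoints = c("baseline", "wk4", "wk6"),
                        trajectories = default_trajectories(),
                        total_reads = 1e5) {
  stop_if_not(all(names(n_subjects) %in% names(trajectories)),
              "every group needs a trajectory")
  rows <- list()
  idx <- 0
  for (g in names(n_subjects)) {
    traj <- trajectories[[g]]
    stop_if_not(all(traj >= 0 & traj <= 1),
                "tumour fractions must be in [0, 1]")
    traj <- if (!is.null(names(traj)) && all(timepoints %in% names(traj))) {
      traj[timepoints]
    } else {
      stop_if_not(length(traj) >= length(timepoints),
                  "trajectory for %s shorter than timepoints", g)
      traj[seq_along(timepoints)]
    }
    for (s in seq_len(n_subjects[[g]])) {
      idx <- idx + 1
      rows[[length(rows) + 1]] <-
        data.frame(subject = sprintf("S%02d", idx), group = g,
                   timepoint = timepoints,
                   tumour_fraction = as.numeric(traj),
                   total_reads = total_reads, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a multi-timepoint cohort
#'
#' Draws one ground-truth copy-number profile per subject (shared across its
#' timepoints) and simulates each planned sample at its planned tumour
#' fraction. The returned truth table maps every sample to its subject,
#' group, timepoint and fraction.
#'
#' @param plan a [cohort_plan()] data frame.
#' @param grid bin grid.
#' @param seed RNG seed governing profiles and counts.
#' @param n_segments,aberrant_frac,cn_states passed to
#'   [random_cna_profile()].
#' @param noise_model,dispersion,params passed to [simulate_sample()].
#' @return list of class `cohort`: `samples` (list of `sample_counts`),
#'   `truth` (data frame), `profiles` (per subject).
#' @export
simulate_cohort <- function(plan, grid, seed = NULL, n_segments = 6,
                            aberrant_frac = c(0.5, 0.7),
                            cn_states = c(0, 1, 3, 4),
                            noise_model = "negative_binomial",
                            dispersion = 0.05, params = bias_params()) {
  stop_if_not(is.data.frame(plan) &&
                all(c("subject", "group", "timepoint", "tumour_fraction",
                      "total_reads") %in% names(plan)),
              "`plan` must be a cohort plan data frame")
  key <- paste(plan$subject, plan$timepoint)
  stop_if_not(!anyDuplicated(key),
              "duplicate (subject, timepoint) in plan: %s",
              paste(unique(key[duplicated(key)]), collapse = ", "))
  stop_if_not(all(plan$group %in% c("PR", "SD", "PD")),
              "`group` must be one of PR, SD, PD")
  stop_if_not(all(plan$tumour_fraction >= 0 & plan$tumour_fraction <= 1),
              "tumour fractions must be in [0, 1]")
  set_seed_if(seed)
  subjects <- unique(plan$subject)
  profiles <- lapply(subjects, function(s)
    random_cna_profile(grid, n_segments = n_segments,
                       aberrant_frac = aberrant_frac, cn_states = cn_states))
  names(profiles) <- subjects
  samples <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sid <- paste0(plan$subject[i], "_", plan$timepoint[i])
    samples[[i]] <- simulate_sample(grid, profiles[[plan$subject[i]]],
                                    tumour_fraction = plan$tumour_fraction[i],
                                    total_reads = plan$total_reads[i],
                                    noise_model = noise_model,
                                    dispersion = dispersion, params = params,
                                    sample_id = sid)
  }
  truth <- data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"),
                      subject = plan$subject, group = plan$group,
                      timepoint = plan$timepoint,
                      tumour_fraction = plan$tumour_fraction,
                      stringsAsFactors = FALSE)
  structure(list(samples = samples, truth = truth, profiles = profiles),
            class = "cohort")
}

#' Simulate an expression-panel count matrix
#'
#' Emulates a targeted expression panel (negative-binomial counts over a few
#' hundred genes) with a benefit group (SD, optionally PR) and a progressive
#' disease (PD) group. A designated set of signature genes is shifted up in
#' the benefit group by `effect_log2fc`; additional differential genes can be
#' planted in either direction; all remaining genes are null.
#'
#' @param n_genes total genes.
#' @param n_per_group named vector, e.g. `c(SD = 12, PD = 6)`; each >= 3.
#' @param effect_log2fc log2 fold change of the signature genes (benefit over
#'   PD); >= 0, 0 plants nothing.
#' @param signature_genes labels of the designated signature genes.
#' @param n_extra_degs additional differential genes (half up, half down).
#' @param extra_log2fc |log2FC| of the extra differential genes.
#' @param dispersion NB dispersion.
#' @param base_mean_log mean of the log-normal baseline expression.
#' @param seed RNG seed.
#' @return list of class `expression_fixture`: `counts` (genes x samples),
#'   `labels`, `truth` (signature, up, down gene label sets).
#' @export
simulate_expression <- function(n_genes = 500, n_per_group = c(SD = 12, PD = 6),
                                effect_log2fc = 2,
                                signature_genes = c("CHGA", "FGF10", "PTPRC",
                                                    "MIA", "TRIM72", "SEC14L2"),
                                n_extra_degs = 20, extra_log2fc = 0.6,
                                dispersion = 0.1, base_mean_log = log(100),
                                seed = NULL) {
  stop_if_not(all(n_per_group >= 3),
              "each group needs >= 3 samples (tests unidentifiable below)")
  stop_if_not("PD" %in% names(n_per_group), "`n_per_group` must include PD")
  stop_if_not(is.numeric(effect_log2fc) && effect_log2fc >= 0,
              "`effect_log2fc` must be >= 0")
  stop_if_not(length(signature_genes) <= n_genes,
              "more signature genes than genes")
  set_seed_if(seed)
  genes <- paste0("GENE", sprintf("%04d", seq_len(n_genes)))
  genes[seq_along(signature_genes)] <- signature_genes
  labels <- rep(names(n_per_group), times = n_per_group)
  n_samp <- length(labels)
  benefit <- labels != "PD"

  base_mu <- exp(rnorm(n_genes, base_mean_log, 1))
  lfc <- rep(0, n_genes)
  up <- character(0); down <- character(0)
  if (effect_log2fc > 0) {
    lfc[seq_along(signature_genes)] <- effect_log2fc
    up <- signature_genes
  }
  if (n_extra_degs > 0) {
    pool <- setdiff(seq_len(n_genes), seq_along(signature_genes))
    extra <- sample(pool, min(n_extra_degs, length(pool)))
    half <- length(extra) %/% 2
    if (half > 0) {
      lfc[extra[seq_len(half)]] <- extra_log2fc
      up <- c(up, genes[extra[seq_len(half)]])
    }
    if (length(extra) > half) {
      rest <- extra[(half + 1):length(extra)]
      lfc[rest] <- -extra_log2fc
      down <- genes[rest]
    }
  }

  counts <- matrix(0L, n_genes, n_samp,
                   dimnames = list(genes, paste0(labels, seq_len(n_samp))))
  for (j in seq_len(n_samp)) {
    mu <- if (benefit[j]) base_mu * 2^lfc else base_mu
    counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  structure(list(counts = counts, labels = labels,
                 truth = list(signature = if (effect_log2fc > 0)
                                signature_genes else character(0),
                              up = up, down = down)),
            class = "expression_fixture")
}
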