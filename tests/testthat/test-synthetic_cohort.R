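# Generators: bin grids, bias model, samples, panels, cohorts, expression.

test_that("bin grid satisfies its structural invariants and is deterministic", {
  grid <- make_bin_grid(100, bin_size = 30000, n_chroms = 2, seed = 1)
  expect_equal(nrow(grid), 100)
  expect_true(all(grid$end - grid$start == 30000))
  expect_true(all(grid$gc >= 0 & grid$gc <= 1))
  expect_true(all(grid$mappability >= 0 & grid$mappability <= 1))
  # coordinates restart at 0 on each chromosome, sorted and non-overlapping
  for (ch in unique(grid$chrom)) {
    sub <- grid[grid$chrom == ch, ]
    expect_equal(sub$start[1], 0)
    expect_true(all(diff(sub$start) == 30000))
  }
  expect_identical(grid, make_bin_grid(100, bin_size = 30000, n_chroms = 2,
                                       seed = 1))
  expect_error(make_bin_grid(5), "n_bins")
})

test_that("bias model: flat params give unit rates, closed form holds", {
  grid <- small_grid()
  expect_equal(expected_bin_rate(grid, flat_bias()), rep(1, nrow(grid)))
  bp <- bias_params(gc_curvature = -20, gc_peak = 0.45, map_exponent = 1)
  r <- expected_bin_rate(grid, bp)
  expect_true(all(r > 0))
  expect_equal(mean(r), 1)
  # the rate ratio of two bins equals the closed-form bias ratio
  i <- which.max(abs(grid$gc - 0.45)); j <- which.min(abs(grid$gc - 0.45))
  expected_ratio <- exp(-20 * ((grid$gc[i] - 0.45)^2 - (grid$gc[j] - 0.45)^2)) *
    (grid$mappability[i] / grid$mappability[j])^1
  expect_equal(r[i] / r[j], expected_ratio, tolerance = 1e-12)
  # identical (gc, mappability) implies identical rate
  g2 <- grid; g2$gc[2] <- g2$gc[1]; g2$mappability[2] <- g2$mappability[1]
  r2 <- expected_bin_rate(g2, bp)
  expect_equal(r2[1], r2[2])
})

test_that("sample simulation follows the ctDNA dilution model", {
  grid <- make_bin_grid(20000, n_chroms = 2, seed = 3)
  prof <- cna_profile(1, 10000, 4)
  # f = 0.5, CN = 4: depth ratio (2*0.5 + 0.5*4)/2 = 1.5 vs neutral bins
  s <- simulate_sample(grid, prof, tumour_fraction = 0.5, total_reads = 2e6,
                       noise_model = "poisson", params = flat_bias(),
                       seed = 4)
  ratio <- mean(s$counts[1:10000]) / mean(s$counts[10001:20000])
  expect_equal(ratio, 1.5, tolerance = 0.02)
  # f = 0: expected counts equal the bias-only expectation
  grid2 <- small_grid()
  s0 <- simulate_sample(grid2, NULL, 0, total_reads = 1e5, seed = 5)
  r <- expected_bin_rate(grid2, bias_params())
  expect_equal(s0$truth$expected, 1e5 * r / sum(r), tolerance = 1e-12)
  # f = 1, CN = 0: zero expected (and hence zero observed) reads
  prof0 <- cna_profile(1, 50, 0)
  s1 <- simulate_sample(grid2, prof0, 1, total_reads = 1e4,
                        noise_model = "poisson", seed = 6)
  expect_true(all(s1$counts[1:50] == 0))
  # CN segment outside grid errors
  expect_error(simulate_sample(grid2, cna_profile(1, 10000, 3), 0.1, 1e4),
               "outside")
  # determinism
  expect_identical(simulate_sample(grid2, NULL, 0, 1e4, seed = 7),
                   simulate_sample(grid2, NULL, 0, 1e4, seed = 7))
})

test_that("healthy panel encodes artifacts and validates arguments", {
  grid <- small_grid()
  expect_error(simulate_healthy_panel(grid, artifact_multiplier = 0),
               "artifact_multiplier")
  pan <- simulate_healthy_panel(grid, n_controls = 6, total_reads = 5e4,
                                artifact_bins = 1:10, artifact_multiplier = 3,
                                noise_model = "poisson", params = flat_bias(),
                                seed = 8)
  expect_equal(dim(pan$counts), c(nrow(grid), 6))
  m_art <- mean(pan$counts[1:10, ]); m_clean <- mean(pan$counts[-(1:10), ])
  expect_equal(m_art / m_clean, 3, tolerance = 0.1)
  # multiplier 1 leaves artifact bins indistinguishable in expectation
  pan1 <- simulate_healthy_panel(grid, n_controls = 6, total_reads = 5e4,
                                 artifact_bins = 1:10,
                                 artifact_multiplier = 1,
                                 noise_model = "poisson",
                                 params = flat_bias(), seed = 9)
  expect_equal(mean(pan1$counts[1:10, ]) / mean(pan1$counts[-(1:10), ]), 1,
               tolerance = 0.1)
})

test_that("cohort plans and cohorts respect their contracts", {
  grid <- small_grid()
  plan <- cohort_plan(n_subjects = c(PR = 2, SD = 2, PD = 2),
                      total_reads = 2e4)
  expect_equal(nrow(plan), 18)
  # group trajectories follow the configured dynamics
  traj <- default_trajectories()
  expect_true(all(diff(traj$PD) >= 0))
  expect_true(all(diff(traj$PR) < 0))
  expect_true(all(diff(traj$SD) == 0))
  # single-timepoint plans pick the right trajectory entry by name
  p6 <- cohort_plan(n_subjects = c(PD = 1), timepoints = "wk6")
  expect_equal(p6$tumour_fraction, traj$PD[["wk6"]])
  coh <- simulate_cohort(plan, grid, seed = 10)
  expect_equal(length(coh$samples), nrow(plan))
  expect_identical(coh$truth$tumour_fraction, plan$tumour_fraction)
  dup <- rbind(plan, plan[1, ])
  expect_error(simulate_cohort(dup, grid, seed = 1), "duplicate")
  c1 <- simulate_cohort(plan, grid, seed = 12)
  c2 <- simulate_cohort(plan, grid, seed = 12)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$samples[[3]]$counts, c2$samples[[3]]$counts)
})

test_that("expression fixture plants the configured truth", {
  expect_error(simulate_expression(n_per_group = c(SD = 2, PD = 6)), ">= 3")
  null_fix <- simulate_expression(n_genes = 50, effect_log2fc = 0,
                                  n_extra_degs = 0, seed = 1)
  expect_length(null_fix$truth$signature, 0)
  expect_length(null_fix$truth$up, 0)
  fix <- simulate_expression(n_genes = 100, effect_log2fc = 2,
                             n_extra_degs = 10, seed = 2)
  expect_setequal(fix$truth$signature,
                  c("CHGA", "FGF10", "PTPRC", "MIA", "TRIM72", "SEC14L2"))
  expect_true(all(fix$truth$signature %in% rownames(fix$counts)))
  expect_equal(dim(fix$counts), c(100, 18))
  expect_identical(fix$counts,
                   simulate_expression(n_genes = 100, effect_log2fc = 2,
                                       n_extra_degs = 10, seed = 2)$counts)
  # signature genes really are shifted up in the benefit group
  ben <- fix$labels != "PD"
  shift <- rowMeans(fix$counts[fix$truth$signature, ben]) /
    pmax(rowMeans(fix$counts[fix$truth$signature, !ben]), 1)
  expect_true(median(shift) > 2)
})
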