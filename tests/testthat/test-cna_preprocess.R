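# Preprocessing: downsampling, bias correction, masking, log2 ratios.

test_that("downsampling is exact without-replacement thinning", {
  grid <- small_grid(60, n_chroms = 1)
  s <- simulate_sample(grid, NULL, 0, 1e4, noise_model = "poisson", seed = 1)
  expect_identical(downsample_counts(s, sum(s$counts)), s)
  # zero bins stay zero, total hit exactly
  s2 <- s; s2$counts <- c(10L, 0L, 10L, rep(0L, nrow(grid) - 3))
  s2$total_reads <- 20L
  d <- downsample_counts(s2, 10, seed = 2)
  expect_equal(sum(d$counts), 10)
  expect_equal(d$counts[2], 0)
  expect_true(all(d$counts <= s2$counts))
  # error names both totals
  expect_error(downsample_counts(s2, 100), "100.*20|20.*100")
  expect_warning(d3 <- downsample_counts(s2, 100, allow_smaller = TRUE),
                 "fewer")
  expect_identical(d3$counts, s2$counts)
})

test_that("downsampled counts match the hypergeometric mean", {
  grid <- small_grid(60, n_chroms = 1)
  s <- simulate_sample(grid, NULL, 0, 100, noise_model = "poisson", seed = 1)
  s$counts <- c(100L, 100L, rep(0L, nrow(grid) - 2))
  s$total_reads <- 200L
  reps <- 400
  set.seed(3)
  first <- replicate(reps, downsample_counts(s, 100)$counts[1])
  # hypergeometric: mean 50, var = 100*.5*.5*100/199
  se <- sqrt(100 * 0.25 * 100 / 199 / reps)
  expect_lt(abs(mean(first) - 50), 3 * se)
})

test_that("GC/mappability correction inverts the bias model", {
  grid <- make_bin_grid(1000, n_chroms = 2, seed = 4)
  # bias-free sample: correction is close to a no-op
  s0 <- simulate_sample(grid, NULL, 0, 3e5, params = flat_bias(), seed = 5)
  corr0 <- correct_gc_mappability(s0, grid)
  expect_lt(abs(mean(corr0) / mean(s0$counts) - 1), 0.02)
  # GC bias (monotone over the simulated GC range): corrected counts
  # decorrelate from GC
  sb <- simulate_sample(grid, NULL, 0, 3e5,
                        params = bias_params(gc_curvature = -20,
                                             gc_peak = 0.6), seed = 6)
  raw_rho <- cor(sb$counts, grid$gc, method = "spearman")
  corr <- correct_gc_mappability(sb, grid)
  expect_gt(abs(raw_rho), 0.2)
  expect_lt(abs(cor(corr, grid$gc, method = "spearman")), 0.1)
  # constant counts with varying gc stay constant
  sc <- sb; sc$counts <- rep(100L, nrow(grid))
  cc <- correct_gc_mappability(sc, grid)
  expect_equal(cc, rep(100, nrow(grid)), tolerance = 1e-6)
  expect_error(correct_gc_mappability(sb$counts[1:20], small_grid(20)),
               ">= 50")
})

test_that("static blacklist masking is pure bookkeeping", {
  grid <- small_grid(100, n_chroms = 1, static_blacklist_frac = 0.1)
  v <- rep(1, 100)
  masked <- apply_static_blacklist(v, grid)
  expect_equal(attr(masked, "n_masked"), sum(grid$static_blacklist))
  expect_equal(sum(!is.na(masked)), 100 - sum(grid$static_blacklist))
  g0 <- grid; g0$static_blacklist <- FALSE
  expect_equal(as.numeric(apply_static_blacklist(v, g0)), v)
  g1 <- grid; g1$static_blacklist <- TRUE
  expect_error(apply_static_blacklist(v, g1), "no usable bins")
})

test_that("control normalisation divides by the median", {
  expect_equal(median_normalise_control(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(median_normalise_control(rep(7, 5)), rep(1, 5))
  expect_equal(median_normalise_control(c(2, 4, 6)),
               median_normalise_control(10 * c(2, 4, 6)))
  expect_error(median_normalise_control(c(0, 0, 0)), "positive")
})

test_that("log2 ratios are median-centred and mask degenerate bins", {
  grid <- small_grid(100, n_chroms = 1, static_blacklist_frac = 0)
  ctrl <- rep(1, 100)
  expect_equal(log2_ratio(ctrl, ctrl, grid)$log2r, rep(0, 100))
  # global scale is unidentifiable: 2x control re-centres to zero
  expect_equal(log2_ratio(2 * ctrl, ctrl, grid)$log2r, rep(0, 100))
  # one doubled bin stands out at ~1 while the rest sit at ~0
  s <- ctrl; s[10] <- 2
  p <- log2_ratio(s, ctrl, grid)
  expect_equal(p$log2r[10], 1)
  expect_equal(p$log2r[-10], rep(0, 99))
  # zero-count and zero-control bins are masked, not pseudocounted
  s2 <- ctrl; s2[5] <- 0
  c2 <- ctrl; c2[7] <- 0
  p2 <- log2_ratio(s2, c2, grid)
  expect_true(all(p2$mask[c(5, 7)]))
  expect_true(all(is.na(p2$log2r[c(5, 7)])))
  expect_error(log2_ratio(ctrl[1:20], ctrl[1:20], small_grid(20)), "usable")
})

test_that("noise-free dilution recovery is exact through the ratio stage", {
  grid <- small_grid(400, n_chroms = 1, static_blacklist_frac = 0)
  prof <- cna_profile(c(21, 201), c(100, 280), c(4, 1))
  cn <- rep(2, 400); cn[21:100] <- 4; cn[201:280] <- 1
  r <- expected_bin_rate(grid, bias_params())
  f <- 0.3
  sample_mu <- r * (2 * (1 - f) + f * cn) / 2
  control_mu <- r
  p <- log2_ratio(sample_mu, control_mu, grid)
  expect_equal(p$log2r[21:100], rep(log2((2 * 0.7 + 0.3 * 4) / 2), 80),
               tolerance = 1e-6)
  expect_equal(p$log2r[201:280], rep(log2((2 * 0.7 + 0.3 * 1) / 2), 80),
               tolerance = 1e-6)
  expect_equal(p$log2r[1:20], rep(0, 20), tolerance = 1e-6)
})
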