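# Expression normalisation, differential ranking, PCA separation,
# co-expression.

test_that("median normalisation equalises sample medians and keeps ranks", {
  m <- matrix(rpois(200, 50) + 1, 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  mn <- median_normalise(m)
  meds <- apply(mn, 2, function(col) median(col[col > 0]))
  expect_equal(unname(meds), rep(meds[[1]], 10))
  # a doubled sample comes back into line
  m2 <- m; m2[, 3] <- 2 * m[, 3]
  mn2 <- median_normalise(m2)
  expect_equal(median(mn2[, 3]), median(mn2[, 1]), tolerance = 0.1)
  # within-sample rank order is preserved (pure rescaling)
  expect_equal(order(mn[, 5]), order(m[, 5]))
  m3 <- m; m3[, 2] <- 0
  expect_error(median_normalise(m3), "median")
})

test_that("differential ranking finds planted signature genes", {
  fix <- simulate_expression(n_genes = 300, n_per_group = c(SD = 12, PD = 6),
                             effect_log2fc = 2, n_extra_degs = 10, seed = 41)
  deg <- rank_degs(fix$counts, fix$labels)
  expect_s3_class(deg, "deg_table")
  expect_true(all(deg$q >= deg$p - 1e-12))
  top <- top_k_overexpressed(deg, 6)
  expect_setequal(top, fix$truth$signature)
  # constant genes are never differential
  m <- fix$counts; m[1, ] <- 5L
  deg2 <- rank_degs(m, fix$labels, normalise = FALSE)
  expect_equal(deg2$p[deg2$gene == rownames(m)[1]], 1)
  expect_false(deg2$deg[deg2$gene == rownames(m)[1]])
  expect_error(rank_degs(fix$counts[, 1:8],
                         c(rep("SD", 6), rep("PD", 2))), ">= 3")
})

test_that("BH adjustment equals the textbook step-up", {
  set.seed(42)
  for (r in 1:20) {
    p <- runif(sample(10:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("top-k selection warns when short of overexpressed genes", {
  deg <- data.frame(gene = c("a", "b", "c"), log2fc = c(2, 1, -2),
                    p = c(0.001, 0.002, 0.001), q = c(0.01, 0.02, 0.01),
                    deg = c(TRUE, TRUE, TRUE),
                    direction = c("up", "up", "down"))
  expect_equal(top_k_overexpressed(deg, 2), c("a", "b"))
  expect_warning(res <- top_k_overexpressed(deg, 6), "only 2")
  expect_equal(res, c("a", "b"))
  none <- deg; none$direction <- "down"
  expect_warning(res2 <- top_k_overexpressed(none, 2), "no overexpressed")
  expect_length(res2, 0)
})

test_that("PCA separation scores separated and shuffled data sensibly", {
  set.seed(43)
  n1 <- 10; n2 <- 8
  m <- cbind(matrix(rnorm(5 * n1, 0), 5), matrix(rnorm(5 * n2, 5), 5))
  rownames(m) <- paste0("g", 1:5)
  labels <- c(rep("SD", n1), rep("PD", n2))
  ps <- pca_separation(m, labels)
  expect_gt(ps$separation_score, 0.5)
  expect_equal(dim(ps$scores), c(18, 2))
  # the sign convention makes the projection deterministic
  ps2 <- pca_separation(m, labels)
  expect_equal(ps$scores, ps2$scores)
  # shuffled labels give near-zero separation
  sh <- replicate(20, {
    pca_separation(m, sample(labels))$separation_score
  })
  expect_lt(abs(median(sh)), 0.2)
  expect_error(pca_separation(m, c(rep("SD", 17), "PD")), ">= 2 samples")
  expect_error(pca_separation(m[1, , drop = FALSE], labels), ">= 2 genes")
})

test_that("top-2 projection matches the SVD rank-2 optimum", {
  set.seed(44)
  m <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(paste0("g", 1:8), NULL))
  z <- t(scale(t(m)))
  ps <- pca_separation(m, rep(c("SD", "PD"), 6))
  sv <- svd(t(z))
  oracle_scores <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2)
    expect_equal(abs(ps$scores[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("subset comparison favours planted overexpressed genes", {
  fix <- simulate_expression(n_genes = 200, n_per_group = c(SD = 12, PD = 6),
                             effect_log2fc = 2, n_extra_degs = 6, seed = 45)
  deg <- rank_degs(fix$counts, fix$labels)
  cmp <- signature_comparison(fix$counts, deg, fix$labels, k = 6)
  sc <- function(name) cmp$separation_score[cmp$subset == name]
  expect_gte(sc("top_k_overexpressed"), sc("all_genes"))
  # k = 0 rows are flagged as unavailable rather than erroring
  cmp0 <- signature_comparison(fix$counts, deg, fix$labels, k = 0)
  expect_true(is.na(sc0 <- cmp0$separation_score[
    cmp0$subset == "top_k_overexpressed"]))
})

test_that("Spearman co-expression behaves at the boundaries", {
  m <- rbind(a = 1:10, b = 10:1, c = rep(2, 10),
             d = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  sc <- spearman_corr(m)
  expect_equal(sc$rho["a", "a"], 1)
  expect_equal(sc$rho["a", "b"], -1)
  expect_true(all(is.na(sc$rho["c", ])))
  expect_true(sc$p["a", "d"] < 0.05)
  set.seed(46)
  null_m <- matrix(rnorm(40 * 20), 40,
                   dimnames = list(paste0("g", 1:40), NULL))
  sn <- spearman_corr(null_m)
  offdiag <- abs(sn$rho[upper.tri(sn$rho)])
  expect_lt(median(offdiag), 0.25)
  expect_error(spearman_corr(m[, 1:3]), ">= 4")
})
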