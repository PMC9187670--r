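# Exploratory expression analysis: median normalisation, differential
# ranking with FDR control, top-k overexpressed selection, PCA separation
# scoring and Spearman co-expression.
#
# The differential statistic is a self-contained two-sided rank-sum test
# (not a count-model fit): selection, FDR thresholding and the downstream
# PCA logic are the procedures of interest here and are independent of the
# per-gene test used to rank.

#' Median-normalise an expression matrix
#'
#' Scales each sample (column) so all sample medians (over genes with
#' positive expression) equal the global median of those medians.
#'
#' @param mat genes x samples non-negative matrix.
#' @return normalised matrix of the same shape.
#' @export
median_normalise <- function(mat) {
  stop_if_not(is.matrix(mat) && all(mat >= 0), "need a non-negative matrix")
  meds <- apply(mat, 2, function(col) median(col[col > 0]))
  bad <- !is.finite(meds) | meds <= 0
  if (any(bad))
    stop(sprintf("sample(s) %s have non-positive median expression",
                 paste(colnames(mat)[bad] %||% which(bad), collapse = ", ")),
         call. = FALSE)
  target <- median(meds)
  sweep(mat, 2, target / meds, `*`)
}

#' Rank genes for differential expression (benefit vs PD)
#'
#' Per-gene two-sided rank-sum test on median-normalised values comparing
#' the benefit group (all non-PD samples) against PD, with
#' Benjamini-Hochberg adjustment. A gene is called differential when
#' `p < p_cut` and `q < q_cut`. Direction and log2 fold change come from
#' group means (benefit over PD).
#'
#' At the panel's typical group sizes the normal approximation floors the
#' attainable p-value above what an FDR cut of 0.1 can pass, so candidate
#' genes (approximate p below `exact_below`) are re-tested exactly: via the
#' closed-form rank-sum null when the gene has no tied values, or full
#' midrank enumeration otherwise (group sizes permitting).
#'
#' @param mat genes x samples count or normalised matrix.
#' @param labels per-sample group labels (`PD` vs anything else).
#' @param p_cut,q_cut thresholds (defaults 0.05 and 0.1).
#' @param normalise median-normalise first (default `TRUE`).
#' @param exact_below approximate-p threshold under which the exact test is
#'   used; 0 disables exact testing.
#' @return data frame of class `deg_table`: `gene`, `log2fc`, `p`, `q`,
#'   `direction` (`up`/`down`/`none`), `deg` (logical), sorted by `p`.
#' @export
rank_degs <- function(mat, labels, p_cut = 0.05, q_cut = 0.1,
                      normalise = TRUE, exact_below = 0.1) {
  stop_if_not(is.matrix(mat) && ncol(mat) == length(labels),
              "labels must match matrix columns")
  pd <- labels == "PD"
  stop_if_not(sum(pd) >= 3 && sum(!pd) >= 3,
              "need >= 3 samples per group (got %d benefit, %d PD)",
              sum(!pd), sum(pd))
  m <- if (normalise) median_normalise(mat) else mat
  eps <- 0.5
  n <- length(labels)
  nb <- sum(!pd)
  enum_sets <- NULL
  can_enum <- choose(n, nb) <= 1e5
  exact_p <- function(v) {
    r <- rank(v)
    if (!anyDuplicated(v)) {
      U <- sum(r[!pd]) - nb * (nb + 1) / 2
      mn <- nb * (n - nb)
      lo <- min(U, mn - U)
      p <- stats::pwilcox(lo, nb, n - nb) +
        (1 - stats::pwilcox(mn - lo - 1, nb, n - nb))
      return(min(1, p))
    }
    if (!can_enum) return(NA_real_)
    if (is.null(enum_sets))
      enum_sets <<- combn(n, nb)
    rs <- colSums(matrix(r[enum_sets], nrow = nb))
    mu <- nb * (n + 1) / 2
    mean(abs(rs - mu) >= abs(sum(r[!pd]) - mu) - 1e-9)
  }
  res <- t(apply(m, 1, function(v) {
    if (sd(v) == 0) {
      p <- 1; diff <- 0
    } else {
      p <- wilcoxon_rank_sum(v[!pd], v[pd], mode = "normal")$p.value
      if (exact_below > 0 && p < exact_below) {
        pe <- exact_p(v)
        if (!is.na(pe)) p <- pe
      }
      diff <- mean(v[!pd]) - mean(v[pd])
    }
    lfc <- log2((mean(v[!pd]) + eps) / (mean(v[pd]) + eps))
    c(lfc = lfc, p = p, diff = diff)
  }))
  q <- p.adjust(res[, "p"], method = "BH")
  out <- data.frame(gene = rownames(mat) %||% seq_len(nrow(mat)),
                    log2fc = res[, "lfc"], p = res[, "p"], q = q,
                    stringsAsFactors = FALSE)
  out$deg <- out$p < p_cut & out$q < q_cut
  out$direction <- ifelse(!out$deg, "none",
                          ifelse(res[, "diff"] > 0, "up", "down"))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Top-k overexpressed differential genes
#'
#' Differential genes with positive direction, ranked by log2 fold change
#' (largest first; adjusted p-value breaks ties); the first `k` are
#' returned. "Top overexpressed" is read as strongest overexpression among
#' the genes that pass the significance cuts — the discrete rank-test
#' p-values tie heavily at their attainable floor, so fold change is the
#' informative ranking. Fewer than `k` available returns all of them with a
#' warning.
#'
#' @param deg_table a [rank_degs()] table.
#' @param k number of genes (default 6).
#' @return character vector of gene labels.
#' @export
top_k_overexpressed <- function(deg_table, k = 6) {
  stop_if_not(k >= 0, "`k` must be >= 0")
  up <- deg_table[deg_table$deg & deg_table$direction == "up", ]
  up <- up[order(-up$log2fc, up$q), ]
  if (nrow(up) == 0) {
    warning("no overexpressed differential genes")
    return(character(0))
  }
  if (nrow(up) < k)
    warning(sprintf("only %d overexpressed differential genes (< k = %d)",
                    nrow(up), k))
  head(up$gene, k)
}

#' PCA projection and group-separation score
#'
#' Genes are centred and unit-scaled across samples, samples are projected
#' onto the top two principal axes (sign fixed so the largest-absolute
#' loading of each component is positive), and separation between PD and
#' the benefit group is scored as the mean silhouette width of the two
#' groups in the 2-component space.
#'
#' @param mat genes x samples matrix restricted to the gene subset of
#'   interest (>= 2 genes).
#' @param labels per-sample labels; grouping is PD vs the rest.
#' @return list: `scores` (samples x 2), `loadings`, `separation_score`,
#'   `var_explained`.
#' @export
pca_separation <- function(mat, labels) {
  stop_if_not(is.matrix(mat) && nrow(mat) >= 2, "need >= 2 genes")
  stop_if_not(ncol(mat) == length(labels), "labels must match columns")
  grp <- ifelse(labels == "PD", "PD", "benefit")
  stop_if_not(all(table(grp) >= 2) && length(unique(grp)) == 2,
              "silhouette needs >= 2 samples in each of the two groups")
  sds <- apply(mat, 1, sd)
  keep <- sds > 0
  stop_if_not(sum(keep) >= 2, "need >= 2 non-constant genes")
  z <- t(scale(t(mat[keep, , drop = FALSE])))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  ncomp <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {           # sign convention
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  sil <- cluster::silhouette(as.integer(factor(grp)), dist(scores))
  list(scores = scores, loadings = load,
       separation_score = mean(sil[, "sil_width"]),
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)])
}

#' Compare PCA separation across gene subsets
#'
#' Computes the separation score for four nested views of the data: all
#' genes, all differential genes, the top-k overexpressed and the top-k
#' underexpressed differential genes, and orders them.
#'
#' @param mat genes x samples matrix (counts; normalised internally).
#' @param deg_table a [rank_degs()] table on the same genes.
#' @param labels per-sample labels.
#' @param k subset size (default 6).
#' @return data frame with `subset`, `n_genes`, `separation_score`, ordered
#'   by decreasing score; skipped subsets carry `NA`.
#' @export
signature_comparison <- function(mat, deg_table, labels, k = 6) {
  m <- median_normalise(mat)
  degs <- deg_table$gene[deg_table$deg]
  up <- top_k_overexpressed(deg_table, k)
  dn <- {
    d <- deg_table[deg_table$deg & deg_table$direction == "down", ]
    d <- d[order(d$log2fc, d$q), ]
    head(d$gene, k)
  }
  subsets <- list(all_genes = rownames(m), all_degs = degs,
                  top_k_overexpressed = up, top_k_underexpressed = dn)
  score <- function(genes) {
    if (length(genes) < 2) return(NA_real_)
    tryCatch(pca_separation(m[genes, , drop = FALSE], labels)$separation_score,
             error = function(e) NA_real_)
  }
  out <- data.frame(subset = names(subsets),
                    n_genes = vapply(subsets, length, 0L),
                    separation_score = vapply(subsets, score, 0.0),
                    stringsAsFactors = FALSE)
  out[order(-out$separation_score, na.last = TRUE), ]
}

#' Pairwise Spearman co-expression
#'
#' Spearman rank correlations (midranks for ties) among a gene list, with
#' p-values from the t approximation. Constant genes yield `NA` entries.
#'
#' @param mat genes x samples matrix.
#' @param genes gene labels to correlate (>= 2; default all).
#' @return list: `rho` and `p` (symmetric matrices).
#' @export
spearman_corr <- function(mat, genes = rownames(mat)) {
  stop_if_not(ncol(mat) >= 4, "need >= 4 samples")
  sub <- mat[genes, , drop = FALSE]
  n <- ncol(sub)
  constant <- apply(sub, 1, function(v) sd(v) == 0)
  rho <- suppressWarnings(cor(t(sub), method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho)[!constant] <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(rho = rho, p = p)
}
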