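# Shared small fixtures, built in code.

small_grid <- function(n_bins = 200, n_chroms = 2, seed = 11, ...) {
  make_bin_grid(n_bins, bin_size = 30000L, n_chroms = n_chroms, seed = seed,
                ...)
}

# Brute-force Clopper-Pearson oracle: invert the binomial tail probabilities
# directly by root finding on the monotone tail functions.
cp_oracle <- function(x, n, level = 0.95) {
  a <- 1 - level
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  100 * c(lower, upper)
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
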