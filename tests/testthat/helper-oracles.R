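# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, textbook formulas) so they share no
# code path with the package implementation.

# Benjamini-Hochberg step-up, element by element.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}

# Square-root Z statistic and two-sided p, scalar textbook form.
z_brute <- function(x1, N1, x2, N2) {
  z <- (sqrt(x1 / N1) - sqrt(x2 / N2)) / (0.5 * sqrt(1 / N1 + 1 / N2))
  c(z = z, p = 2 * (1 - pnorm(abs(z))))
}

# Signed fold change with pseudocount applied only at zeros.
fc_brute <- function(x1, N1, x2, N2, pc = 0.5) {
  if (x1 == 0 || x2 == 0) { x1 <- x1 + pc; x2 <- x2 + pc }
  if (x1 == 0 && x2 == 0) return(NA_real_)
  r <- (x2 / N2) / (x1 / N1)
  if (r >= 1) r else -1 / r
}

# One-way ANOVA from explicit sums of squares.
anova_brute <- function(values, groups) {
  groups <- as.character(groups)
  g <- unique(groups)
  k <- length(g)
  n <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (gg in g) {
    v <- values[groups == gg]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = F, p = 1 - pf(F, k - 1, n - k))
}

# Tukey HSD adjusted p for one pair, from the studentized range law.
tukey_pair_brute <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  g <- unique(groups)
  k <- length(g)
  n <- length(values)
  ssw <- 0
  for (gg in g) {
    v <- values[groups == gg]
    ssw <- ssw + sum((v - mean(v))^2)
  }
  mse <- ssw / (n - k)
  v1 <- values[groups == g1]; v2 <- values[groups == g2]
  se <- sqrt(mse / 2 * (1 / length(v1) + 1 / length(v2)))
  q <- abs(mean(v1) - mean(v2)) / se
  1 - ptukey(q, k, n - k)
}

# Fraction of C calls at one 0-based site offset across full-length reads.
site_pct_brute <- function(reads, offset) {
  base <- substr(as.character(reads), offset + 1, offset + 1)
  100 * sum(base == "C") / sum(base %in% c("C", "T"))
}

toy_count_table <- function() {
  readCountTable(system.file("extdata", "toy_counts.tsv",
                             package = "dremseq"))
}
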