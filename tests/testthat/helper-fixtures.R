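# Shared fixtures built in code.

# small noiseless feature table: 4 study samples, known dilutions, 3 QC rows
tiny_table <- function() {
  base <- c(100, 200, 400, 800)
  dil <- c(1, 2, 0.5, 1)
  ints <- rbind(outer(dil, base), outer(c(1 / 3, 1 / 5, 1 / 7), base))
  feature_meta <- data.frame(feature_id = paste0("F", 1:4),
                             mz = c(100.1, 200.2, 300.3, 400.4),
                             rt = 1:4, ion_mode = "NEG")
  sample_meta <- data.frame(
    sample_id = c(paste0("S", 1:4), paste0("QC", 1:3)),
    group = c("case", "case", "control", "control", rep("none", 3)),
    sample_type = c(rep("study", 4), rep("QC", 3)),
    nominal_dilution = c(rep(NA, 4), 1 / 3, 1 / 5, 1 / 7))
  feature_table(ints, feature_meta, sample_meta)
}

# separated two-class data for classification tests
separated_xy <- function(n_per = 8, p = 20, delta = 4, sd = 0.3, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p)
  X[seq_len(n_per), 1:3] <- X[seq_len(n_per), 1:3] + delta
  colnames(X) <- sprintf("F%04d", seq_len(p))
  list(x = X, y = factor(rep(c("case", "control"), each = n_per)))
}

# brute-force two-sided Fisher p over all tables with the observed margins,
# using exact integer-valued choose() products (all < 2^53 for N <= 40)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  num <- choose(m, support) * choose(n, k - support)
  den <- choose(m + n, k)
  obs <- num[support == a]
  sum(num[num <= obs]) / den
}

# exact hypergeometric ORA oracle by combinatorial summation
ora_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
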