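# Shared fixture builders and brute-force oracles.

# a minimal cow table with explicit haplotypes
make_cows <- function(haps1, haps2, ids = sprintf("C%03d", seq_along(haps1))) {
  tibble::tibble(animal_id = ids, hap1 = haps1, hap2 = haps2)
}

# noiseless simulation config (no design effects, no noise)
noiseless_config <- function(...) {
  sim_config(expression = expression_model(cv_noise = 0),
             herd_sd = 0, plate_sd = 0, ...)
}

# brute-force upper-tail hypergeometric: P(X >= x) by direct enumeration
brute_hyper_tail <- function(x, K, N, n) {
  j <- max(x, 0):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# textbook one-way ANOVA F from between/within mean squares
brute_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  k <- nlevels(groups)
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# letter-display consistency: sharing a letter <=> pair not significant
letters_consistent <- function(letters_vec, pmat, alpha) {
  groups <- names(letters_vec)
  for (i in seq_along(groups)[-1]) {
    for (j in seq_len(i - 1)) {
      share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                strsplit(letters_vec[j], "")[[1]])) > 0
      sig <- pmat[groups[i], groups[j]] < alpha
      if (share == sig) return(FALSE)
    }
  }
  TRUE
}
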