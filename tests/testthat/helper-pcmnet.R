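# Shared helpers: independent oracles and small simulation utilities.

# Adjusted Rand index between two labelings (direct pair-counting formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  s <- sum(choose(tab, 2))
  expected <- si * sj / choose(length(a), 2)
  (s - expected) / ((si + sj) / 2 - expected)
}

# Brute-force O(m^2) Benjamini-Hochberg step-up: q(i) = min_{j >= i} p(j)*m/j
# computed literally from the definition, independent of stats::p.adjust.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Wigginton-style exact HWE probabilities by ratio recurrence over
# heterozygote counts (independent route: no lgamma).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h+2)/P(h) = 4 * hom_r * hom_c / ((h+2)*(h+1))
      probs[k + 1] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- match(n_Aa, hets)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

# Small planted-structure cohort used across network tests.
planted_cohort <- function(n = 300, p = 10, seed = 1, ...) {
  gt <- make_precision_matrix(p = p, n_communities = 2, seed = seed, ...)
  co <- simulate_cohort(n, gt, seed = seed + 5000)
  list(gt = gt, cohort = co, processed = preprocess_cohort(co))
}

support_metrics <- function(weights, precision_true) {
  truth <- abs(precision_true) > 1e-8 & !diag(nrow(precision_true))
  est <- weights != 0
  ut <- upper.tri(truth)
  tp <- sum(est[ut] & truth[ut])
  c(precision = tp / max(1, sum(est[ut])), recall = tp / sum(truth[ut]))
}
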