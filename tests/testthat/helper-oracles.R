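# Independent oracles used across the suite.

# Brute-force pairing enumeration: represent each pool as integer molecule
# counts and count the four configuration pairings directly. Independent of
# the closed-form coupling algebra.
brute_force_coupling <- function(nS1, nR1, nS2, nR2) {
  pairs <- expand.grid(c1 = rep(c("S", "R"), c(nS1, nR1)),
                       c2 = rep(c("S", "R"), c(nS2, nR2)))
  n1 <- nS1 + nR1
  counts <- table(factor(paste0(pairs$c1, pairs$c2),
                         levels = c("SR", "RS", "SS", "RR")))
  # scale from n1*n2 ordered pairs to n1 dimers (equal pool totals assumed)
  as.numeric(counts) / (nS2 + nR2)
}

# reference Kagan relations evaluated directly (forward residual check)
kagan_product_residual <- function(s, C, ee) {
  log(1 - C * (1 + ee)) / log(1 - C * (1 - ee)) - s
}

ee_from_pool_counts <- function(nS, nR) (nS - nR) / (nS + nR)
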