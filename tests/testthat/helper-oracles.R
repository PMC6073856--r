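# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: direct summation of binomial-coefficient ratios.
hyper_tail_enum <- function(N, K, n, c) {
  i <- c:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# padj_(i) = min over j >= i of p_(j) * m / j, clipped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Sequential biased-urn sampler (Wallenius model): n draws without
# replacement from m1 items of odds w and m2 items of odds 1; returns
# the number of odds-weighted items drawn per replicate.
rwallenius_urn <- function(reps, m1, m2, n, w) {
  white <- rep(m1, reps)
  black <- rep(m2, reps)
  for (j in seq_len(n)) {
    p_white <- w * white / (w * white + black)
    take <- stats::runif(reps) < p_white
    white <- white - take
    black <- black - !take
  }
  m1 - white
}

# Two-feature, two-sample toy count matrix.
toy_cm <- function(counts = matrix(c(10L, 30L, 20L, 60L), 2,
                                   dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2"))),
                   feature_class = "mRNA",
                   group = c("control", "treatment")) {
  count_matrix(counts, feature_class, group)
}

# Small interaction map: m1 -> {g1, g2}, m2 -> {g1, g3}, universe of 10.
toy_map <- function() {
  interaction_map(list(m1 = c("g1", "g2"), m2 = c("g1", "g3")),
                  universe = c(paste0("m", 1:10)))
}
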