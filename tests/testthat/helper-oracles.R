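# Independent brute-force oracles for the information measures.
# Deliberately written as plain elementwise loops with compensated (Kahan)
# summation, sharing no code with the package implementations.

kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

oracle_entropy <- function(p, q) {
  if (q == 1) {
    terms <- numeric(0)
    for (i in seq_along(p)) if (p[i] > 0) terms <- c(terms, -p[i] * log(p[i]))
    kahan_sum(terms) / log(2)
  } else {
    terms <- numeric(0)
    for (i in seq_along(p)) if (p[i] > 0) terms <- c(terms, exp(q * log(p[i])))
    log(kahan_sum(terms)) / ((1 - q) * log(2))
  }
}

oracle_divergence <- function(joint, q) {
  px <- numeric(4); py <- numeric(4)
  for (i in 1:4) for (j in 1:4) {
    px[i] <- px[i] + joint[i, j]
    py[j] <- py[j] + joint[i, j]
  }
  terms <- numeric(0)
  if (q == 1) {
    for (i in 1:4) for (j in 1:4) if (joint[i, j] > 0)
      terms <- c(terms, joint[i, j] * log(joint[i, j] / (px[i] * py[j])))
    kahan_sum(terms) / log(2)
  } else {
    for (i in 1:4) for (j in 1:4) if (joint[i, j] > 0)
      terms <- c(terms, exp(q * log(joint[i, j]) +
                              (1 - q) * log(px[i] * py[j])))
    log(kahan_sum(terms)) / ((q - 1) * log(2))
  }
}

oracle_redundancy <- function(p, q) 1 - oracle_entropy(p, q) / 2

oracle_complexity <- function(D) {
  n <- nrow(D)
  terms <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    terms <- c(terms, D[i, j])
  kahan_sum(terms) / (n * (n - 1) * 2)
}

# exhaustive pairwise win-fraction AUC (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "binding")
  neg <- which(labels == "genomic")
  wins <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# random test-case generators ------------------------------------------

random_dist <- function() {
  # mix of dense, sparse and near-degenerate distributions
  kind <- sample(3L, 1L)
  p <- switch(kind,
    as.vector(stats::rgamma(4, 1)),
    { x <- as.vector(stats::rgamma(4, 0.3)); x },
    { x <- c(1, stats::runif(3, 0, 1e-4)); x })
  if (sample(c(TRUE, FALSE), 1L)) p[sample(4L, sample(0:2, 1L))] <- 0
  if (all(p == 0)) p[1] <- 1
  p / sum(p)
}

random_joint <- function() {
  J <- matrix(stats::rgamma(16, sample(c(0.3, 1, 3), 1L)), 4, 4)
  if (sample(c(TRUE, FALSE), 1L)) J[sample(16L, sample(0:6, 1L))] <- 0
  if (all(J == 0)) J[1, 1] <- 1
  J / sum(J)
}

random_motif_strings <- function(I, L) {
  apply(matrix(sample(c("A", "C", "G", "T"), I * L, replace = TRUE), I, L),
        1L, paste, collapse = "")
}
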