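test_that("position probabilities are pseudocount-smoothed column frequencies", {
  m <- aligned_motifs(c("AA", "AC", "AG", "AT"))
  p0 <- estimate_position_probs(m, pseudocount = 0)
  expect_equal(unname(p0[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p0[, 2]), rep(0.25, 4))
  m2 <- aligned_motifs(c("AG", "AG", "AG", "CG"))
  p5 <- estimate_position_probs(m2, pseudocount = 0.5)
  expect_equal(unname(p5[, 1]), c(3.5, 1.5, 0.5, 0.5) / 6)
  expect_equal(colSums(p5), rep(1, 2), ignore_attr = TRUE)
})

test_that("pair joints count symbol pairs and keep marginals consistent", {
  m <- aligned_motifs(c("AC", "AC", "AC", "AC"))
  J <- estimate_pair_joint(m, 1, 2, pseudocount = 0)
  expect_equal(J["A", "C"], 1)
  expect_equal(sum(J), 1)

  m2 <- aligned_motifs(c("AA", "CC", "AA", "CC"))
  J2 <- estimate_pair_joint(m2, 1, 2, pseudocount = 0)
  expect_equal(J2["A", "A"], 0.5)
  expect_equal(J2["C", "C"], 0.5)

  m3 <- aligned_motifs(c("AC", "CA", "GG", "TT"))
  J3 <- estimate_pair_joint(m3, 1, 2, pseudocount = 0)
  expect_equal(J3["A", "C"], 0.25)
  expect_equal(J3["C", "A"], 0.25)
  expect_equal(J3["G", "G"], 0.25)
  expect_equal(J3["T", "T"], 0.25)

  # with pseudocount a the joint's marginals are the position frequencies
  # smoothed with 4a (each symbol absorbs a whole row/column of cells)
  withr::with_seed(5, m4 <- aligned_motifs(random_motif_strings(12, 6)))
  J4 <- estimate_pair_joint(m4, 2, 5, pseudocount = 0.5)
  p_with_4a <- function(col) {
    enc <- vapply(strsplit(m4$sequences, ""), function(s)
      match(s[col], c("A", "C", "G", "T")), integer(1))
    (tabulate(enc, 4) + 2) / (m4$I + 8)
  }
  expect_equal(unname(rowSums(J4)), p_with_4a(2), tolerance = 1e-12)
  expect_equal(unname(colSums(J4)), p_with_4a(5), tolerance = 1e-12)
  expect_error(estimate_pair_joint(m4, 3, 3), "differ")
})

test_that("redundancy profile reflects per-column conservation", {
  pure <- aligned_motifs(c("ACG", "ACG", "ACG", "ACG"))
  expect_equal(redundancy_profile(pure, q = 1.3, pseudocount = 0), rep(1, 3))
  flat <- aligned_motifs(c("AA", "CC", "GG", "TT"))
  expect_equal(redundancy_profile(flat, q = 0.5, pseudocount = 0), rep(0, 2))
  mixed <- aligned_motifs(c("ACG", "ACG", "ATG", "ATG"))
  expect_equal(redundancy_profile(mixed, q = 2, pseudocount = 0),
               c(1, 0.5, 1))
})

test_that("divergence matrix is symmetric with zero diagonal and detects
           perfect coupling", {
  coupled <- aligned_motifs(c("AA", "CC", "GG", "TT"))
  D <- divergence_matrix(coupled, q = 2, pseudocount = 0)
  expect_equal(D[1, 2], 2)
  expect_identical(D, t(D))
  expect_equal(diag(D), rep(0, 2))

  withr::with_seed(21, m <- aligned_motifs(random_motif_strings(15, 5)))
  D2 <- divergence_matrix(m, q = 1, pseudocount = 0.5)
  expect_identical(D2, t(D2))
  expect_equal(diag(D2), rep(0, 5))
  expect_true(all(D2 >= 0))
})

test_that("finite-sample threshold behaves like an estimation-bias estimate", {
  thr <- finite_sample_threshold(20, q = 1, method = "analytic_bias")
  expect_equal(thr$value, 9 / (40 * log(2)))

  t1 <- finite_sample_threshold(15, 1, n_permutations = 300, seed = 4)
  t2 <- finite_sample_threshold(15, 1, n_permutations = 300, seed = 4)
  expect_identical(t1$value, t2$value)

  t_small <- finite_sample_threshold(10, 1, n_permutations = 400, seed = 1)
  t_big <- finite_sample_threshold(5000, 1, n_permutations = 400, seed = 1)
  expect_lt(t_big$value, t_small$value / 20)
  expect_lt(t_big$value, 0.005)

  expect_warning(finite_sample_threshold(10, 1, n_permutations = 50),
                 "unstable")
})

test_that("screening keeps exactly the pairs above the threshold", {
  D <- matrix(0, 4, 4)
  expect_equal(nrow(screen_correlated_pairs(D, 0.1)), 0)
  D[2, 4] <- D[4, 2] <- 2
  D[1, 3] <- D[3, 1] <- 0.05
  got <- screen_correlated_pairs(D, 0.3)
  expect_equal(unname(got), matrix(c(2L, 4L), 1))
  all_pairs <- screen_correlated_pairs(matrix(0.2, 4, 4) - diag(0.2, 4), 0)
  expect_equal(nrow(all_pairs), 6)
})

test_that("lookup library equals naive appended-candidate recomputation", {
  withr::with_seed(33, m <- aligned_motifs(random_motif_strings(8, 4)))
  pairs <- rbind(c(1L, 2L), c(2L, 4L), c(3L, 4L))
  for (q in c(0.5, 1, 2)) {
    lib <- build_lookup_library(m, pairs, q, pseudocount = 0.5)
    expect_length(lib, nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      for (x in 1:4) for (y in 1:4) {
        cand <- rep("A", 4)
        cand[i] <- c("A", "C", "G", "T")[x]
        cand[j] <- c("A", "C", "G", "T")[y]
        m_aug <- aligned_motifs(c(m$sequences, paste(cand, collapse = "")))
        naive <- renyi_divergence(
          estimate_pair_joint(m_aug, i, j, pseudocount = 0.5), q)
        expect_lt(abs(lib[[k]][x, y] - naive), 1e-9)
      }
    }
  }
})

test_that("for a perfectly coupled pair, concordant candidates perturb the
           divergence less than discordant ones", {
  m <- aligned_motifs(c("AA", "CC", "GG", "TT"))
  lib <- build_lookup_library(m, rbind(c(1L, 2L)), q = 2, pseudocount = 0)
  tab <- lib[[1]]
  # every diagonal (concordant) entry beats every off-diagonal one
  expect_gt(min(diag(tab)), max(tab[row(tab) != col(tab)]))
})

test_that("training assembles a coherent model", {
  withr::with_seed(55, {
    spec <- motif_spec(L = 8, I = 25, conservation = 0.8,
                       coupled_pairs = list(c(2, 6)), coupling = 0.95,
                       seed = 9)
    model <- sigma_train(sample_motif_set(spec), q = 1,
                         screening = list(seed = 2))
  })
  expect_s3_class(model, "sigma_model")
  expect_equal(diag(model$divergence), rep(0, 8))
  expect_true(all(model$redundancy >= 0 & model$redundancy <= 1))
  expect_true(all(model$divergence >= 0))
  expect_gte(model$complexity, 0)
  expect_lte(model$complexity, 1)
  # the strongly coupled planted pair must be screened in
  expect_true(any(model$pairs[, 1] == 2 & model$pairs[, 2] == 6))
  expect_length(model$lookup, nrow(model$pairs))
  # per-position screened divergence sums match the matrix
  for (i in 1:8) {
    js <- c(model$pairs[model$pairs[, 1] == i, 2],
            model$pairs[model$pairs[, 2] == i, 1])
    expect_equal(model$div_rowsum[i],
                 sum(model$divergence[i, js]))
  }
})

test_that("complexity of trained models rises with generator coupling", {
  couplings <- seq(0, 1, length.out = 8)
  C <- vapply(couplings, function(cp) {
    mean(vapply(1:4, function(s) {
      spec <- motif_spec(L = 4, I = 30, conservation = 0.4,
                         coupled_pairs = list(c(1, 2), c(3, 4)),
                         coupling = cp, consensus = "ACGT", seed = 400 + s)
      m <- sample_motif_set(spec)
      motif_complexity(divergence_matrix(m, q = 1, pseudocount = 0.5))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(stats::cor(C, couplings, method = "spearman"), 0.9)
})
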