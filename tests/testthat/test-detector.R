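toy_model <- function(seqs, q = 2, pseudocount = 0, thr = 10) {
  # threshold 10 bits screens out everything; pass thr = 0 to keep all pairs
  sigma_train(aligned_motifs(seqs), q = q, pseudocount = pseudocount,
              threshold = thr)
}

test_that("gamma is zero for a candidate matching a fully conserved set", {
  model <- toy_model(c("ACGT", "ACGT", "ACGT"))
  expect_equal(gamma_profile(model, "ACGT"), rep(0, 4))
})

test_that("gamma matches hand arithmetic on the 3 x AA toy set", {
  model <- toy_model(c("AA", "AA", "AA"))
  # appending CC: each column becomes p = (3/4, 1/4, 0, 0);
  # R_2 = 1 - H_2/2 with H_2 = -log2(9/16 + 1/16) = log2(8/5)
  r_s <- 1 - log2(8 / 5) / 2
  expect_equal(gamma_profile(model, "CC"), rep(1 - r_s, 2))
  # and rho is the inverse redundancy-weighted sum (R^M = 1 at both columns)
  gf <- gain_features(model, "CC")
  expect_equal(unname(gf["rho"]), 1 / (2 * (1 - r_s)))
})

test_that("gamma is invariant to the order of training sequences", {
  withr::with_seed(8, seqs <- random_motif_strings(10, 6))
  cand <- "ACGTAC"
  g1 <- gamma_profile(toy_model(seqs, q = 1.5, pseudocount = 0.5), cand)
  g2 <- gamma_profile(toy_model(rev(seqs), q = 1.5, pseudocount = 0.5), cand)
  expect_equal(g1, g2)
})

test_that("omega is identically zero when no pairs are screened", {
  model <- toy_model(c("ACGT", "AGGT", "ACCT", "ACGA"), thr = 10)
  expect_equal(nrow(model$pairs), 0L)
  expect_equal(omega_profile(model, "ACGT"), rep(0, 4))
})

test_that("discordant candidates disturb a coupled pair more than
           concordant ones", {
  model <- toy_model(c("AA", "CC", "GG", "TT"), thr = 0.5)
  expect_equal(unname(model$pairs), matrix(c(1L, 2L), 1))
  w_conc <- omega_profile(model, "AA")
  w_disc <- omega_profile(model, "AC")
  expect_true(all(w_disc > w_conc))
  # with informative marginals the eta feature orders the same way
  model2 <- toy_model(c("AA", "AA", "CC", "CC"), thr = 0.5)
  expect_gt(gain_features(model2, "AA")["eta"],
            gain_features(model2, "AC")["eta"])
})

test_that("lookup and naive paths agree for gamma, omega and the features", {
  withr::with_seed(13, {
    spec <- motif_spec(L = 7, I = 15, conservation = 0.6,
                       coupled_pairs = list(c(1, 5), c(2, 7)),
                       coupling = 0.9, seed = 3)
    model <- sigma_train(sample_motif_set(spec), q = 1.4,
                         screening = list(seed = 1))
    for (rep in 1:30) {
      cand <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
      expect_equal(gamma_profile(model, cand, "lookup"),
                   gamma_profile(model, cand, "naive"), tolerance = 1e-9)
      expect_equal(omega_profile(model, cand, "lookup"),
                   omega_profile(model, cand, "naive"), tolerance = 1e-9)
      expect_equal(gain_features(model, cand, method = "lookup"),
                   gain_features(model, cand, method = "naive"),
                   tolerance = 1e-9)
    }
  })
})

test_that("a perfect-consensus candidate with no screened pairs hits the
           feature cap", {
  model <- toy_model(c("ACGT", "ACGT", "ACGT"))
  gf <- gain_features(model, "ACGT", epsilon = 1e-12)
  expect_equal(unname(gf), c(1e12, 1e12))
})

test_that("true sites concentrate at larger rho than background windows", {
  withr::with_seed(77, {
    spec <- motif_spec(L = 10, I = 20, conservation = 0.9, seed = 19)
    model <- sigma_train(sample_motif_set(spec), q = 1,
                         screening = list(seed = 1))
    pos <- sample_motif_set(spec, n = 200, seed = 20)$sequences
    bg <- sample_background(10000, seed = 21)
    starts <- sample.int(9991, 200)
    neg <- vapply(starts, function(s) substr(bg, s, s + 9), character(1))
    rho_pos <- vapply(pos, function(s) gain_features(model, s)["rho"],
                      numeric(1))
    rho_neg <- vapply(neg, function(s) gain_features(model, s)["rho"],
                      numeric(1))
    expect_gt(stats::median(rho_pos), stats::median(rho_neg))
  })
})

test_that("QDA separates separated clouds and is indifferent on identical
           ones", {
  withr::with_seed(1, {
    b <- cbind(rho = stats::rnorm(60, 10), eta = stats::rnorm(60, 8))
    g <- cbind(rho = stats::rnorm(60, 0), eta = stats::rnorm(60, 0))
    qda <- fit_qda(b, g)
    expect_true(all(predict(qda, b)$label == "binding"))
    expect_true(all(predict(qda, g)$label == "genomic"))

    x <- cbind(rho = stats::rnorm(300), eta = stats::rnorm(300))
    qda0 <- fit_qda(x[1:150, ], x[151:300, ], priors = c(0.5, 0.5))
    test <- cbind(rho = stats::rnorm(400), eta = stats::rnorm(400))
    sc <- predict(qda0, test)$score
    auc <- roc_auc(c(sc[1:200], sc[201:400]),
                   rep(c("binding", "genomic"), each = 200))$auc
    expect_gt(auc, 0.4); expect_lt(auc, 0.6)
  })
})

test_that("QDA agrees with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(2, {
    b <- cbind(rho = stats::rnorm(50, 4, 1), eta = stats::rnorm(50, 3, 2))
    g <- cbind(rho = stats::rnorm(90, 1, 2), eta = stats::rnorm(90, 1, 1))
  })
  ours <- predict(fit_qda(b, g), rbind(b, g))$label
  ref <- MASS::qda(rbind(b, g),
                   grouping = rep(c("binding", "genomic"), c(50, 90)))
  theirs <- as.character(predict(ref, rbind(b, g))$class)
  expect_gt(mean(ours == theirs), 0.98)
})

test_that("equal class covariances collapse the boundary to a line", {
  withr::with_seed(3, base <- cbind(rho = stats::rnorm(40), eta = stats::rnorm(40)))
  shifted <- sweep(base, 2, c(5, 5), `+`)  # identical covariance by construction
  qda <- fit_qda(shifted, base, priors = c(0.5, 0.5))
  # score along any line must be affine: second differences vanish
  t <- seq(0, 5, length.out = 21)
  line <- cbind(rho = t, eta = 2 * t - 1)
  sc <- predict(qda, line)$score
  expect_lt(max(abs(diff(diff(sc)))), 1e-8)
})

test_that("a tied score is labelled genomic and scores are monotone from
           genomic to binding mean", {
  withr::with_seed(4, b <- cbind(rho = stats::rnorm(50, 3), eta = stats::rnorm(50, 2)))
  g <- -b  # exact mirror: identical covariances, opposite means
  qda <- fit_qda(b, g, priors = c(0.5, 0.5))
  at_origin <- predict(qda, c(rho = 0, eta = 0))
  expect_identical(at_origin$score, 0)
  expect_identical(at_origin$label, "genomic")

  t <- seq(0, 1, length.out = 30)
  seg <- cbind(rho = (1 - t) * qda$means$genomic[1] + t * qda$means$binding[1],
               eta = (1 - t) * qda$means$genomic[2] + t * qda$means$binding[2])
  sc <- predict(qda, seg)$score
  expect_true(all(diff(sc) > 0))
})

test_that("degenerate fits fail loudly without regularization", {
  b <- cbind(rho = rep(1, 5), eta = rep(2, 5))
  g <- cbind(rho = rnorm(5), eta = rnorm(5))
  expect_error(fit_qda(b, g, regularization = 0), "regulari")
  expect_s3_class(fit_qda(b, g, regularization = NULL), "sigma_qda")
  expect_error(fit_qda(b[1:2, ], g), "at least 3")
})

test_that("scanning yields one window per start position and skips
           ambiguous windows", {
  withr::with_seed(31, {
    spec <- motif_spec(L = 10, I = 15, conservation = 0.9, seed = 5)
    model <- sigma_train(sample_motif_set(spec), q = 1,
                         screening = list(seed = 1))
    b <- cbind(rho = stats::rnorm(20, 5), eta = stats::rnorm(20, 5))
    g <- cbind(rho = stats::rnorm(20), eta = stats::rnorm(20))
    qda <- fit_qda(b, g)
  })
  one <- scan_sequence(model, qda, sample_background(10, seed = 1),
                       strand_mode = "forward")
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start, 10)

  seq1500 <- sample_background(1500, seed = 2)
  res <- scan_sequence(model, qda, seq1500, strand_mode = "forward")
  expect_equal(nrow(res), 1491L)
  expect_true(all(res$strand == "+"))

  withN <- paste0(substr(seq1500, 1, 100), "N", substr(seq1500, 102, 200))
  expect_message(resN <- scan_sequence(model, qda, withN, "forward"),
                 "skipping 10 window")
  expect_equal(nrow(resN), 200 - 10 + 1 - 10)
  expect_error(scan_sequence(model, qda, "ACGT"), "shorter")
})

test_that("planted consensus sites rank at the top of a 5 kb scan", {
  spec <- motif_spec(L = 10, I = 20, conservation = 0.95, seed = 11)
  model <- sigma_train(sample_motif_set(spec), q = 1,
                       screening = list(seed = 1))
  bg <- sample_background(5000, seed = 12)
  planted <- plant_motifs(bg, spec, 5, seed = 13, strand = "forward")
  train_bg <- sample_background(20000, seed = 14)
  qda <- sigmotif:::.default_qda(model, train_bg, sigma_config(seed = 2))
  det <- scan_sequence(model, qda, planted$sequence, "both")
  top10 <- det$start[order(-det$score)][1:10]
  expect_true(all(planted$truth$start %in% top10))
})
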