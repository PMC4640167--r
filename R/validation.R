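#' ROC curve and AUC from detector scores
#'
#' Sweeps a threshold over the scores with \code{"binding"} as the
#' positive class. The AUC is computed by the rank (Mann-Whitney) method
#' with midranks for ties, which equals the trapezoidal area under the
#' empirical ROC.
#'
#' @param scores Numeric scores, larger = more binding-like.
#' @param labels Vector the same length as \code{scores}; either the
#'   strings \code{"binding"}/\code{"genomic"} or a logical with
#'   \code{TRUE} = binding.
#' @return Object of class \code{"roc_curve"}: \code{thresholds},
#'   \code{tpr}, \code{fpr} (each starting at 0 and ending at 1) and
#'   \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- if (is.logical(labels)) labels else labels == "binding"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to build a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # one ROC vertex per distinct threshold; curve starts at (0, 0)
  vert <- which(c(diff(s) != 0, TRUE))
  structure(list(thresholds = c(Inf, s[vert]),
                 tpr = c(0, tp[vert]) / n1,
                 fpr = c(0, fp[vert]) / n0,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve over", length(x$thresholds), "thresholds; AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' Mean-dispersion model-selection score for per-fold AUCs
#'
#' \eqn{\nu_{auc} = \mu_{auc} (1 - \sigma_{auc})}: close to 1 only when the
#' cross-validated AUC is both high on average and stable across folds.
#' \eqn{\sigma_{auc}} is the population variance of the fold AUCs by
#' default; the standard deviation can be selected instead.
#'
#' @param aucs Numeric vector of per-fold AUCs (length at least 2).
#' @param dispersion \code{"variance"} (default) or \code{"sd"}; both use
#'   the population (1/n) form.
#' @return A single number in [0, 1] when the AUCs are in [0, 1].
#' @export
nu_auc <- function(aucs, dispersion = c("variance", "sd")) {
  dispersion <- match.arg(dispersion)
  if (length(aucs) < 2L)
    stop("nu_auc needs at least 2 fold AUCs")
  mu <- mean(aucs)
  v <- mean((aucs - mu)^2)
  s <- if (dispersion == "variance") v else sqrt(v)
  mu * (1 - s)
}

#' Leave-one-out cross-validation and Rényi-order selection
#'
#' For every order q on the grid, each aligned site is held out in turn:
#' the model is trained on the remaining I - 1 sites, a quadratic
#' discriminant is fitted on the training sites' gain features against
#' seeded background windows, and the held-out site plus fresh background
#' windows are scored, giving one fold AUC. The grid point maximizing
#' \eqn{\nu_{auc}} over folds is selected; the report also carries the
#' outer mean and standard deviation of the fold AUCs at the chosen q.
#'
#' @param motifs An \code{\link{aligned_motifs}} set with at least 3
#'   sequences.
#' @param background Character string long enough to draw negative
#'   windows from.
#' @param q_grid Rényi orders to evaluate; default a 0.1-step grid over
#'   (0, 2].
#' @param pseudocount,screening,epsilon Model options as in
#'   \code{\link{sigma_train}} / \code{\link{gain_features}}.
#' @param negatives_per_positive Background windows per positive, drawn
#'   once per q and shared across folds.
#' @param regularization Ridge for the fold discriminants (NULL =
#'   automatic).
#' @param dispersion Passed to \code{\link{nu_auc}}.
#' @param seed Master seed for all sampling.
#' @return Object of class \code{"sigma_validation"}: \code{grid} (data
#'   frame with q, mu_auc, sigma_auc, nu_auc), \code{chosen_q},
#'   \code{fold_aucs} at the chosen q, \code{mu_auc}, \code{sigma_auc},
#'   \code{sd_auc}, \code{nu_auc}, plus the configuration used.
#' @export
loo_cv <- function(motifs, background, q_grid = seq(0.1, 2, by = 0.1),
                   pseudocount = 0.5, screening = list(),
                   negatives_per_positive = 10L, regularization = NULL,
                   epsilon = 1e-12, dispersion = c("variance", "sd"),
                   seed = 1L) {
  dispersion <- match.arg(dispersion)
  if (is.character(motifs)) motifs <- aligned_motifs(motifs)
  stopifnot(inherits(motifs, "aligned_motifs"))
  if (motifs$I < 3L)
    stop("leave-one-out needs at least 3 sequences")
  nb <- nchar(background)
  L <- motifs$L
  if (nb < L + 1L) stop("background shorter than the motif")
  npp <- as.integer(negatives_per_positive)

  sc <- utils::modifyList(
    list(method = "permutation", n_permutations = 1000L,
         percentile = 95, seed = seed), screening)

  # negative windows shared across folds (train pool and test pool per q)
  draw_windows <- function(k, s) {
    withr::with_seed(s, {
      starts <- sample.int(nb - L + 1L, k, replace = TRUE)
      vapply(starts, function(st) substr(background, st, st + L - 1L),
             character(1L))
    })
  }

  fold_auc_matrix <- matrix(NA_real_, motifs$I, length(q_grid))
  for (qi in seq_along(q_grid)) {
    q <- q_grid[qi]
    thr <- finite_sample_threshold(motifs$I - 1L, q, method = sc$method,
                                   n_permutations = sc$n_permutations,
                                   percentile = sc$percentile,
                                   seed = sc$seed, pseudocount = pseudocount)
    neg_train <- draw_windows(npp * (motifs$I - 1L), seed * 13L + qi)
    neg_test <- draw_windows(npp, seed * 29L + qi)
    for (f in seq_len(motifs$I)) {
      train_seqs <- motifs$sequences[-f]
      model <- sigma_train(aligned_motifs(train_seqs, motifs$source_id),
                           q = q, pseudocount = pseudocount,
                           threshold = thr)
      pos_pts <- t(vapply(train_seqs, function(s)
        gain_features(model, s, epsilon), numeric(2L)))
      neg_pts <- t(vapply(neg_train, function(s)
        gain_features(model, s, epsilon), numeric(2L)))
      qda <- fit_qda(pos_pts, neg_pts, regularization = regularization)
      test_pts <- rbind(
        gain_features(model, motifs$sequences[f], epsilon),
        t(vapply(neg_test, function(s) gain_features(model, s, epsilon),
                 numeric(2L))))
      sc_test <- predict(qda, test_pts)$score
      lab <- c("binding", rep("genomic", length(neg_test)))
      fold_auc_matrix[f, qi] <- roc_auc(sc_test, lab)$auc
    }
  }
  mu <- colMeans(fold_auc_matrix)
  sig <- apply(fold_auc_matrix, 2L, function(a) mean((a - mean(a))^2))
  if (dispersion == "sd") sig <- sqrt(sig)
  nu <- mu * (1 - sig)
  best <- which.max(nu)
  fold_aucs <- fold_auc_matrix[, best]
  structure(
    list(grid = data.frame(q = q_grid, mu_auc = mu, sigma_auc = sig,
                           nu_auc = nu),
         chosen_q = q_grid[best],
         fold_aucs = fold_aucs,
         mu_auc = mean(fold_aucs),
         sigma_auc = sig[best],
         sd_auc = stats::sd(fold_aucs),
         nu_auc = nu[best],
         dispersion = dispersion,
         config = list(pseudocount = pseudocount, screening = sc,
                       negatives_per_positive = npp, epsilon = epsilon,
                       seed = seed)),
    class = "sigma_validation")
}

#' @export
print.sigma_validation <- function(x, ...) {
  cat("Leave-one-out validation (dispersion = ", x$dispersion, ")\n",
      sep = "")
  cat("  chosen q = ", x$chosen_q, ": nu_auc = ", signif(x$nu_auc, 4),
      " (mean AUC ", signif(x$mu_auc, 4), ", sd ", signif(x$sd_auc, 4),
      ")\n", sep = "")
  invisible(x)
}

#' Detector performance across motif complexity
#'
#' Runs the detector in three configurations on each synthetic spec -
#' entropy-only (classify on rho alone), divergence-only (eta alone) and
#' the full two-feature detector - and tabulates held-out AUC against the
#' trained model's complexity C. This reproduces the regime behaviour the
#' method is built around: per-position information dominates for
#' near-independent motifs (low C), pairwise dependence dominates for
#' strongly coupled motifs (high C), and the combined detector tracks the
#' better of the two.
#'
#' @param specs List of \code{\link{motif_spec}} objects spanning the
#'   coupling range of interest.
#' @param q Rényi order used for all models.
#' @param n_candidates Held-out positives per spec (an equal number of
#'   training positives is drawn; negatives are
#'   \code{negatives_per_positive} times as many).
#' @param negatives_per_positive Background windows per positive.
#' @param background_length Length of the seeded background sequence each
#'   spec's negatives are drawn from.
#' @param pseudocount,epsilon,regularization,screening As elsewhere.
#' @return Data frame with one row per spec: \code{coupling}, \code{C},
#'   \code{auc_entropy}, \code{auc_divergence}, \code{auc_sigma},
#'   \code{n_screened_pairs}.
#' @export
complexity_sweep <- function(specs, q = 1, n_candidates = 100L,
                             negatives_per_positive = 2L,
                             background_length = 20000L,
                             pseudocount = 0.5, epsilon = 1e-12,
                             regularization = NULL, screening = list()) {
  rows <- lapply(specs, function(spec) {
    train_set <- sample_motif_set(spec)
    sc <- utils::modifyList(
      list(method = "permutation", n_permutations = 1000L,
           percentile = 95, seed = spec$seed), screening)
    model <- sigma_train(train_set, q = q, pseudocount = pseudocount,
                         screening = sc)
    L <- spec$L
    n_neg <- n_candidates * negatives_per_positive
    bg <- sample_background(background_length, spec$background,
                            seed = spec$seed + 101L)
    win <- withr::with_seed(spec$seed + 211L, {
      starts <- sample.int(nchar(bg) - L + 1L, 2L * n_neg, replace = TRUE)
      vapply(starts, function(st) substr(bg, st, st + L - 1L), character(1L))
    })
    pos_train <- apply(withr::with_seed(spec$seed + 307L,
      .draw_motif_matrix(spec, n_candidates)), 1L, .decode_seq)
    pos_test <- apply(withr::with_seed(spec$seed + 401L,
      .draw_motif_matrix(spec, n_candidates)), 1L, .decode_seq)
    feats <- function(seqs) t(vapply(seqs, function(s)
      gain_features(model, s, epsilon), numeric(2L)))
    ptr <- feats(pos_train); pte <- feats(pos_test)
    ntr <- feats(win[seq_len(n_neg)]); nte <- feats(win[n_neg + seq_len(n_neg)])
    lab <- c(rep("binding", nrow(pte)), rep("genomic", nrow(nte)))
    auc_for <- function(cols) {
      qda <- fit_qda(ptr[, cols, drop = FALSE], ntr[, cols, drop = FALSE],
                     regularization = regularization)
      sc_te <- predict(qda, rbind(pte, nte)[, cols, drop = FALSE])$score
      roc_auc(sc_te, lab)$auc
    }
    data.frame(coupling = spec$coupling, C = model$complexity,
               auc_entropy = auc_for("rho"),
               auc_divergence = auc_for("eta"),
               auc_sigma = auc_for(c("rho", "eta")),
               n_screened_pairs = nrow(model$pairs))
  })
  do.call(rbind, rows)
}

#' Paired Wilcoxon comparison of two AUC vectors
#'
#' Convenience wrapper for comparing per-motif AUCs of two detector
#' configurations (e.g. full vs entropy-only) with the paired Wilcoxon
#' signed-rank test.
#'
#' @param auc_a,auc_b Paired AUC vectors of equal length.
#' @param ... Passed to \code{stats::wilcox.test}.
#' @return The \code{htest} object.
#' @export
compare_auc_wilcoxon <- function(auc_a, auc_b, ...) {
  stopifnot(length(auc_a) == length(auc_b))
  stats::wilcox.test(auc_a, auc_b, paired = TRUE, ...)
}
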