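#' Per-position redundancy change when a candidate joins the training set
#'
#' For each motif position i, the absolute difference between the training
#' redundancy and the redundancy re-estimated with the candidate appended
#' (training counts plus one): \eqn{\gamma_i = |R_q^{M_i} - R_q^{S_i}|}.
#' A candidate that looks like the training sites barely perturbs the
#' profile (small \eqn{\gamma}); a background sequence erodes conserved
#' positions (large \eqn{\gamma}).
#'
#' @param model A \code{\link{sigma_train}} model.
#' @param candidate Length-L string over A, C, G, T.
#' @param method \code{"lookup"} reads the precomputed appended-symbol
#'   redundancies; \code{"naive"} re-estimates from scratch. Both are exact
#'   and agree to machine precision; naive exists as the reference path.
#' @return Non-negative numeric vector of length L.
#' @export
gamma_profile <- function(model, candidate, method = c("lookup", "naive")) {
  method <- match.arg(method)
  x <- .check_candidate(model, candidate)
  if (method == "lookup") {
    rs <- model$redundancy_lookup[cbind(seq_len(model$motifs$L), x)]
  } else {
    m2 <- aligned_motifs(c(model$motifs$sequences, .decode_seq(x)))
    rs <- redundancy_profile(m2, model$q, model$pseudocount)
  }
  abs(model$redundancy - rs)
}

#' Per-position pairwise-divergence change when a candidate joins the set
#'
#' For each position i, the divergence aggregate \eqn{D_q^{M_i}} is the sum
#' of the divergences of the screened correlated pairs involving i.
#' \eqn{\omega_i = |D_q^{M_i} - D_q^{S_i}|} measures how much that
#' aggregate moves when the candidate is appended. Candidates that respect
#' the motif's position couplings leave it almost unchanged; background
#' sequences dilute the couplings. Positions in no screened pair have
#' \eqn{\omega_i = 0}.
#'
#' @inheritParams gamma_profile
#' @return Non-negative numeric vector of length L.
#' @export
omega_profile <- function(model, candidate, method = c("lookup", "naive")) {
  method <- match.arg(method)
  x <- .check_candidate(model, candidate)
  L <- model$motifs$L
  ds <- numeric(L)
  if (nrow(model$pairs) > 0L) {
    if (method == "lookup") {
      for (k in seq_len(nrow(model$pairs))) {
        i <- model$pairs[k, 1L]; j <- model$pairs[k, 2L]
        v <- model$lookup[[k]][x[i], x[j]]
        ds[i] <- ds[i] + v
        ds[j] <- ds[j] + v
      }
    } else {
      m2 <- aligned_motifs(c(model$motifs$sequences, .decode_seq(x)))
      enc <- .encode_motifs(m2)
      for (k in seq_len(nrow(model$pairs))) {
        i <- model$pairs[k, 1L]; j <- model$pairs[k, 2L]
        v <- renyi_divergence(
          .joint_from_columns(enc[, i], enc[, j], model$pseudocount), model$q)
        ds[i] <- ds[i] + v
        ds[j] <- ds[j] + v
      }
    }
  }
  abs(model$div_rowsum - ds)
}

#' Information-gain features (rho, eta) of a candidate sequence
#'
#' The two coordinates of the information-gain space:
#' \deqn{\rho = |\sum_i R_q^{M_i} \gamma_i|^{-1}, \qquad
#'       \eta = |\sum_i |R_q^{M_i}| \omega_i|^{-1}}
#' Both are inverses of redundancy-weighted information changes, so
#' binding-like candidates (small change) score high and background
#' candidates score low. When an inner sum falls below the floor
#' \code{epsilon} (e.g. a candidate identical to a fully conserved
#' consensus, or a model with no screened pairs) the feature is capped at
#' \code{1/epsilon}.
#'
#' @inheritParams gamma_profile
#' @param epsilon Denominator floor; features are capped at
#'   \code{1/epsilon} (default \code{1e-12}).
#' @return Named numeric vector \code{c(rho = , eta = )}.
#' @export
gain_features <- function(model, candidate, epsilon = 1e-12,
                          method = c("lookup", "naive")) {
  method <- match.arg(method)
  g <- gamma_profile(model, candidate, method)
  w <- omega_profile(model, candidate, method)
  r <- model$redundancy
  c(rho = 1 / max(abs(sum(r * g)), epsilon),
    eta = 1 / max(abs(sum(abs(r) * w)), epsilon))
}

.check_candidate <- function(model, candidate) {
  stopifnot(inherits(model, "sigma_model"))
  if (is.character(candidate)) candidate <- .encode_seq(candidate)
  if (length(candidate) != model$motifs$L)
    stop("candidate length ", length(candidate), " != motif length ",
         model$motifs$L)
  if (anyNA(candidate))
    stop("candidate contains non-ACGT symbols")
  candidate
}

# vectorized (rho, eta) for many windows; sym is an n x L integer matrix
.gain_batch <- function(model, sym, epsilon = 1e-12) {
  n <- nrow(sym)
  L <- model$motifs$L
  red <- model$redundancy
  rs <- matrix(model$redundancy_lookup[cbind(rep(seq_len(L), each = n),
                                             as.vector(sym))], n, L)
  G <- abs(matrix(red, n, L, byrow = TRUE) - rs)
  rho_den <- abs(as.vector(G %*% red))
  DS <- matrix(0, n, L)
  if (nrow(model$pairs) > 0L) {
    for (k in seq_len(nrow(model$pairs))) {
      i <- model$pairs[k, 1L]; j <- model$pairs[k, 2L]
      v <- model$lookup[[k]][cbind(sym[, i], sym[, j])]
      DS[, i] <- DS[, i] + v
      DS[, j] <- DS[, j] + v
    }
  }
  W <- abs(matrix(model$div_rowsum, n, L, byrow = TRUE) - DS)
  eta_den <- abs(as.vector(W %*% abs(red)))
  cbind(rho = 1 / pmax(rho_den, epsilon),
        eta = 1 / pmax(eta_den, epsilon))
}

#' Fit a quadratic discriminant on information-gain points
#'
#' Class-conditional Gaussian model over the (rho, eta) plane (or any
#' feature subset of it): per-class mean, covariance and prior. The
#' decision boundary between the two classes is the quadratic locus where
#' the class log-posteriors tie; it degenerates to a line when the class
#' covariances coincide.
#'
#' @param binding_points,genomic_points Numeric matrices (or data frames)
#'   of gain features, one row per candidate, same columns; at least 3
#'   rows each.
#' @param regularization Non-negative ridge added to each covariance
#'   diagonal. The strict default 0 raises an error on singular
#'   covariances; \code{NULL} picks a small automatic ridge
#'   (\code{1e-8} of the mean feature variance, floored at 1e-12), which
#'   is what the scanning and validation pipelines use.
#' @param priors Length-2 class priors (binding, genomic); default the
#'   empirical class proportions.
#' @return Object of class \code{"sigma_qda"}.
#' @export
fit_qda <- function(binding_points, genomic_points, regularization = 0,
                    priors = NULL) {
  b <- .as_feature_matrix(binding_points)
  g <- .as_feature_matrix(genomic_points)
  if (ncol(b) != ncol(g)) stop("feature dimensions differ between classes")
  if (nrow(b) < 3L || nrow(g) < 3L)
    stop("need at least 3 points per class to estimate covariances")
  if (is.null(priors)) {
    priors <- c(nrow(b), nrow(g)) / (nrow(b) + nrow(g))
  } else {
    stopifnot(length(priors) == 2L, all(priors > 0),
              abs(sum(priors) - 1) < 1e-8)
  }
  covs <- list(binding = stats::cov(b), genomic = stats::cov(g))
  if (is.null(regularization)) {
    regularization <- max(1e-8 * mean(c(diag(covs$binding),
                                        diag(covs$genomic))), 1e-12)
  }
  stopifnot(regularization >= 0)
  d <- ncol(b)
  prep <- lapply(covs, function(S) {
    S <- S + diag(regularization, d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("singular class covariance; refit with a positive ",
           "'regularization' (or regularization = NULL for automatic)")
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
  structure(
    list(features = colnames(b),
         means = list(binding = colMeans(b), genomic = colMeans(g)),
         covariances = list(binding = covs$binding + diag(regularization, d),
                            genomic = covs$genomic + diag(regularization, d)),
         inv = list(binding = prep$binding$inv, genomic = prep$genomic$inv),
         logdet = c(binding = prep$binding$logdet,
                    genomic = prep$genomic$logdet),
         priors = c(binding = priors[1L], genomic = priors[2L]),
         regularization = regularization),
    class = "sigma_qda"
  )
}

.as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- c("rho", "eta")[seq_len(ncol(x))]
  x
}

#' Classify gain points with a fitted quadratic discriminant
#'
#' The score is the binding-minus-genomic log-posterior difference (up to
#' the shared normalizing constant); positive scores are labelled
#' \code{"binding"}, zero or negative scores \code{"genomic"} (exact ties
#' go to the background class, favouring specificity).
#'
#' @param object A fitted \code{\link{fit_qda}} model.
#' @param newdata Matrix/data frame of gain features (same columns as the
#'   fit), or a single named vector.
#' @param ... Unused.
#' @return Data frame with columns \code{score} and \code{label}.
#' @export
predict.sigma_qda <- function(object, newdata, ...) {
  x <- .as_feature_matrix(if (is.null(dim(newdata)) && !is.null(names(newdata)))
    t(newdata) else newdata)
  if (ncol(x) != length(object$means$binding))
    stop("newdata has ", ncol(x), " features; model was fitted on ",
         length(object$means$binding))
  lp <- function(cls) {
    cen <- sweep(x, 2L, object$means[[cls]])
    maha <- rowSums((cen %*% object$inv[[cls]]) * cen)
    log(object$priors[[cls]]) - 0.5 * object$logdet[[cls]] - 0.5 * maha
  }
  score <- lp("binding") - lp("genomic")
  data.frame(score = score,
             label = ifelse(score > 0, "binding", "genomic"),
             row.names = NULL)
}

#' Scan a sequence for motif hits with a trained model and discriminant
#'
#' Slides a window of the motif length over the sequence with step 1,
#' computes each window's information-gain features via the lookup tables,
#' and scores them with the quadratic discriminant. In \code{"both"} mode
#' the reverse complement of every window is scored too and the better
#' strand is reported. Windows containing non-ACGT symbols (e.g. N runs)
#' are skipped and counted in the \code{skipped_windows} attribute.
#'
#' @param model A \code{\link{sigma_train}} model.
#' @param qda A \code{\link{fit_qda}} discriminant fitted on (rho, eta).
#' @param sequence Character string (or \code{Biostrings::DNAString}) of
#'   length at least L.
#' @param strand_mode \code{"both"} (default) or \code{"forward"}.
#' @param sequence_id Name used in the output and BED chrom column.
#' @param epsilon Denominator floor for the gain features.
#' @return Data frame of class \code{"sigma_detections"}: one row per
#'   scored window with \code{sequence_id}, 0-based half-open
#'   \code{start}/\code{end}, \code{strand}, \code{rho}, \code{eta},
#'   \code{score}, \code{label}; rows ordered by (sequence_id, start,
#'   strand). The trained model's \code{source_id} is kept in the
#'   \code{"model_id"} attribute.
#' @export
scan_sequence <- function(model, qda, sequence, strand_mode = c("both", "forward"),
                          sequence_id = "seq", epsilon = 1e-12) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(model, "sigma_model"), inherits(qda, "sigma_qda"))
  sequence <- as.character(sequence)
  x <- .encode_seq(sequence)
  L <- model$motifs$L
  n <- length(x)
  if (n < L) stop("sequence (", n, " nt) shorter than motif length ", L)
  starts <- seq_len(n - L + 1L)
  idx <- outer(starts, 0L:(L - 1L), `+`)
  sym <- matrix(x[idx], nrow = length(starts))
  valid <- !apply(is.na(sym), 1L, any)
  n_skipped <- sum(!valid)
  if (n_skipped > 0L)
    message("skipping ", n_skipped, " window(s) containing non-ACGT symbols")
  starts <- starts[valid]
  sym <- sym[valid, , drop = FALSE]
  if (length(starts) == 0L) {
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      rho = numeric(), eta = numeric(), score = numeric(),
                      label = character())
  } else {
    feat_f <- .gain_batch(model, sym, epsilon)
    pred_f <- predict(qda, feat_f)
    if (strand_mode == "both") {
      rc_sym <- matrix(c(4L, 3L, 2L, 1L)[sym[, L:1L, drop = FALSE]],
                       nrow = nrow(sym))
      feat_r <- .gain_batch(model, rc_sym, epsilon)
      pred_r <- predict(qda, feat_r)
      use_rc <- pred_r$score > pred_f$score
      feat <- feat_f; pred <- pred_f
      feat[use_rc, ] <- feat_r[use_rc, ]
      pred[use_rc, ] <- pred_r[use_rc, ]
      strand <- ifelse(use_rc, "-", "+")
    } else {
      feat <- feat_f; pred <- pred_f
      strand <- rep("+", length(starts))
    }
    out <- data.frame(sequence_id = sequence_id, start = starts - 1L,
                      end = starts - 1L + L, strand = strand,
                      rho = feat[, "rho"], eta = feat[, "eta"],
                      score = pred$score, label = pred$label,
                      stringsAsFactors = FALSE)
    out <- out[order(out$sequence_id, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "model_id") <- model$motifs$source_id
  attr(out, "skipped_windows") <- n_skipped
  class(out) <- c("sigma_detections", "data.frame")
  out
}
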