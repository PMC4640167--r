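#' Per-position nucleotide probabilities of an aligned motif set
#'
#' Column-wise relative frequencies with an optional pseudocount added to
#' every cell: \eqn{p(x) = (n_x + a) / (I + 4a)}. The default pseudocount
#' used in training (0.5, Jeffreys-style) keeps probabilities strictly
#' positive for the small training sets (5-50 sites) this method targets;
#' pass 0 for exact empirical frequencies.
#'
#' @param m An \code{\link{aligned_motifs}} object.
#' @param pseudocount Non-negative real added to each nucleotide count.
#' @return A 4 x L matrix of probabilities, rows A, C, G, T; each column
#'   sums to 1.
#' @export
estimate_position_probs <- function(m, pseudocount = 0.5) {
  stopifnot(inherits(m, "aligned_motifs"), pseudocount >= 0)
  enc <- .encode_motifs(m)
  counts <- apply(enc, 2L, tabulate, nbins = 4L)
  probs <- (counts + pseudocount) / (m$I + 4 * pseudocount)
  rownames(probs) <- NUC
  probs
}

#' Joint nucleotide probabilities for a pair of motif positions
#'
#' Counts the observed (symbol at i, symbol at j) pairs across the aligned
#' set, adds the pseudocount to each of the 16 cells, and normalizes.
#'
#' @inheritParams estimate_position_probs
#' @param i,j Distinct 1-based positions in 1..L.
#' @return A 4 x 4 joint probability matrix (rows = symbol at \code{i},
#'   columns = symbol at \code{j}).
#' @export
estimate_pair_joint <- function(m, i, j, pseudocount = 0.5) {
  stopifnot(inherits(m, "aligned_motifs"))
  if (i == j) stop("positions i and j must differ")
  if (min(i, j) < 1L || max(i, j) > m$L) stop("positions out of range 1..L")
  enc <- .encode_motifs(m)
  .joint_from_columns(enc[, i], enc[, j], pseudocount)
}

.joint_from_columns <- function(xi, xj, pseudocount) {
  counts <- matrix(tabulate((xi - 1L) * 4L + xj, nbins = 16L),
                   nrow = 4L, byrow = TRUE, dimnames = list(NUC, NUC))
  (counts + pseudocount) / (length(xi) + 16 * pseudocount)
}

#' Redundancy profile of an aligned motif set
#'
#' The L-vector of per-position redundancies \eqn{R_q = 1 - H_q/H_{max}}
#' computed from the position probabilities: the information-content
#' footprint of the motif.
#'
#' @inheritParams estimate_position_probs
#' @param q Rényi order.
#' @return Numeric vector of length L with entries in [0, 1].
#' @export
redundancy_profile <- function(m, q, pseudocount = 0.5) {
  probs <- estimate_position_probs(m, pseudocount)
  apply(probs, 2L, renyi_redundancy, q = q)
}

#' Pairwise Rényi divergence matrix of an aligned motif set
#'
#' For every ordered pair of positions, the divergence between the joint
#' symbol distribution and the product of its marginals. The matrix is
#' symmetric by construction and its main diagonal is set to zero.
#'
#' @inheritParams redundancy_profile
#' @return Symmetric L x L matrix in bits with a zero diagonal.
#' @export
divergence_matrix <- function(m, q, pseudocount = 0.5) {
  stopifnot(inherits(m, "aligned_motifs"))
  enc <- .encode_motifs(m)
  L <- m$L
  D <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      d <- renyi_divergence(.joint_from_columns(enc[, i], enc[, j],
                                                pseudocount), q)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Finite-sample screening threshold for pairwise divergence
#'
#' Empirical divergence between two truly independent positions is biased
#' above zero because probabilities are plug-in frequency estimates from
#' only I sequences. Position pairs are only treated as correlated when
#' their divergence exceeds this estimation bias. Two estimators are
#' offered:
#' \describe{
#'   \item{permutation}{draw \code{n_permutations} pairs of independent
#'     columns of length I from \code{marginals}, compute each pair's
#'     divergence with the same pseudocount used in training, and return
#'     the requested percentile of that null distribution (default, exact
#'     for any q).}
#'   \item{analytic_bias}{the Miller-Madow first-order bias of plug-in
#'     mutual information, \eqn{(|X|-1)(|Y|-1) / (2 I \ln 2)} bits; a fast
#'     approximation appropriate for q near 1.}
#' }
#'
#' @param I Training-set size (number of aligned sequences).
#' @param q Rényi order.
#' @param method \code{"permutation"} or \code{"analytic_bias"}.
#' @param n_permutations Number of null column pairs (permutation method).
#' @param percentile Percentile of the null distribution, in (0, 100).
#' @param seed Integer seed making the permutation null reproducible.
#' @param pseudocount Pseudocount matching the one used for the model.
#' @param marginals Length-4 symbol distribution the null columns are drawn
#'   from; the uniform default is the maximum-entropy (conservative) null.
#' @return A list of class \code{"screening_threshold"} with the threshold
#'   \code{value} (bits) and the parameters that produced it.
#' @export
finite_sample_threshold <- function(I, q,
                                    method = c("permutation", "analytic_bias"),
                                    n_permutations = 1000L,
                                    percentile = 95,
                                    seed = 1L,
                                    pseudocount = 0.5,
                                    marginals = rep(0.25, 4)) {
  method <- match.arg(method)
  stopifnot(I >= 2L, percentile > 0, percentile < 100)
  .check_dist(marginals)
  if (method == "permutation") {
    if (n_permutations < 100L)
      warning("fewer than 100 permutations: the percentile estimate is unstable")
    null_div <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(k) {
        xi <- sample.int(4L, I, replace = TRUE, prob = marginals)
        xj <- sample.int(4L, I, replace = TRUE, prob = marginals)
        renyi_divergence(.joint_from_columns(xi, xj, pseudocount), q)
      }, numeric(1L))
    })
    value <- stats::quantile(null_div, probs = percentile / 100,
                             names = FALSE, type = 7)
  } else {
    value <- 9 / (2 * I * log(2))
  }
  structure(list(value = value, method = method,
                 n_permutations = if (method == "permutation") n_permutations else NA_integer_,
                 percentile = if (method == "permutation") percentile else NA_real_,
                 seed = seed, I = I, q = q, pseudocount = pseudocount),
            class = "screening_threshold")
}

#' Select the correlated position pairs of a divergence matrix
#'
#' Returns the unordered pairs (i < j) whose divergence strictly exceeds
#' the finite-sample threshold; only these pairs enter the pairwise part of
#' the detector and its lookup library.
#'
#' @param div L x L divergence matrix in bits.
#' @param threshold A \code{\link{finite_sample_threshold}} result, or a
#'   bare numeric threshold in bits.
#' @return Integer matrix with columns \code{i}, \code{j}, one row per
#'   screened pair (zero rows when nothing passes).
#' @export
screen_correlated_pairs <- function(div, threshold) {
  thr <- if (inherits(threshold, "screening_threshold")) threshold$value else threshold
  stopifnot(is.numeric(thr), length(thr) == 1L, thr >= 0)
  idx <- which(upper.tri(div) & div > thr, arr.ind = TRUE)
  pairs <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Precompute the candidate-appended divergence lookup library
#'
#' For each screened position pair (i, j) the scan must know the pair's
#' divergence after the candidate sequence is appended to the training set
#' (counts I + 1). Only 16 outcomes exist per pair - one per (symbol at i,
#' symbol at j) combination - so they are computed once here and the scan
#' reads them by indexing, turning an O(L^2) recomputation per window into
#' a table lookup over the screened pairs.
#'
#' @inheritParams estimate_position_probs
#' @param pairs Integer matrix of screened pairs (columns \code{i}, \code{j}).
#' @param q Rényi order.
#' @return Named list, one 4 x 4 numeric matrix per pair (name
#'   \code{"i:j"}); entry (x, y) is the pair's divergence in bits when the
#'   appended candidate carries symbol x at i and y at j.
#' @export
build_lookup_library <- function(m, pairs, q, pseudocount = 0.5) {
  stopifnot(inherits(m, "aligned_motifs"))
  enc <- .encode_motifs(m)
  out <- vector("list", nrow(pairs))
  if (nrow(pairs) > 0L)
    names(out) <- paste0(pairs[, 1L], ":", pairs[, 2L])
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    base <- matrix(tabulate((enc[, i] - 1L) * 4L + enc[, j], nbins = 16L),
                   nrow = 4L, byrow = TRUE)
    tab <- matrix(0, 4L, 4L, dimnames = list(NUC, NUC))
    for (x in 1:4) for (y in 1:4) {
      cnt <- base
      cnt[x, y] <- cnt[x, y] + 1L
      joint <- (cnt + pseudocount) / (m$I + 1L + 16 * pseudocount)
      tab[x, y] <- renyi_divergence(joint, q)
    }
    out[[k]] <- tab
  }
  out
}

#' Train a SIGMA motif model
#'
#' Builds the complete trained representation of an aligned binding-site
#' set: position probabilities, the redundancy profile and pairwise
#' divergence matrix at Rényi order \code{q}, the finite-sample screen of
#' correlated position pairs, and the lookup tables that let the scanner
#' re-estimate both quantities with a candidate appended in O(L + pairs)
#' per window.
#'
#' @param motifs An \code{\link{aligned_motifs}} object (or character vector
#'   of equal-length sequences, which is wrapped automatically).
#' @param q Rényi order in (0, 2]; \code{q = 1} uses the Shannon/mutual-
#'   information limit.
#' @param pseudocount Pseudocount per count cell (default 0.5).
#' @param screening List of screening options: \code{method}
#'   ("permutation" or "analytic_bias"), \code{n_permutations},
#'   \code{percentile}, \code{seed}. Partial lists are completed with the
#'   defaults of \code{\link{finite_sample_threshold}}.
#' @param threshold Optional precomputed \code{\link{finite_sample_threshold}}
#'   (or bare numeric, bits) overriding \code{screening}.
#' @return An object of class \code{"sigma_model"}; see Details.
#' @details The model stores, besides the inputs: \code{position_probs}
#'   (4 x L), \code{redundancy} (length L), \code{divergence} (L x L, zero
#'   diagonal), \code{threshold}, \code{pairs} (screened pairs, i < j),
#'   \code{lookup} (per-pair candidate-appended divergences),
#'   \code{redundancy_lookup} (L x 4: per-position redundancy after
#'   appending each possible candidate symbol) and \code{div_rowsum}
#'   (per-position sum of screened divergences). Positions are 1-based
#'   throughout.
#' @examples
#' set.seed(1)
#' m <- aligned_motifs(replicate(10, paste(sample(c("A","C","G","T"), 8,
#'                     TRUE, prob = c(.7,.1,.1,.1)), collapse = "")))
#' mod <- sigma_train(m, q = 1)
#' mod$redundancy
#' @export
sigma_train <- function(motifs, q = 1, pseudocount = 0.5,
                        screening = list(), threshold = NULL) {
  if (is.character(motifs)) motifs <- aligned_motifs(motifs)
  stopifnot(inherits(motifs, "aligned_motifs"))
  .check_order(q)
  stopifnot(pseudocount >= 0)

  enc <- .encode_motifs(motifs)
  probs <- estimate_position_probs(motifs, pseudocount)
  red <- apply(probs, 2L, renyi_redundancy, q = q)
  D <- divergence_matrix(motifs, q, pseudocount)

  if (is.null(threshold)) {
    sc <- utils::modifyList(
      list(method = "permutation", n_permutations = 1000L,
           percentile = 95, seed = 1L), screening)
    threshold <- finite_sample_threshold(
      motifs$I, q, method = sc$method, n_permutations = sc$n_permutations,
      percentile = sc$percentile, seed = sc$seed, pseudocount = pseudocount)
  } else if (is.numeric(threshold)) {
    threshold <- structure(list(value = threshold, method = "fixed"),
                           class = "screening_threshold")
  }
  pairs <- screen_correlated_pairs(D, threshold)
  lookup <- build_lookup_library(motifs, pairs, q, pseudocount)

  # per-position redundancy after appending one candidate symbol (L x 4)
  counts <- apply(enc, 2L, tabulate, nbins = 4L)
  red_lu <- matrix(0, motifs$L, 4L, dimnames = list(NULL, NUC))
  for (i in seq_len(motifs$L)) for (x in 1:4) {
    cnt <- counts[, i]
    cnt[x] <- cnt[x] + 1L
    p <- (cnt + pseudocount) / (motifs$I + 1L + 4 * pseudocount)
    red_lu[i, x] <- renyi_redundancy(p, q)
  }

  div_rowsum <- numeric(motifs$L)
  if (nrow(pairs) > 0L)
    for (k in seq_len(nrow(pairs))) {
      d <- D[pairs[k, 1L], pairs[k, 2L]]
      div_rowsum[pairs[k, 1L]] <- div_rowsum[pairs[k, 1L]] + d
      div_rowsum[pairs[k, 2L]] <- div_rowsum[pairs[k, 2L]] + d
    }

  structure(
    list(motifs = motifs, q = q, pseudocount = pseudocount,
         position_probs = probs, redundancy = red, divergence = D,
         threshold = threshold, pairs = pairs, lookup = lookup,
         redundancy_lookup = red_lu, div_rowsum = div_rowsum,
         complexity = motif_complexity(D)),
    class = "sigma_model"
  )
}

#' @export
print.sigma_model <- function(x, ...) {
  cat("SIGMA motif model '", x$motifs$source_id, "'\n", sep = "")
  cat("  I = ", x$motifs$I, " sites, L = ", x$motifs$L,
      ", q = ", x$q, ", pseudocount = ", x$pseudocount, "\n", sep = "")
  cat("  screened correlated pairs: ", nrow(x$pairs),
      " (threshold ", signif(x$threshold$value, 4), " bits, ",
      x$threshold$method, ")\n", sep = "")
  cat("  complexity C = ", signif(x$complexity, 4), "\n", sep = "")
  invisible(x)
}
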