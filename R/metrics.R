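#' Parametric information measures on nucleotide distributions
#'
#' Rényi entropy of order \code{q} for a probability distribution over the
#' four-letter nucleotide alphabet (A, C, G, T), in bits:
#' \deqn{H_q(p) = \frac{1}{1-q} \log_2 \sum_i p_i^q}
#' The \code{q = 1} case is served by the analytic Shannon limit
#' \eqn{-\sum_i p_i \log_2 p_i}. Zero-probability symbols contribute zero by
#' the usual continuity convention.
#'
#' @param p Numeric vector of 4 probabilities (A, C, G, T order); must be
#'   non-negative and sum to 1.
#' @param q Rényi order, a positive real. Orders in (0, 2] are the useful
#'   range for motif work; larger orders are accepted.
#' @return Entropy in bits, a value in [0, 2].
#' @examples
#' renyi_entropy(rep(0.25, 4), q = 2)   # 2 bits, maximum entropy
#' renyi_entropy(c(1, 0, 0, 0), q = 0.5) # 0 bits, fully conserved
#' @export
renyi_entropy <- function(p, q) {
  .check_dist(p)
  .check_order(q)
  pos <- p[p > 0]
  if (abs(q - 1) < .Machine$double.eps) {
    h <- -sum(pos * log2(pos))
  } else {
    h <- log2(sum(pos^q)) / (1 - q)
  }
  # clamp float dust at the boundaries of [0, log2(4)]
  min(max(h, 0), 2)
}

#' Rényi divergence between a joint nucleotide distribution and the product
#' of its own marginals
#'
#' Measures the statistical dependence between two motif positions:
#' \deqn{D_q(P) = \frac{1}{q-1} \log_2 \sum_{ij} P_{ij}^q Q_{ij}^{1-q}}
#' where \eqn{Q} is the outer product of \eqn{P}'s marginals. At \code{q = 1}
#' this is the mutual information \eqn{\sum P \log_2 (P/Q)}. It is zero if
#' and only if the joint factorizes. Cells with \eqn{P_{ij} = 0} contribute
#' zero; a zero marginal product can only occur where \eqn{P_{ij} = 0} since
#' \eqn{Q} is derived from \eqn{P} itself.
#'
#' @param joint 4x4 matrix of joint probabilities, rows indexing the first
#'   position's symbol, columns the second's; entries non-negative, total 1.
#' @param q Rényi order, positive real.
#' @return Divergence in bits, non-negative.
#' @examples
#' p <- c(0.5, 0.2, 0.2, 0.1)
#' renyi_divergence(outer(p, p), q = 1.5)      # 0: independent positions
#' renyi_divergence(diag(rep(0.25, 4)), q = 2) # 2 bits: perfect coupling
#' @export
renyi_divergence <- function(joint, q) {
  .check_joint(joint)
  .check_order(q)
  px <- rowSums(joint)
  py <- colSums(joint)
  Q <- outer(px, py)
  keep <- joint > 0
  if (abs(q - 1) < .Machine$double.eps) {
    d <- sum(joint[keep] * log2(joint[keep] / Q[keep]))
  } else {
    d <- log2(sum(joint[keep]^q * Q[keep]^(1 - q))) / (q - 1)
  }
  max(d, 0)
}

#' Redundancy (normalized information content) of a motif position
#'
#' Rényi entropy expressed relative to the maximum entropy of the alphabet:
#' \eqn{R_q = 1 - H_q / H_{max}} with \eqn{H_{max} = \log_2 4 = 2} bits.
#' 1 means a fully conserved position, 0 a uniform (uninformative) one.
#'
#' @inheritParams renyi_entropy
#' @param h_max Maximum entropy in bits; 2 for nucleotide data.
#' @return Dimensionless redundancy in [0, 1].
#' @export
renyi_redundancy <- function(p, q, h_max = 2) {
  stopifnot(is.numeric(h_max), length(h_max) == 1L, h_max > 0)
  r <- 1 - renyi_entropy(p, q) / h_max
  min(max(r, 0), 1)
}

#' Complexity of a motif: mean pairwise divergence relative to maximum entropy
#'
#' Averages the off-diagonal entries of a position-by-position divergence
#' matrix and normalizes by the alphabet's maximum entropy:
#' \deqn{C = \frac{\sum_{i \ne j} D_{ij}}{N (N-1) H_{max}}}
#' C lies in [0, 1]; values near 1 indicate strong inter-position
#' correlation, values near 0 an effectively independent (PWM-like) motif.
#'
#' @param div_matrix Square L x L matrix of pairwise divergences in bits,
#'   with a zero main diagonal.
#' @param h_max Maximum entropy in bits (2 for nucleotides).
#' @return Dimensionless complexity in [0, 1].
#' @export
motif_complexity <- function(div_matrix, h_max = 2) {
  if (!is.matrix(div_matrix) || nrow(div_matrix) != ncol(div_matrix))
    stop("'div_matrix' must be a square matrix")
  n <- nrow(div_matrix)
  if (n < 2L)
    stop("complexity needs at least 2 positions")
  off <- div_matrix
  diag(off) <- 0
  sum(off) / (n * (n - 1) * h_max)
}

# ---- input validation helpers -----------------------------------------

.check_dist <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) != 4L)
    stop("distribution must be a numeric vector of length 4 (A, C, G, T)")
  if (any(p < -tol))
    stop("distribution has negative entries")
  if (abs(sum(p) - 1) > tol)
    stop("distribution does not sum to 1 (got ", format(sum(p)), ")")
  invisible(TRUE)
}

.check_joint <- function(joint, tol = 1e-8) {
  if (!is.matrix(joint) || !all(dim(joint) == c(4L, 4L)))
    stop("joint must be a 4x4 numeric matrix")
  if (any(joint < -tol))
    stop("joint has negative entries")
  if (abs(sum(joint) - 1) > tol)
    stop("joint does not sum to 1 (got ", format(sum(joint)), ")")
  invisible(TRUE)
}

.check_order <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("Rényi order 'q' must be a single positive real")
  invisible(TRUE)
}
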