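#' Specify a synthetic motif family
#'
#' Describes a generator for aligned binding-site sets with controllable
#' per-position conservation and pairwise position coupling, the desk-scale
#' stand-in for curated alignment databases. Defaults mirror the data
#' regime the detector targets: short motifs (L around 6-25) trained from
#' small site collections (I around 9-44).
#'
#' @param L Motif length (positions), at least 2.
#' @param I Number of training sites to draw.
#' @param conservation Probability of the consensus symbol at each
#'   position; scalar or length-L vector, each entry in (0.25, 1]. 0.25
#'   would be indistinguishable from uniform background, hence excluded.
#' @param coupled_pairs List of integer pairs \code{c(i, j)} (1-based,
#'   i < j, pairwise disjoint) whose symbols co-vary.
#' @param coupling Probability in [0, 1] that a coupled pair's second
#'   symbol is copied from the first (identity partner map) instead of
#'   being drawn independently; 0 gives an independent (PWM-like) motif,
#'   1 a deterministic diagonal joint. Trained-model complexity C grows
#'   monotonically with it.
#' @param background Length-4 symbol composition used for background
#'   sequence, or a 4x4 row-stochastic matrix for an order-1 Markov
#'   background.
#' @param consensus Optional consensus as a length-L string or vector of
#'   symbols; drawn uniformly at random (seeded) when omitted.
#' @param seed Integer seed; all sampling from this spec is reproducible.
#' @return Object of class \code{"motif_spec"}.
#' @export
motif_spec <- function(L, I, conservation = 0.85, coupled_pairs = list(),
                       coupling = 0, background = rep(0.25, 4),
                       consensus = NULL, seed = 1L) {
  stopifnot(L >= 2L, I >= 2L, coupling >= 0, coupling <= 1)
  conservation <- rep_len(conservation, L)
  if (any(conservation <= 0.25) || any(conservation > 1))
    stop("conservation must lie in (0.25, 1]: at or below 0.25 the ",
         "position is background")
  if (length(coupled_pairs) > 0L) {
    cp <- do.call(rbind, lapply(coupled_pairs, function(p) {
      stopifnot(length(p) == 2L)
      sort(as.integer(p))
    }))
    if (any(cp < 1L) || any(cp > L) || any(cp[, 1L] == cp[, 2L]) ||
        anyDuplicated(as.vector(cp)) > 0L)
      stop("coupled_pairs must be disjoint pairs of distinct positions in 1..L")
  } else {
    cp <- matrix(integer(), 0L, 2L)
  }
  colnames(cp) <- c("i", "j")
  if (is.null(consensus)) {
    consensus <- withr::with_seed(seed, sample.int(4L, L, replace = TRUE))
  } else {
    if (is.character(consensus) && length(consensus) == 1L)
      consensus <- strsplit(toupper(consensus), "")[[1L]]
    consensus <- if (is.character(consensus)) match(consensus, NUC)
                 else as.integer(consensus)
    if (length(consensus) != L || anyNA(consensus))
      stop("consensus must be L valid nucleotides")
  }
  structure(list(L = L, I = I, conservation = conservation,
                 coupled_pairs = cp, coupling = coupling,
                 background = background, consensus = consensus,
                 seed = as.integer(seed)),
            class = "motif_spec")
}

# draw n sequences (integer n x L matrix) from a spec, under the current RNG
.draw_motif_matrix <- function(spec, n) {
  L <- spec$L
  out <- matrix(0L, n, L)
  for (i in seq_len(L)) {
    cons <- spec$consensus[i]
    p <- rep((1 - spec$conservation[i]) / 3, 4L)
    p[cons] <- spec$conservation[i]
    out[, i] <- sample.int(4L, n, replace = TRUE, prob = p)
  }
  if (nrow(spec$coupled_pairs) > 0L && spec$coupling > 0) {
    for (k in seq_len(nrow(spec$coupled_pairs))) {
      i <- spec$coupled_pairs[k, 1L]; j <- spec$coupled_pairs[k, 2L]
      copy <- stats::runif(n) < spec$coupling
      out[copy, j] <- out[copy, i]
    }
  }
  out
}

#' Sample an aligned motif set from a synthetic spec
#'
#' Each sequence is drawn position-wise from the conservation profile
#' (consensus symbol with the stated probability, the other three symbols
#' equally likely otherwise); then, for every coupled pair, the second
#' position is overwritten with a copy of the first with probability
#' \code{coupling}. Identical seeds give identical sets.
#'
#' @param spec A \code{\link{motif_spec}}.
#' @param n Number of sequences (defaults to \code{spec$I}).
#' @param seed Seed (defaults to \code{spec$seed}).
#' @return An \code{\link{aligned_motifs}} object.
#' @export
sample_motif_set <- function(spec, n = spec$I, seed = spec$seed) {
  stopifnot(inherits(spec, "motif_spec"))
  mat <- withr::with_seed(seed, .draw_motif_matrix(spec, n))
  aligned_motifs(apply(mat, 1L, .decode_seq), source_id = "synthetic")
}

#' Sample a background DNA sequence
#'
#' Either i.i.d. from a length-4 composition, or an order-1 Markov chain
#' when \code{composition} is a 4x4 row-stochastic transition matrix (the
#' first symbol is drawn from the matrix's stationary distribution).
#'
#' @param length Sequence length in nucleotides.
#' @param composition Length-4 probability vector (A, C, G, T) or 4x4
#'   transition matrix with rows summing to 1.
#' @param seed Integer seed.
#' @return A character string of the requested length.
#' @export
sample_background <- function(length, composition = rep(0.25, 4), seed = 1L) {
  stopifnot(length >= 1L)
  x <- withr::with_seed(seed, {
    if (is.matrix(composition)) {
      if (!all(dim(composition) == c(4L, 4L)) || any(composition < 0) ||
          any(abs(rowSums(composition) - 1) > 1e-8))
        stop("Markov composition must be a 4x4 row-stochastic matrix")
      ev <- eigen(t(composition))
      stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
      stat <- pmax(stat / sum(stat), 0)
      stat <- stat / sum(stat)
      out <- integer(length)
      out[1L] <- sample.int(4L, 1L, prob = stat)
      for (t in seq_len(length - 1L))
        out[t + 1L] <- sample.int(4L, 1L, prob = composition[out[t], ])
      out
    } else {
      .check_dist(composition)
      sample.int(4L, length, replace = TRUE, prob = composition)
    }
  })
  .decode_seq(x)
}

#' Plant motif instances into a background sequence
#'
#' Substitutes \code{n_instances} motif realizations at seeded,
#' non-overlapping positions of the background and returns the modified
#' sequence with a ground-truth table. In \code{"both"} strand mode each
#' instance is reverse-complemented with probability 1/2 before insertion.
#'
#' @param background Character string to plant into.
#' @param motifs A \code{\link{motif_spec}} (instances are freshly drawn)
#'   or an \code{\link{aligned_motifs}} set (instances are resampled from
#'   its sequences).
#' @param n_instances Number of instances to plant.
#' @param seed Integer seed.
#' @param strand \code{"forward"} or \code{"both"}.
#' @param sequence_id Name recorded in the truth table.
#' @return List with \code{sequence} (modified string) and \code{truth}, a
#'   data frame of 0-based half-open intervals (\code{sequence_id},
#'   \code{start}, \code{end}, \code{strand}) sorted by start.
#' @export
plant_motifs <- function(background, motifs, n_instances, seed = 1L,
                         strand = c("forward", "both"),
                         sequence_id = "synthetic_seq") {
  strand <- match.arg(strand)
  n <- nchar(background)
  L <- if (inherits(motifs, "motif_spec")) motifs$L else motifs$L
  if (n_instances == 0L)
    return(list(sequence = background,
                truth = data.frame(sequence_id = character(),
                                   start = integer(), end = integer(),
                                   strand = character())))
  if (n_instances * L > n)
    stop("background too short to hold ", n_instances,
         " non-overlapping instances of length ", L)
  res <- withr::with_seed(seed, {
    inst <- if (inherits(motifs, "motif_spec")) {
      .draw_motif_matrix(motifs, n_instances)
    } else {
      picks <- sample.int(motifs$I, n_instances, replace = TRUE)
      t(vapply(picks, function(p) .encode_seq(motifs$sequences[p]),
               integer(L)))
    }
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_instances) {
      cand <- sample.int(n - L + 1L, 1L)
      if (all(abs(cand - starts) >= L)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_instances)
        stop("could not place ", n_instances,
             " non-overlapping instances; background too crowded")
    }
    strands <- if (strand == "both") {
      ifelse(stats::runif(n_instances) < 0.5, "-", "+")
    } else rep("+", n_instances)
    list(inst = inst, starts = starts, strands = strands)
  })
  x <- .encode_seq(background)
  for (k in seq_len(n_instances)) {
    ins <- res$inst[k, ]
    if (res$strands[k] == "-") ins <- .revcomp_idx(ins)
    x[res$starts[k]:(res$starts[k] + L - 1L)] <- ins
  }
  ord <- order(res$starts)
  list(sequence = .decode_seq(x),
       truth = data.frame(sequence_id = sequence_id,
                          start = res$starts[ord] - 1L,
                          end = res$starts[ord] - 1L + L,
                          strand = res$strands[ord],
                          stringsAsFactors = FALSE))
}
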