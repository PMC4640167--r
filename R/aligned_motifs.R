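NUC <- c("A", "C", "G", "T")

#' Construct a set of aligned binding-site sequences
#'
#' The training input of the detector: I aligned sequences of a common
#' length L over the strict alphabet {A, C, G, T}. Sequences are uppercased
#' on entry; anything else (ambiguity codes, gaps, ragged lengths) is an
#' error, because downstream probability estimates assume a rectangular
#' ACGT matrix.
#'
#' @param sequences Character vector of I sequences, all of equal length L.
#' @param source_id Free-text label for the set (e.g. a transcription-factor
#'   name); carried through to reports and BED output.
#' @return An object of class \code{"aligned_motifs"} with elements
#'   \code{sequences}, \code{I}, \code{L} and \code{source_id}.
#' @examples
#' m <- aligned_motifs(c("ACGT", "ACGA", "ACGT"), source_id = "toy")
#' m$I; m$L
#' @export
aligned_motifs <- function(sequences, source_id = "motif") {
  if (!is.character(sequences) || length(sequences) < 2L)
    stop("need a character vector of at least 2 aligned sequences")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])
    stop("aligned sequences must share one length; records ",
         paste(bad, collapse = ", "), " differ from record 1 (",
         lens[1L], " nt)")
  }
  if (lens[1L] < 2L)
    stop("motif length must be at least 2")
  bad_chr <- grepl("[^ACGT]", sequences)
  if (any(bad_chr))
    stop("non-ACGT symbols in records ",
         paste(which(bad_chr), collapse = ", "))
  structure(
    list(sequences = sequences, I = length(sequences), L = lens[1L],
         source_id = as.character(source_id)[1L]),
    class = "aligned_motifs"
  )
}

#' @export
print.aligned_motifs <- function(x, ...) {
  cat("Aligned motif set '", x$source_id, "': ", x$I, " sequences x ",
      x$L, " positions\n", sep = "")
  invisible(x)
}

# integer encoding A=1 C=2 G=3 T=4; I x L matrix
.encode_motifs <- function(m) {
  enc <- vapply(strsplit(m$sequences, "", fixed = TRUE),
                function(s) match(s, NUC), integer(m$L))
  matrix(t(enc), nrow = m$I, ncol = m$L)
}

.encode_seq <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], NUC)
}

.decode_seq <- function(idx) paste(NUC[idx], collapse = "")

# reverse complement on the integer encoding (A<->T, C<->G)
.revcomp_idx <- function(idx) rev(c(4L, 3L, 2L, 1L)[idx])
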