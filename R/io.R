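#' Read an aligned binding-site set from disk
#'
#' Three layouts are accepted: FASTA (all records the same length), plain
#' text with one sequence per line (blank lines ignored), and JASPAR
#' "sites"-style FASTA in which the aligned core is uppercase and flanking
#' genomic context is lowercase - only the uppercase core is kept.
#' Soft-masked lowercase letters in plain FASTA are uppercased (with a
#' message); ragged lengths or residual non-ACGT symbols are errors naming
#' the offending records.
#'
#' @param path File path.
#' @param format One of \code{"auto"}, \code{"fasta"}, \code{"lines"},
#'   \code{"jaspar_sites"}. \code{"auto"} decides from the extension
#'   (\code{.sites} = JASPAR, \code{.fa/.fasta/.fna} = FASTA) or, failing
#'   that, from a leading \code{">"}.
#' @param source_id Label for the set; defaults to the file name without
#'   extension.
#' @return An \code{\link{aligned_motifs}} object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "lines",
                                            "jaspar_sites"),
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- if (ext == "sites") "jaspar_sites"
              else if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta"
              else {
                first <- readLines(path, n = 1L)
                if (length(first) && startsWith(first, ">")) "fasta" else "lines"
              }
  }
  seqs <- switch(format,
    fasta = {
      x <- as.character(Biostrings::readBStringSet(path))
      n_soft <- sum(vapply(gregexpr("[acgt]", x),
                           function(g) sum(g > 0), numeric(1L)))
      if (n_soft > 0)
        message("uppercased ", n_soft, " soft-masked (lowercase) letters")
      unname(x)
    },
    jaspar_sites = {
      x <- as.character(Biostrings::readBStringSet(path))
      core <- gsub("[^A-Z]", "", x)
      empty <- nchar(core) == 0L
      if (any(empty))
        stop("no uppercase aligned core in records ",
             paste(which(empty), collapse = ", "))
      unname(core)
    },
    lines = {
      x <- trimws(readLines(path))
      x[nzchar(x)]
    })
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  aligned_motifs(seqs, source_id = source_id)
}

#' Write detections to BED6 or TSV
#'
#' BED6 uses the 0-based half-open coordinates the scan already carries,
#' with the model id in the name column and the QDA score rescaled
#' linearly to integers in [0, 1000] over the written set (a constant
#' score maps to 0). TSV keeps rho, eta and the raw score at full
#' precision (17 significant digits, so values round-trip exactly through
#' \code{\link{read_detections}}). Rows are written in (sequence, start,
#' strand) order in both formats.
#'
#' @param results A \code{\link{scan_sequence}} result (or compatible data
#'   frame).
#' @param path Output file path.
#' @param format \code{"bed6"} or \code{"tsv"}.
#' @param name BED name column; defaults to the \code{model_id} attribute
#'   of \code{results}, or \code{"sigma"}.
#' @return Invisibly, the path.
#' @export
write_detections <- function(results, path, format = c("bed6", "tsv"),
                             name = NULL) {
  format <- match.arg(format)
  req <- c("sequence_id", "start", "end", "strand", "rho", "eta",
           "score", "label")
  if (!all(req %in% names(results)))
    stop("results must have columns: ", paste(req, collapse = ", "))
  if (is.null(name))
    name <- attr(results, "model_id") %||% "sigma"
  o <- order(results$sequence_id, results$start, results$strand)
  results <- results[o, , drop = FALSE]
  if (format == "bed6") {
    if (nrow(results) == 0L) {
      bed_score <- integer(0)
    } else {
      rng <- range(results$score)
      bed_score <- if (diff(rng) == 0) rep(0L, nrow(results))
                   else as.integer(round(1000 * (results$score - rng[1L]) /
                                           diff(rng)))
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     results$sequence_id, results$start, results$end,
                     name, bed_score, results$strand)
  } else {
    header <- paste(req, collapse = "\t")
    lines <- c(header,
               sprintf("%s\t%d\t%d\t%s\t%.17g\t%.17g\t%.17g\t%s",
                       results$sequence_id, results$start, results$end,
                       results$strand, results$rho, results$eta,
                       results$score, results$label))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a detections TSV written by \code{\link{write_detections}}
#'
#' @param path TSV path.
#' @return Data frame with the scan columns (numeric values recovered
#'   exactly).
#' @export
read_detections <- function(path) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "numeric",
                                          "numeric", "character"))
  out
}

#' Serialize a trained model to a self-describing JSON file
#'
#' Stores the training sequences, all estimated quantities and the
#' screening record with full numeric precision, so
#' \code{\link{read_sigma_model}} reconstructs a model whose every field
#' is identical to the original.
#'
#' @param model A \code{\link{sigma_train}} model.
#' @param path Output path (conventionally \code{.json}).
#' @return Invisibly, the path.
#' @export
write_sigma_model <- function(model, path) {
  stopifnot(inherits(model, "sigma_model"))
  payload <- list(
    format = "sigma_model",
    version = 1L,
    source_id = model$motifs$source_id,
    sequences = model$motifs$sequences,
    q = model$q,
    pseudocount = model$pseudocount,
    threshold = unclass(model$threshold),
    pairs = model$pairs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a serialized model back
#'
#' Re-trains deterministically from the stored sequences, order and
#' pseudocount, reusing the stored screening threshold, so the
#' reconstruction is exact (training is a pure function of those inputs).
#'
#' @param path Path written by \code{\link{write_sigma_model}}.
#' @return A \code{\link{sigma_train}} model.
#' @export
read_sigma_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sigma_model"))
    stop("not a sigma model file: ", path)
  thr <- structure(p$threshold, class = "screening_threshold")
  sigma_train(aligned_motifs(p$sequences, p$source_id),
              q = p$q, pseudocount = p$pseudocount, threshold = thr)
}

#' Write a ground-truth table (or any interval set) as BED
#'
#' @param truth Data frame with \code{sequence_id}, 0-based \code{start},
#'   \code{end}, \code{strand}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", truth$sequence_id,
                   truth$start, truth$end, "planted", 0L, truth$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Reads the first six BED columns (fewer are tolerated); coordinates stay
#' 0-based half-open.
#'
#' @param path BED path.
#' @return Data frame with \code{sequence_id}, \code{start}, \code{end}
#'   and, when present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 3L)
    stop("not a BED file (need at least 3 columns): ", path)
  names(raw)[1:3] <- c("sequence_id", "start", "end")
  if (ncol(raw) >= 4L) names(raw)[4L] <- "name"
  if (ncol(raw) >= 5L) names(raw)[5L] <- "score"
  if (ncol(raw) >= 6L) names(raw)[6L] <- "strand"
  raw
}

#' Validated run configuration
#'
#' Gathers the knobs shared by the train/scan/validate entry points,
#' validates their ranges, and gives them one serializable home; every
#' pipeline output is accompanied by a JSON echo of the configuration that
#' produced it.
#'
#' @param q Rényi order (ignored when \code{q_grid} is given).
#' @param q_grid Optional grid of orders in (0, 2] for validation.
#' @param pseudocount Non-negative pseudocount.
#' @param screening_method \code{"permutation"} or \code{"analytic_bias"}.
#' @param n_permutations,percentile Permutation-null options.
#' @param epsilon Gain-feature denominator floor.
#' @param strand \code{"both"} or \code{"forward"}.
#' @param negatives_per_positive Background windows per positive.
#' @param regularization QDA ridge; NULL = automatic.
#' @param seed Master seed.
#' @return List of class \code{"sigma_config"}.
#' @export
sigma_config <- function(q = 1, q_grid = NULL, pseudocount = 0.5,
                         screening_method = c("permutation", "analytic_bias"),
                         n_permutations = 1000L, percentile = 95,
                         epsilon = 1e-12, strand = c("both", "forward"),
                         negatives_per_positive = 10L,
                         regularization = NULL, seed = 1L) {
  screening_method <- match.arg(screening_method)
  strand <- match.arg(strand)
  .check_order(q)
  if (!is.null(q_grid)) {
    stopifnot(all(q_grid > 0), all(q_grid <= 2))
  }
  stopifnot(pseudocount >= 0, n_permutations >= 1L,
            percentile > 0, percentile < 100, epsilon > 0,
            negatives_per_positive >= 1L)
  structure(list(q = q, q_grid = q_grid, pseudocount = pseudocount,
                 screening_method = screening_method,
                 n_permutations = as.integer(n_permutations),
                 percentile = percentile, epsilon = epsilon,
                 strand = strand,
                 negatives_per_positive = as.integer(negatives_per_positive),
                 regularization = regularization,
                 seed = as.integer(seed)),
            class = "sigma_config")
}

.write_config_echo <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
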