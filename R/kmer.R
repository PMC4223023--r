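# k-mer profile and Manhattan distance between sequences. Long sequences are
# summarized by the counts of their overlapping k-mers (k = 6 by default);
# the distance between two sequences is the sum over all k-mers of the
# absolute count difference. The distance works on raw occurrence counts, so
# sequences of very different lengths score large distances by design; an
# optional post-hoc normalization by the number of counted windows is
# available where a length-free score is wanted.

#' Overlapping k-mer counts of a nucleotide sequence
#'
#' Counts every overlapping window of length \code{k}, case-insensitively.
#' Windows containing a non-ACGT symbol are skipped; their number is recorded
#' in the \code{n_dropped} field.
#'
#' @param sequence A character scalar or \code{Biostrings::DNAString}.
#' @param k Word length, an integer in 1..12 (default 6).
#' @return Object of class \code{kmer_profile}: list with \code{k},
#'   \code{counts} (named integer vector of the k-mers that occur),
#'   \code{n_windows} (number of counted windows) and \code{n_dropped}.
#' @export
kmer_profile <- function(sequence, k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    stop("kmer_profile: k must be a positive integer", call. = FALSE)
  if (k > 12L)
    stop("kmer_profile: k > 12 is not supported", call. = FALSE)
  if (inherits(sequence, "DNAString"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- chartr("acgtu", "ACGTT", sequence)
  seq_up <- gsub("[^ACGT]", "N", seq_up)
  n <- nchar(seq_up)
  total_windows <- max(0L, n - k + 1L)
  if (total_windows == 0L) {
    out <- list(k = k, counts = stats::setNames(integer(0), character(0)),
                n_windows = 0L, n_dropped = 0L)
    class(out) <- "kmer_profile"
    return(out)
  }
  freq <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq_up),
                                               width = k)
  freq <- freq[freq > 0L]
  counted <- sum(freq)
  out <- list(k = k, counts = freq, n_windows = as.integer(counted),
              n_dropped = as.integer(total_windows - counted))
  class(out) <- "kmer_profile"
  out
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("k-mer profile: k = %d, %d distinct %d-mers over %d windows",
              x$k, length(x$counts), x$k, x$n_windows))
  if (x$n_dropped) cat(sprintf(" (%d ambiguous windows dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Manhattan distance between two k-mer profiles
#'
#' Sum over the union of occurring k-mers of the absolute count difference.
#' A metric on profiles: nonnegative, zero iff the profiles are equal,
#' symmetric, and satisfying the triangle inequality.
#'
#' @param p,q \code{kmer_profile} objects with equal \code{k}.
#' @return Nonnegative numeric distance (an integer value).
#' @export
kmer_manhattan_distance <- function(p, q) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  if (p$k != q$k)
    stop("kmer_manhattan_distance: profiles have different k (",
         p$k, " vs ", q$k, ")", call. = FALSE)
  words <- union(names(p$counts), names(q$counts))
  cp <- rep(0L, length(words)); cq <- cp
  cp[match(names(p$counts), words)] <- p$counts
  cq[match(names(q$counts), words)] <- q$counts
  sum(abs(as.numeric(cp) - as.numeric(cq)))
}

#' Pairwise k-mer distances between FASTA records
#'
#' Reads a multi-record FASTA, builds one k-mer profile per record and
#' returns the Manhattan distance for each requested id pair (default: all
#' unordered pairs).
#'
#' @param fasta Path to a FASTA file or a named character vector /
#'   \code{DNAStringSet} of sequences.
#' @param pairs Optional two-column data.frame or matrix of record ids; by
#'   default all unordered record pairs are compared.
#' @param k Word length (default 6).
#' @param normalize If \code{TRUE}, divide each distance by the total number
#'   of counted windows in the two sequences (a length-adjusted score, off by
#'   default).
#' @return Data.frame \code{id_a}, \code{id_b}, \code{distance}.
#' @export
sequence_distances <- function(fasta, pairs = NULL, k = 6L,
                               normalize = FALSE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    Biostrings::readDNAStringSet(fasta)
  else fasta
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm))
    stop("sequence_distances: records must have unique ids", call. = FALSE)
  profs <- lapply(seq_along(seqs), function(i)
    kmer_profile(as.character(seqs[[i]]), k = k))
  names(profs) <- nm
  if (is.null(pairs)) {
    if (length(nm) < 2L)
      stop("sequence_distances: need at least two records", call. = FALSE)
    cmb <- utils::combn(nm, 2L)
    pairs <- data.frame(id_a = cmb[1L, ], id_b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("id_a", "id_b")
    unk <- setdiff(c(pairs$id_a, pairs$id_b), nm)
    if (length(unk))
      stop("sequence_distances: unknown record id(s): ",
           paste(utils::head(unk, 5L), collapse = ", "), call. = FALSE)
  }
  d <- mapply(function(a, b) {
    dd <- kmer_manhattan_distance(profs[[a]], profs[[b]])
    if (normalize) {
      tot <- profs[[a]]$n_windows + profs[[b]]$n_windows
      if (tot > 0) dd <- dd / tot
    }
    dd
  }, pairs$id_a, pairs$id_b)
  data.frame(id_a = pairs$id_a, id_b = pairs$id_b, distance = as.numeric(d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname sequence_distances
#' @param distances Data.frame from \code{sequence_distances}.
#' @param path Output path.
#' @param config Optional named list echoed as '#' provenance comments.
#' @export
write_sequence_distances <- function(distances, path, config = NULL) {
  .write_table_with_header(distances, path, config)
}
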