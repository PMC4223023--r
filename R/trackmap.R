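# Per-gene aggregation of positional feature tracks and Z-score comparison
# between the two species over syntenic one-to-one ortholog pairs.

#' Per-gene feature values from a BED track
#'
#' Unweighted track: the fraction of the gene's base pairs covered by the
#' union of the track elements (in [0, 1]). Weighted track: the
#' overlap-length-weighted sum of element weights divided by the full gene
#' length, so bases without signal contribute 0 and a weight of 1 everywhere
#' reduces to the unweighted case. Overlapping weighted elements sum.
#'
#' @param genes Gene table (1-based inclusive coordinates).
#' @param track Feature track from \code{\link{read_bed}} (0-based
#'   half-open), attribute \code{has_weights} selects the mode.
#' @return Numeric vector of per-gene values, in the order of \code{genes}.
#' @export
gene_feature_values <- function(genes, track) {
  len <- genes$end - genes$start + 1L
  if (any(len <= 0L))
    stop("gene_feature_values: gene of non-positive length", call. = FALSE)
  weighted <- isTRUE(attr(track, "has_weights"))
  vals <- numeric(nrow(genes))
  if (!nrow(track)) return(vals)
  for (ch in unique(genes$chromosome)) {
    gi <- which(genes$chromosome == ch)
    ti <- which(track$chromosome == ch)
    if (!length(ti)) next
    gr <- IRanges::IRanges(start = genes$start[gi], end = genes$end[gi])
    # BED half-open [start, end) -> 1-based inclusive [start+1, end]
    tr <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    if (weighted) {
      hits <- IRanges::findOverlaps(gr, tr)
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        ov <- IRanges::width(IRanges::pintersect(gr[qh], tr[sh]))
        contrib <- ov * track$weight[ti][sh]
        acc <- tapply(contrib, qh, sum)
        vals[gi[as.integer(names(acc))]] <- as.numeric(acc)
      }
    } else {
      trr <- IRanges::reduce(tr)
      hits <- IRanges::findOverlaps(gr, trr)
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        ov <- IRanges::width(IRanges::pintersect(gr[qh], trr[sh]))
        acc <- tapply(ov, qh, sum)
        vals[gi[as.integer(names(acc))]] <- as.numeric(acc)
      }
    }
  }
  vals / len
}

#' Z-score normalization (population SD)
#'
#' Subtracts the mean and divides by the population standard deviation
#' (denominator n). A constant vector yields all zeros with a warning.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of Z-scores (mean 0, population SD 1 when the input
#'   is not constant).
#' @export
zscore_normalize <- function(values) {
  if (length(values) < 2L)
    stop("zscore_normalize: need at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    warning("zscore_normalize: constant input, returning zeros",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - m) / s
}

#' Compare two feature tracks over syntenic ortholog pairs
#'
#' Aggregates each track to per-gene values (\code{\link{gene_feature_values}}),
#' Z-scores each species' vector, and reports the per-pair absolute Z-score
#' difference d_i = |z_A,i - z_B,i| together with its mean, the compact
#' similarity measure between the two tracks. The per-pair table is sorted
#' ascending by difference so the most conserved orthologs come first.
#'
#' @param pairs Data.frame with columns \code{gene_a}, \code{gene_b} (e.g.
#'   the \code{$pairs} of a \code{\link{synteny_map}}).
#' @param genes_a,genes_b Gene tables.
#' @param track_a,track_b Feature tracks for the two species.
#' @return Object of class \code{track_comparison}: list with \code{table}
#'   (gene_a, gene_b, value_a, value_b, z_a, z_b, difference) and
#'   \code{mean_difference}.
#' @export
compare_tracks <- function(pairs, genes_a, genes_b, track_a, track_b) {
  if (inherits(pairs, "synteny_map")) pairs <- pairs$pairs
  ia <- match(pairs$gene_a, genes_a$gene_id)
  ib <- match(pairs$gene_b, genes_b$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("compare_tracks: pair member(s) missing from gene tables",
         call. = FALSE)
  va <- gene_feature_values(genes_a[ia, , drop = FALSE], track_a)
  vb <- gene_feature_values(genes_b[ib, , drop = FALSE], track_b)
  za <- zscore_normalize(va)
  zb <- zscore_normalize(vb)
  difference_scores(za, zb,
                    table_extra = data.frame(gene_a = pairs$gene_a,
                                             gene_b = pairs$gene_b,
                                             value_a = va, value_b = vb,
                                             stringsAsFactors = FALSE))
}

#' Per-pair Z-score differences and their mean
#'
#' @param z_a,z_b Pair-aligned Z-score vectors of equal length.
#' @param table_extra Optional data.frame of per-pair annotation columns
#'   (same length) carried into the output table.
#' @return A \code{track_comparison} (see \code{\link{compare_tracks}}).
#' @export
difference_scores <- function(z_a, z_b, table_extra = NULL) {
  if (length(z_a) != length(z_b))
    stop("difference_scores: Z-score vectors differ in length", call. = FALSE)
  d <- abs(z_a - z_b)
  tab <- data.frame(z_a = z_a, z_b = z_b, difference = d)
  if (!is.null(table_extra)) tab <- cbind(table_extra, tab)
  tab <- tab[order(tab$difference), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab, mean_difference = mean(d), n = length(d))
  class(out) <- "track_comparison"
  out
}

#' @export
print.track_comparison <- function(x, ...) {
  cat("Track comparison over", x$n, "ortholog pairs\n")
  cat(sprintf("  mean |z_A - z_B| difference: %.4f\n", x$mean_difference))
  invisible(x)
}

#' @export
summary.track_comparison <- function(object, ...) {
  print(object)
  cat("  most conserved pairs (lowest difference):\n")
  print(utils::head(object$table, 5L))
  invisible(object)
}

#' Randomize a feature track
#'
#' Per chromosome, keeps the element count and the multiset of element
#' lengths but draws each start uniformly from the valid positions
#' (overlaps permitted). Weighted tracks keep their weights attached to the
#' (length-preserved) elements. Uses the current RNG state; call
#' \code{set.seed} for reproducibility.
#'
#' @param track Feature track (0-based half-open).
#' @param chrom_sizes Named vector of chromosome lengths covering every
#'   chromosome present in the track.
#' @return A randomized feature track of the same dialect.
#' @export
randomize_track <- function(track, chrom_sizes) {
  if (!nrow(track)) return(track)
  miss <- setdiff(unique(track$chromosome), names(chrom_sizes))
  if (length(miss))
    stop("randomize_track: no chromosome length for ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- track
  for (ch in unique(track$chromosome)) {
    i <- which(track$chromosome == ch)
    len <- track$end[i] - track$start[i]
    L <- chrom_sizes[[ch]]
    if (any(len > L))
      stop(sprintf("randomize_track: element longer than chromosome %s", ch),
           call. = FALSE)
    # uniform integer start in [0, L - len]
    start <- floor(stats::runif(length(i)) * (L - len + 1))
    out$start[i] <- as.integer(start)
    out$end[i] <- as.integer(start + len)
  }
  out
}

#' Rank-sum significance of real vs randomized track differences
#'
#' Two-sample Wilcoxon rank-sum test (normal approximation with tie
#' correction), one-sided with alternative "the real per-pair differences are
#' smaller than the randomized ones".
#'
#' @param real,random \code{track_comparison} objects (or numeric difference
#'   vectors), each over at least 20 pairs.
#' @return The one-sided p-value.
#' @export
significance_vs_random <- function(real, random) {
  dx <- if (inherits(real, "track_comparison")) real$table$difference
        else as.numeric(real)
  dy <- if (inherits(random, "track_comparison")) random$table$difference
        else as.numeric(random)
  if (length(dx) < 20L || length(dy) < 20L)
    stop("significance_vs_random: need at least 20 pairs per sample",
         call. = FALSE)
  stats::wilcox.test(dx, dy, alternative = "less", exact = FALSE,
                     correct = FALSE)$p.value
}

#' Write the per-gene track-comparison table
#'
#' Tabular output: gene_A, gene_B, value_A, value_B, z_A, z_B, difference,
#' sorted ascending by difference.
#'
#' @param comparison A \code{track_comparison} from
#'   \code{\link{compare_tracks}}.
#' @param path Output path.
#' @param config Optional named list echoed as '#' provenance comments.
#' @export
write_track_comparison <- function(comparison, path, config = NULL) {
  tab <- comparison$table
  keep <- intersect(c("gene_a", "gene_b", "value_a", "value_b",
                      "z_a", "z_b", "difference"), names(tab))
  out <- tab[keep]
  names(out) <- sub("_a$", "_A", sub("_b$", "_B", names(out)))
  .write_table_with_header(out, path, config)
}
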