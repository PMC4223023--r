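# Breakpoint and block detection inside one syntenic region.
#
# Pairs are ordered by species-A coordinate; pi[i] is the rank of pair i's
# B-gene among the region's B-genes. A breakpoint sits after position i
# whenever |pi[i+1] - pi[i]| != 1, i.e. the two A-adjacent genes' orthologs
# are not adjacent in B. Maximal runs with no internal breakpoint ("strips")
# are the candidate blocks: within a strip the pi values are consecutive and
# strictly monotone, ascending (conserved/translocated order) or descending
# (inverted order).

#' Rank the resolved pairs of one region
#'
#' Orders resolved pairs by species-A coordinate and computes the permutation
#' pi giving each pair's B-side genomic rank. Genes without a resolved
#' ortholog are invisible at this stage.
#'
#' @param pairs Data.frame with columns \code{gene_a}, \code{gene_b} (and
#'   optionally \code{provenance}).
#' @param genes_a,genes_b Gene tables covering the pair members.
#' @return A list of class \code{ranked_region}: \code{pairs} (in A order,
#'   with coordinates and strands of both sides), \code{pi} (integer
#'   permutation), \code{n}.
#' @export
rank_region <- function(pairs, genes_a, genes_b) {
  n <- nrow(pairs)
  if (!n) {
    out <- list(pairs = cbind(pairs,
                              data.frame(start_a = integer(0), end_a = integer(0),
                                         strand_a = character(0),
                                         start_b = integer(0), end_b = integer(0),
                                         strand_b = character(0))),
                pi = integer(0), n = 0L)
    class(out) <- "ranked_region"
    return(out)
  }
  ia <- match(pairs$gene_a, genes_a$gene_id)
  ib <- match(pairs$gene_b, genes_b$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("rank_region: pair member(s) missing from gene tables", call. = FALSE)
  df <- pairs
  df$start_a <- genes_a$start[ia]; df$end_a <- genes_a$end[ia]
  df$strand_a <- genes_a$strand[ia]
  df$start_b <- genes_b$start[ib]; df$end_b <- genes_b$end[ib]
  df$strand_b <- genes_b$strand[ib]
  o <- order(df$start_a, df$end_a, df$gene_a)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  pi <- order(order(df$start_b, df$end_b, df$gene_b))
  out <- list(pairs = df, pi = as.integer(pi), n = n)
  class(out) <- "ranked_region"
  out
}

#' Find breakpoints in a ranked region
#'
#' A breakpoint lies after A-position i (1 <= i < n) iff
#' \code{abs(pi[i+1] - pi[i]) != 1}: the orthologs of the two A-adjacent
#' genes are not adjacent in species B.
#'
#' @param r A \code{ranked_region}, or an integer permutation.
#' @return Integer vector of breakpoint positions (sorted), possibly empty.
#' @export
find_breakpoints <- function(r) {
  pi <- if (inherits(r, "ranked_region")) r$pi else as.integer(r)
  if (length(pi) < 2L) return(integer(0))
  which(abs(diff(pi)) != 1L)
}

# strips of a permutation: maximal runs with |diff| == 1; returns a list of
# index ranges (start, end) into pi
.strips <- function(pi) {
  n <- length(pi)
  if (n == 0L) return(list())
  cuts <- which(abs(diff(pi)) != 1L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

.n_breakpoints <- function(pi) {
  if (length(pi) < 2L) return(0L)
  sum(abs(diff(pi)) != 1L)
}

#' Peel micro-rearranged blocks out of a ranked region
#'
#' Iteratively extracts rearranged segments until the remaining backbone is
#' perfectly collinear (no breakpoints). Each round considers the maximal
#' conserved runs ("strips") delimited by the current breakpoints and peels
#' the one acting as the displaced segment: the strip whose removal most
#' reduces the breakpoint count, with ties broken by preferring a strip of
#' reversed gene order (an inverted segment), then fewer gene pairs, then
#' smaller combined bp span in the two species, then the lexicographically
#' smallest member gene-id set. Ranks are recomputed after every extraction,
#' so blocks nested inside larger rearrangements are peeled before their
#' host. The tie-break chain is invariant under swapping the two species.
#'
#' @param r A \code{ranked_region}.
#' @return A list with \code{backbone} (integer indices into \code{r$pairs}
#'   of the collinear backbone, in A order) and \code{blocks}: a list whose
#'   elements carry \code{members} (indices into \code{r$pairs}),
#'   \code{pi_at_extraction} (residual ranks, a consecutive monotone run) and
#'   \code{kind} (\code{"translocation"} or \code{"inversion"}).
#' @export
peel_blocks <- function(r) {
  stopifnot(inherits(r, "ranked_region"))
  n <- r$n
  if (n == 0L) return(list(backbone = integer(0), blocks = list()))
  alive <- seq_len(n)
  b_rank0 <- r$pi            # original B ranks
  blocks <- list()
  span_a <- as.numeric(r$pairs$end_a) - as.numeric(r$pairs$start_a)
  span_b <- as.numeric(r$pairs$end_b) - as.numeric(r$pairs$start_b)

  repeat {
    pi_sub <- rank(b_rank0[alive])
    nb <- .n_breakpoints(pi_sub)
    if (nb == 0L) break
    st <- .strips(pi_sub)
    best <- NULL
    for (s in st) {
      keep <- setdiff(seq_along(alive), s[1L]:s[2L])
      red <- nb - .n_breakpoints(rank(b_rank0[alive[keep]]))
      members <- alive[s[1L]:s[2L]]
      key <- list(
        red = red,
        desc = s[2L] > s[1L] && pi_sub[s[1L]] > pi_sub[s[2L]],
        npairs = length(members),
        span = (max(as.numeric(r$pairs$end_a[members])) -
                  min(as.numeric(r$pairs$start_a[members]))) +
               (max(as.numeric(r$pairs$end_b[members])) -
                  min(as.numeric(r$pairs$start_b[members]))),
        ids = paste(sort(c(r$pairs$gene_a[members], r$pairs$gene_b[members])),
                    collapse = "\r"),
        s = s, members = members)
      if (is.null(best) ||
          key$red > best$red ||
          (key$red == best$red && key$desc > best$desc) ||
          (key$red == best$red && key$desc == best$desc &&
             key$npairs < best$npairs) ||
          (key$red == best$red && key$desc == best$desc &&
             key$npairs == best$npairs && key$span < best$span) ||
          (key$red == best$red && key$desc == best$desc &&
             key$npairs == best$npairs && key$span == best$span &&
             key$ids < best$ids))
        best <- key
    }
    pi_blk <- pi_sub[best$s[1L]:best$s[2L]]
    blocks[[length(blocks) + 1L]] <-
      list(members = best$members,
           pi_at_extraction = as.integer(pi_blk),
           kind = if (length(pi_blk) >= 2L && pi_blk[1L] > pi_blk[2L])
             "inversion" else "translocation")
    alive <- setdiff(alive, best$members)
    if (!length(alive)) break
  }
  list(backbone = alive, blocks = blocks)
}

#' Classify a peeled block as translocation or inversion
#'
#' Multi-gene blocks: inversion iff the block's gene order is reversed
#' relative to the backbone's direction (for the usual same-orientation
#' backbone: residual ranks descend). If the strand relation of the members
#' contradicts the order-based call, the conflict is reported via
#' \code{message()} and order wins. Single-gene blocks carry no order
#' signal; they are called an inversion iff the pair's strand relation
#' (same/opposite strand in the two species) differs from the dominant
#' strand relation of the backbone.
#'
#' @param block A block from \code{\link{peel_blocks}}.
#' @param r The \code{ranked_region} the block came from.
#' @param backbone Integer indices of the backbone pairs (for the dominant
#'   strand relation); may be empty.
#' @return \code{"translocation"} or \code{"inversion"}.
#' @export
classify_block <- function(block, r, backbone = integer(0)) {
  m <- block$members
  same_strand <- r$pairs$strand_a[m] == r$pairs$strand_b[m]
  if (length(m) >= 2L) {
    blk_pi <- if (!is.null(block$pi_at_extraction)) block$pi_at_extraction
              else r$pi[m]
    blk_asc <- blk_pi[1L] < blk_pi[2L]
    bb_asc <- if (length(backbone) >= 2L)
      r$pi[backbone[1L]] < r$pi[backbone[2L]] else TRUE
    ord_kind <- if (blk_asc == bb_asc) "translocation" else "inversion"
    strand_kind <- NULL
    if (length(backbone)) {
      dom <- mean(r$pairs$strand_a[backbone] == r$pairs$strand_b[backbone]) >= 0.5
      flipped <- mean(same_strand != dom)
      strand_kind <- if (flipped > 0.5) "inversion" else "translocation"
      if (!is.null(strand_kind) && strand_kind != ord_kind)
        message(sprintf(
          "block [%s]: strand relation suggests %s but gene order indicates %s; order wins",
          paste(r$pairs$gene_a[m], collapse = ","), strand_kind, ord_kind))
    }
    return(ord_kind)
  }
  if (length(backbone)) {
    dom <- mean(r$pairs$strand_a[backbone] == r$pairs$strand_b[backbone]) >= 0.5
    if (same_strand != dom) "inversion" else "translocation"
  } else {
    if (same_strand) "translocation" else "inversion"
  }
}

#' Detect external translocations between syntenic regions
#'
#' A gene with no ortholog inside its own region whose link partner (i) lies
#' in a different region and (ii) is itself internally unpaired forms an
#' external pair; maximal runs of consecutive external pairs joining the same
#' two regions with consistent order are merged into one external block. A
#' gene eligible for several partners gets the one with the highest combined
#' identity (reported via \code{message()}).
#'
#' @param orphans_a,orphans_b Data.frames (\code{gene_id}, \code{region_id},
#'   \code{rank}) of internally unpaired genes that had no link inside their
#'   own region, with their genomic rank among all the region's genes.
#' @param links Full ortholog table.
#' @return A list of external blocks; each has \code{region_a},
#'   \code{region_b} and \code{pairs} (data.frame \code{gene_a},
#'   \code{gene_b}, \code{provenance = "external"}).
#' @export
detect_external_blocks <- function(orphans_a, orphans_b, links) {
  cand <- links[links$gene_a %in% orphans_a$gene_id &
                  links$gene_b %in% orphans_b$gene_id, , drop = FALSE]
  if (!nrow(cand)) return(list())
  ia <- match(cand$gene_a, orphans_a$gene_id)
  ib <- match(cand$gene_b, orphans_b$gene_id)
  keep <- orphans_a$region_id[ia] != orphans_b$region_id[ib]
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(list())
  ia <- ia[keep]; ib <- ib[keep]

  # greedy one-to-one matching by combined identity (deterministic)
  score <- .link_identity(cand)
  o <- order(-score, cand$gene_a, cand$gene_b)
  used_a <- character(0); used_b <- character(0)
  sel <- logical(nrow(cand))
  multi <- unique(c(cand$gene_a[duplicated(cand$gene_a)],
                    cand$gene_b[duplicated(cand$gene_b)]))
  if (length(multi))
    message("external pairing: ", length(multi),
            " gene(s) with several eligible partners resolved by highest identity")
  for (k in o) {
    if (cand$gene_a[k] %in% used_a || cand$gene_b[k] %in% used_b) next
    sel[k] <- TRUE
    used_a <- c(used_a, cand$gene_a[k])
    used_b <- c(used_b, cand$gene_b[k])
  }
  cand <- cand[sel, , drop = FALSE]
  ia <- match(cand$gene_a, orphans_a$gene_id)
  ib <- match(cand$gene_b, orphans_b$gene_id)

  df <- data.frame(gene_a = cand$gene_a, gene_b = cand$gene_b,
                   region_a = orphans_a$region_id[ia],
                   region_b = orphans_b$region_id[ib],
                   rank_a = orphans_a$rank[ia],
                   rank_b = orphans_b$rank[ib],
                   stringsAsFactors = FALSE)
  df <- df[order(df$region_a, df$rank_a), , drop = FALSE]

  # merge maximal runs: same region pair, A-ranks and B-ranks both advancing
  # by exactly one gene, with a consistent direction in B
  blocks <- list()
  i <- 1L
  nd <- nrow(df)
  while (i <= nd) {
    j <- i
    dir <- 0L
    while (j < nd &&
           df$region_a[j + 1L] == df$region_a[i] &&
           df$region_b[j + 1L] == df$region_b[i] &&
           df$rank_a[j + 1L] == df$rank_a[j] + 1L &&
           abs(df$rank_b[j + 1L] - df$rank_b[j]) == 1L &&
           (dir == 0L || df$rank_b[j + 1L] - df$rank_b[j] == dir)) {
      dir <- df$rank_b[j + 1L] - df$rank_b[j]
      j <- j + 1L
    }
    blocks[[length(blocks) + 1L]] <-
      list(region_a = df$region_a[i], region_b = df$region_b[i],
           pairs = data.frame(gene_a = df$gene_a[i:j],
                              gene_b = df$gene_b[i:j],
                              provenance = "external",
                              stringsAsFactors = FALSE))
    i <- j + 1L
  }
  blocks
}
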