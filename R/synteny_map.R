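#' Refine syntenic regions into blocks of perfectly conserved gene order
#'
#' The top-level pipeline. Assigns genes to their syntenic regions (midpoint
#' rule), resolves one-to-many / many-to-many ortholog groups into syntenic
#' one-to-one pairs, detects breakpoints and peels out internally rearranged
#' blocks (translocations and inversions), and pairs up external orthologs
#' translocated between regions. Every input region yields one
#' \emph{original} refined region (its collinear backbone) plus zero or more
#' \emph{internal} regions (one per peeled block) and \emph{external}
#' regions; derived regions are named \code{<parent>_<counter>}.
#'
#' @param genes_a,genes_b Gene tables (see \code{\link{read_gene_table}}), or
#'   pass a single list with elements \code{genes_a}, \code{genes_b},
#'   \code{regions}, \code{orthologs} as the first argument.
#' @param regions Syntenic-region pair table.
#' @param orthologs Pairwise ortholog table with percent identities.
#' @return An object of class \code{synteny_map}: a list with
#'   \describe{
#'     \item{regions}{data.frame of refined regions: \code{region_id},
#'       \code{parent_region_id}, \code{type}, \code{rearrangement},
#'       intervals in both species, \code{n_pairs}.}
#'     \item{pairs}{data.frame of syntenic one-to-one pairs with the refined
#'       region each belongs to and its \code{provenance}.}
#'     \item{removals}{genes removed during resolution, with reasons.}
#'     \item{blocks}{per-block detail (member pairs, residual ranks at
#'       extraction, kind, parent, nesting).}
#'     \item{unassigned}{gene ids outside every syntenic region.}
#'     \item{summary}{named counts.}
#'   }
#' @examples
#' sim <- simulate_genome_pair(n_regions = 3, genes_per_region = 12, seed = 1)
#' sim <- plant_rearrangements(sim, n_internal = 2, n_external = 1, seed = 2)
#' map <- synteny_map(sim)
#' map
#' @export
synteny_map <- function(genes_a, genes_b = NULL, regions = NULL,
                        orthologs = NULL) {
  if (is.list(genes_a) && !is.data.frame(genes_a) &&
      all(c("genes_a", "genes_b", "regions", "orthologs") %in% names(genes_a))) {
    dataset <- genes_a
    genes_b <- dataset$genes_b; regions <- dataset$regions
    orthologs <- dataset$orthologs; genes_a <- dataset$genes_a
  }
  validate_genes(genes_a); validate_genes(genes_b); validate_regions(regions)

  asg_a <- assign_genes_to_regions(genes_a, regions, "A")
  asg_b <- assign_genes_to_regions(genes_b, regions, "B")
  ga_idx <- split(match(asg_a$assigned$gene_id, genes_a$gene_id),
                  asg_a$assigned$region_id)
  gb_idx <- split(match(asg_b$assigned$gene_id, genes_b$gene_id),
                  asg_b$assigned$region_id)
  rank_a_all <- stats::setNames(asg_a$assigned$rank, asg_a$assigned$gene_id)
  rank_b_all <- stats::setNames(asg_b$assigned$rank, asg_b$assigned$gene_id)
  region_of_a <- stats::setNames(asg_a$assigned$region_id,
                                 asg_a$assigned$gene_id)
  region_of_b <- stats::setNames(asg_b$assigned$region_id,
                                 asg_b$assigned$gene_id)

  # pre-split links by species-A region for speed; links crossing regions are
  # picked up again during external detection
  link_region <- region_of_a[orthologs$gene_a]
  same_region <- !is.na(link_region) &
    !is.na(region_of_b[orthologs$gene_b]) &
    link_region == region_of_b[orthologs$gene_b]
  links_by_region <- split(orthologs[same_region, , drop = FALSE],
                           link_region[same_region])

  region_ids <- regions$region_id
  res <- vector("list", length(region_ids))
  names(res) <- region_ids
  removals <- list()
  orphans_a <- list(); orphans_b <- list()

  for (rid in region_ids) {
    sub_a <- genes_a[ga_idx[[rid]], , drop = FALSE]
    sub_b <- genes_b[gb_idx[[rid]], , drop = FALSE]
    if (is.null(sub_a)) sub_a <- genes_a[0L, , drop = FALSE]
    if (is.null(sub_b)) sub_b <- genes_b[0L, , drop = FALSE]
    li <- links_by_region[[rid]]
    if (is.null(li)) li <- orthologs[0L, , drop = FALSE]
    rr <- resolve_region(sub_a, sub_b, li)
    res[[rid]] <- rr
    if (nrow(rr$removed)) {
      rem <- rr$removed
      rem$region_id <- rid
      removals[[length(removals) + 1L]] <- rem
      orp <- rem[rem$reason == "no_ortholog", , drop = FALSE]
      if (nrow(orp)) {
        oa <- orp$gene_id[orp$species == "A"]
        ob <- orp$gene_id[orp$species == "B"]
        if (length(oa))
          orphans_a[[length(orphans_a) + 1L]] <-
            data.frame(gene_id = oa, region_id = rid,
                       rank = unname(rank_a_all[oa]), stringsAsFactors = FALSE)
        if (length(ob))
          orphans_b[[length(orphans_b) + 1L]] <-
            data.frame(gene_id = ob, region_id = rid,
                       rank = unname(rank_b_all[ob]), stringsAsFactors = FALSE)
      }
    }
  }
  removals <- if (length(removals)) do.call(rbind, removals)
              else data.frame(gene_id = character(0), species = character(0),
                              reason = character(0), region_id = character(0),
                              stringsAsFactors = FALSE)
  empty_orph <- data.frame(gene_id = character(0), region_id = character(0),
                           rank = integer(0), stringsAsFactors = FALSE)
  orphans_a <- if (length(orphans_a)) do.call(rbind, orphans_a) else empty_orph
  orphans_b <- if (length(orphans_b)) do.call(rbind, orphans_b) else empty_orph

  ext_blocks <- detect_external_blocks(orphans_a, orphans_b, orthologs)

  # assemble refined regions
  reg_rows <- list()
  pair_rows <- list()
  block_detail <- list()
  ext_by_region <- if (length(ext_blocks))
    split(seq_along(ext_blocks),
          vapply(ext_blocks, function(b) b$region_a, "")) else list()

  for (k in seq_along(region_ids)) {
    rid <- region_ids[k]
    reg_in <- regions[k, ]
    rr <- res[[rid]]
    sub_a <- genes_a[ga_idx[[rid]], , drop = FALSE]
    sub_b <- genes_b[gb_idx[[rid]], , drop = FALSE]
    ranked <- rank_region(rr$pairs, sub_a, sub_b)
    peeled <- peel_blocks(ranked)

    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      region_id = rid, parent_region_id = NA_character_, type = "original",
      rearrangement = "none",
      chrom_a = reg_in$chrom_a, start_a = reg_in$start_a, end_a = reg_in$end_a,
      chrom_b = reg_in$chrom_b, start_b = reg_in$start_b, end_b = reg_in$end_b,
      n_pairs = length(peeled$backbone), stringsAsFactors = FALSE)
    if (length(peeled$backbone)) {
      bp <- ranked$pairs[peeled$backbone, , drop = FALSE]
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        region_id = rid, gene_a = bp$gene_a, gene_b = bp$gene_b,
        provenance = bp$provenance, ord = bp$start_a, ord_b = bp$start_b,
        stringsAsFactors = FALSE)
    }

    # children: internal blocks then external blocks, ordered by A start
    children <- list()
    for (blk in peeled$blocks) {
      m <- blk$members
      kind <- classify_block(blk, ranked, peeled$backbone)
      children[[length(children) + 1L]] <- list(
        what = "internal", kind = kind,
        a_start = min(ranked$pairs$start_a[m]),
        a_end = max(ranked$pairs$end_a[m]),
        b_start = min(ranked$pairs$start_b[m]),
        b_end = max(ranked$pairs$end_b[m]),
        chrom_b = reg_in$chrom_b,
        pairs = ranked$pairs[m, c("gene_a", "gene_b", "provenance"),
                             drop = FALSE],
        pi_at_extraction = blk$pi_at_extraction)
    }
    for (ei in ext_by_region[[rid]]) {
      eb <- ext_blocks[[ei]]
      ia <- match(eb$pairs$gene_a, genes_a$gene_id)
      ib <- match(eb$pairs$gene_b, genes_b$gene_id)
      children[[length(children) + 1L]] <- list(
        what = "external", kind = "translocation",
        a_start = min(genes_a$start[ia]), a_end = max(genes_a$end[ia]),
        b_start = min(genes_b$start[ib]), b_end = max(genes_b$end[ib]),
        chrom_b = regions$chrom_b[match(eb$region_b, regions$region_id)],
        region_b = eb$region_b,
        pairs = eb$pairs)
    }
    if (length(children)) {
      o <- order(vapply(children, function(ch) ch$a_start, 0))
      children <- children[o]
      for (ci in seq_along(children)) {
        ch <- children[[ci]]
        cid <- paste0(rid, "_", ci)
        reg_rows[[length(reg_rows) + 1L]] <- data.frame(
          region_id = cid, parent_region_id = rid, type = ch$what,
          rearrangement = ch$kind,
          chrom_a = reg_in$chrom_a, start_a = ch$a_start, end_a = ch$a_end,
          chrom_b = ch$chrom_b, start_b = ch$b_start, end_b = ch$b_end,
          n_pairs = nrow(ch$pairs), stringsAsFactors = FALSE)
        pr <- ch$pairs
        pr$provenance <- if (ch$what == "external") "external" else
          pr$provenance
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          region_id = cid, gene_a = pr$gene_a, gene_b = pr$gene_b,
          provenance = pr$provenance,
          ord = genes_a$start[match(pr$gene_a, genes_a$gene_id)],
          ord_b = genes_b$start[match(pr$gene_b, genes_b$gene_id)],
          stringsAsFactors = FALSE)
        block_detail[[length(block_detail) + 1L]] <- list(
          region_id = cid, parent_region_id = rid, type = ch$what,
          kind = ch$kind, gene_a = pr$gene_a, gene_b = pr$gene_b,
          pi_at_extraction = ch$pi_at_extraction)
      }
    }
  }

  regions_out <- do.call(rbind, reg_rows)
  rownames(regions_out) <- NULL
  pairs_out <- if (length(pair_rows)) do.call(rbind, pair_rows)
               else data.frame(region_id = character(0), gene_a = character(0),
                               gene_b = character(0), provenance = character(0),
                               ord = integer(0), ord_b = integer(0),
                               stringsAsFactors = FALSE)
  pairs_out <- pairs_out[order(pairs_out$region_id, pairs_out$ord), ,
                         drop = FALSE]
  rownames(pairs_out) <- NULL

  # nesting: smallest other block whose A-span strictly contains this one
  if (length(block_detail) > 1L) {
    sp <- cbind(
      start = vapply(block_detail, function(b)
        regions_out$start_a[match(b$region_id, regions_out$region_id)], 0),
      end = vapply(block_detail, function(b)
        regions_out$end_a[match(b$region_id, regions_out$region_id)], 0))
    par_reg <- vapply(block_detail, function(b) b$parent_region_id, "")
    for (i in seq_along(block_detail)) {
      inside <- which(par_reg == par_reg[i] &
                        sp[, "start"] <= sp[i, "start"] &
                        sp[, "end"] >= sp[i, "end"] &
                        seq_along(block_detail) != i)
      if (length(inside)) {
        j <- inside[which.min(sp[inside, "end"] - sp[inside, "start"])]
        block_detail[[i]]$nested_in <- block_detail[[j]]$region_id
      }
    }
  }

  smry <- c(
    n_input_regions = nrow(regions),
    n_refined_regions = nrow(regions_out),
    n_original = sum(regions_out$type == "original"),
    n_internal = sum(regions_out$type == "internal"),
    n_external = sum(regions_out$type == "external"),
    n_translocations = sum(regions_out$rearrangement == "translocation"),
    n_inversions = sum(regions_out$rearrangement == "inversion"),
    n_pairs = nrow(pairs_out),
    n_removed_genes = nrow(removals),
    n_unassigned = length(asg_a$unassigned) + length(asg_b$unassigned))

  out <- list(regions = regions_out, pairs = pairs_out, removals = removals,
              blocks = block_detail,
              unassigned = list(a = asg_a$unassigned, b = asg_b$unassigned),
              summary = smry, call = match.call())
  class(out) <- "synteny_map"
  out
}

#' @export
print.synteny_map <- function(x, ...) {
  s <- x$summary
  cat("Refined synteny map\n")
  cat(sprintf("  input regions:    %d\n", s[["n_input_regions"]]))
  cat(sprintf("  refined regions:  %d (original %d, internal %d, external %d)\n",
              s[["n_refined_regions"]], s[["n_original"]], s[["n_internal"]],
              s[["n_external"]]))
  cat(sprintf("  rearrangements:   %d translocations, %d inversions\n",
              s[["n_translocations"]], s[["n_inversions"]]))
  cat(sprintf("  syntenic 1:1 ortholog pairs: %d\n", s[["n_pairs"]]))
  cat(sprintf("  genes removed in resolution: %d\n", s[["n_removed_genes"]]))
  invisible(x)
}

#' @export
summary.synteny_map <- function(object, ...) {
  print(object)
  if (nrow(object$removals)) {
    cat("  removal reasons:\n")
    tb <- table(object$removals$reason)
    for (nm in names(tb)) cat(sprintf("    %-18s %d\n", nm, tb[[nm]]))
  }
  if (length(object$unassigned$a) || length(object$unassigned$b))
    cat(sprintf("  syntenic-block-free genes: %d (A) + %d (B)\n",
                length(object$unassigned$a), length(object$unassigned$b)))
  invisible(object)
}

#' Dot-plot of one refined region
#'
#' Plots species-A gene rank against species-B gene rank for the resolved
#' pairs of one input region, coloring backbone and derived blocks.
#'
#' @param x A \code{synteny_map}.
#' @param region_id An input (parent) region id.
#' @param ... Passed to \code{plot}.
#' @export
plot.synteny_map <- function(x, region_id = NULL, ...) {
  if (is.null(region_id))
    region_id <- x$regions$region_id[x$regions$type == "original"][1L]
  kids <- x$regions$region_id[
    !is.na(x$regions$parent_region_id) &
      x$regions$parent_region_id == region_id]
  sel <- x$pairs[x$pairs$region_id %in% c(region_id, kids), , drop = FALSE]
  if (!nrow(sel)) {
    graphics::plot.new()
    return(invisible(x))
  }
  ra <- rank(sel$ord)
  rb <- rank(sel$ord_b)
  grp <- match(sel$region_id, c(region_id, kids))
  graphics::plot(ra, rb, col = grp, pch = 19,
                 xlab = "gene rank in A", ylab = "gene rank in B",
                 main = paste("region", region_id), ...)
  invisible(x)
}

#' Swap the two species of a synteny input
#'
#' Returns the same dataset with species A and B exchanged (gene tables,
#' region intervals and ortholog direction). Useful for checking that block
#' detection does not depend on the choice of reference genome.
#'
#' @param dataset A list with \code{genes_a}, \code{genes_b}, \code{regions},
#'   \code{orthologs}.
#' @return A list of the same shape with the species swapped.
#' @export
swap_species <- function(dataset) {
  regions <- dataset$regions
  regions_sw <- data.frame(region_id = regions$region_id,
                           chrom_a = regions$chrom_b,
                           start_a = regions$start_b, end_a = regions$end_b,
                           chrom_b = regions$chrom_a,
                           start_b = regions$start_a, end_b = regions$end_a,
                           stringsAsFactors = FALSE)
  orth <- dataset$orthologs
  orth_sw <- data.frame(gene_a = orth$gene_b, gene_b = orth$gene_a,
                        identity_ab = orth$identity_ba,
                        identity_ba = orth$identity_ab,
                        stringsAsFactors = FALSE)
  list(genes_a = dataset$genes_b, genes_b = dataset$genes_a,
       regions = regions_sw, orthologs = orth_sw)
}

#' Canonical block pair-sets of a synteny map
#'
#' Returns one string per derived (internal or external) region encoding its
#' member ortholog pairs as an unordered set, independent of which species
#' was used as the reference. Two maps describe the same rearrangements iff
#' these sets are equal.
#'
#' @param map A \code{synteny_map}.
#' @param swapped Set \code{TRUE} if \code{map} was computed on a
#'   species-swapped input, so pair members are reported in the original
#'   orientation.
#' @return Sorted character vector, one element per block.
#' @export
block_pair_sets <- function(map, swapped = FALSE) {
  out <- vapply(map$blocks, function(b) {
    a <- if (swapped) b$gene_b else b$gene_a
    bb <- if (swapped) b$gene_a else b$gene_b
    paste(sort(paste(a, bb, sep = "|")), collapse = ";")
  }, "")
  sort(out)
}
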