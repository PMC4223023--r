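# Resolution of raw orthology links within a syntenic region into syntenic
# one-to-one pairs. Groups are connected components of the bipartite link
# graph restricted to the region; one-to-many groups are reduced by sequence
# identity, asymmetric many-to-many groups are trimmed to symmetry, and
# symmetric groups are split positionally (i-th gene with i-th gene).

# combined identity used for all rankings: mean of both directions
.link_identity <- function(links) (links$identity_ab + links$identity_ba) / 2

#' Group region orthology links into ortholog groups
#'
#' Computes the connected components of the bipartite orthology graph
#' restricted to one syntenic region. Genes with no link inside the region
#' form the \code{no_ortholog} class and take no further part in resolution.
#'
#' @param genes_a,genes_b Character vectors of gene ids in genomic order
#'   within the region (species A and B).
#' @param links Data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{identity_ab}, \code{identity_ba}; only rows with both endpoints in
#'   the region are used.
#' @return A list of groups. Each group is a list with \code{genes_a},
#'   \code{genes_b} (ordered as in the input = genomic order), \code{links}
#'   (the component's link rows) and \code{class} (\code{one_internal} or
#'   \code{many_internal}). The \code{no_ortholog} gene ids are attached as
#'   attribute \code{no_ortholog} (list with \code{a} and \code{b}).
#' @export
group_orthologs <- function(genes_a, genes_b, links) {
  links <- links[links$gene_a %in% genes_a & links$gene_b %in% genes_b, ,
                 drop = FALSE]
  ids <- c(paste0("A\r", genes_a), paste0("B\r", genes_b))
  parent <- seq_along(ids)
  idx <- stats::setNames(seq_along(ids), ids)

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(links)) {
    la <- idx[paste0("A\r", links$gene_a)]
    lb <- idx[paste0("B\r", links$gene_b)]
    for (k in seq_len(nrow(links))) {
      ra <- find(la[k]); rb <- find(lb[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(ids), find, 0L)
  linked <- logical(length(ids))
  if (nrow(links)) linked[c(idx[paste0("A\r", links$gene_a)],
                            idx[paste0("B\r", links$gene_b)])] <- TRUE

  groups <- list()
  for (r in unique(root[linked])) {
    members <- which(root == r & linked)
    ga <- genes_a[genes_a %in% sub("^A\r", "", ids[members[startsWith(ids[members], "A")]])]
    gb <- genes_b[genes_b %in% sub("^B\r", "", ids[members[startsWith(ids[members], "B")]])]
    glinks <- links[links$gene_a %in% ga & links$gene_b %in% gb, , drop = FALSE]
    cls <- if (length(ga) == 1L && length(gb) == 1L) "one_internal"
           else "many_internal"
    groups[[length(groups) + 1L]] <-
      list(genes_a = ga, genes_b = gb, links = glinks, class = cls)
  }
  attr(groups, "no_ortholog") <-
    list(a = genes_a[!paste0("A\r", genes_a) %in% ids[linked]],
         b = genes_b[!paste0("B\r", genes_b) %in% ids[linked]])
  groups
}

#' Reduce a one-to-many ortholog group to a single pair
#'
#' Keeps the pair whose link has the highest combined identity (mean of the
#' two directional percent identities); ties are broken by smaller genomic
#' rank distance between the two genes within their region, then by gene id.
#' All other genes of the group are reported as losers.
#'
#' @param group A group from \code{\link{group_orthologs}} with exactly one
#'   gene on one side and two or more on the other.
#' @param rank_a,rank_b Optional named integer vectors of genomic ranks used
#'   for the tie-break.
#' @return A list with \code{pair} (data.frame \code{gene_a}, \code{gene_b},
#'   \code{provenance = "one_to_many_reduced"}) and \code{losers} (character
#'   vector of removed gene ids).
#' @export
reduce_one_to_many <- function(group, rank_a = NULL, rank_b = NULL) {
  na <- length(group$genes_a); nb <- length(group$genes_b)
  if (!((na == 1L && nb >= 2L) || (nb == 1L && na >= 2L)))
    stop("reduce_one_to_many: group is not one-to-many (",
         na, " vs ", nb, " genes)", call. = FALSE)
  li <- group$links
  score <- .link_identity(li)
  rd <- rep(0, nrow(li))
  if (!is.null(rank_a) && !is.null(rank_b)) {
    ra <- rank_a[li$gene_a]; rb <- rank_b[li$gene_b]
    ok <- !is.na(ra) & !is.na(rb)
    rd[ok] <- abs(ra[ok] - rb[ok])
  }
  o <- order(-score, rd, li$gene_a, li$gene_b)
  best <- li[o[1L], ]
  losers <- setdiff(c(group$genes_a, group$genes_b),
                    c(best$gene_a, best$gene_b))
  list(pair = data.frame(gene_a = best$gene_a, gene_b = best$gene_b,
                         provenance = "one_to_many_reduced",
                         stringsAsFactors = FALSE),
       losers = losers)
}

#' Trim an asymmetric many-to-many group to symmetry
#'
#' For a group with n genes in species A and m in species B (n != m), removes
#' exactly |n - m| genes from the larger side: those with the lowest average
#' combined identity to their linked partners in the group (ties: gene id).
#'
#' @param group A group from \code{\link{group_orthologs}}.
#' @return A list with \code{group} (the symmetric group) and \code{removed}
#'   (character vector of trimmed gene ids; empty if already symmetric).
#' @export
symmetrize_group <- function(group) {
  na <- length(group$genes_a); nb <- length(group$genes_b)
  if (na == nb) return(list(group = group, removed = character(0)))
  score <- .link_identity(group$links)
  side <- if (na > nb) "a" else "b"
  genes <- if (side == "a") group$genes_a else group$genes_b
  linkg <- if (side == "a") group$links$gene_a else group$links$gene_b
  avg <- vapply(genes, function(g) mean(score[linkg == g]), 0)
  avg[is.nan(avg)] <- -Inf  # a member with no link ranks lowest
  delta <- abs(na - nb)
  o <- order(avg, genes)
  removed <- genes[o[seq_len(delta)]]
  if (side == "a") {
    group$genes_a <- setdiff(group$genes_a, removed)
  } else {
    group$genes_b <- setdiff(group$genes_b, removed)
  }
  group$links <- group$links[!(group$links$gene_a %in% removed) &
                               !(group$links$gene_b %in% removed), ,
                             drop = FALSE]
  list(group = group, removed = removed)
}

#' Split a symmetric many-to-many group by gene order
#'
#' Pairs the i-th gene of species A with the i-th gene of species B, both in
#' genomic order within the region. The produced pairs need not correspond to
#' input links: order, not identity, decides.
#'
#' @param group A symmetric group (equal side sizes).
#' @return Data.frame of pairs with \code{provenance = "order_split"}
#'   (\code{"direct"} for a trivial 1x1 group).
#' @export
split_symmetric_group <- function(group) {
  na <- length(group$genes_a); nb <- length(group$genes_b)
  if (na != nb)
    stop("split_symmetric_group: group is asymmetric (", na, " vs ", nb, ")",
         call. = FALSE)
  data.frame(gene_a = group$genes_a, gene_b = group$genes_b,
             provenance = if (na == 1L) "direct" else "order_split",
             stringsAsFactors = FALSE)
}

# same-species coordinate overlaps within one region: all participants go.
# With genes sorted by start, gene i overlaps a later gene iff
# end[i] >= start[i+1], and an earlier one iff start[i] <= max(end[1..i-1]).
.overlapping_genes <- function(genes) {
  if (nrow(genes) < 2L) return(character(0))
  bad <- character(0)
  for (ch in unique(genes$chromosome)) {
    sel <- genes$chromosome == ch
    if (sum(sel) < 2L) next
    o <- order(genes$start[sel], genes$end[sel])
    id <- genes$gene_id[sel][o]
    st <- genes$start[sel][o]
    en <- genes$end[sel][o]
    n <- length(id)
    with_later <- c(en[-n] >= st[-1L], FALSE)
    with_earlier <- c(FALSE, st[-1L] <= cummax(en)[-n])
    bad <- c(bad, id[with_later | with_earlier])
  }
  unique(bad)
}

#' Resolve one syntenic region into one-to-one syntenic ortholog pairs
#'
#' Applies, in order: exclusion of same-species coordinate-overlapping genes,
#' grouping into connected components, reduction of one-to-many groups by
#' identity, trimming of asymmetric many-to-many groups, and positional
#' splitting of symmetric groups.
#'
#' @param genes_a,genes_b Gene-table rows for this region (one species each),
#'   any row order; genomic order is recomputed internally.
#' @param links Ortholog table (is filtered to the region's genes).
#' @return A list of class \code{resolution_report}: \code{pairs} (data.frame
#'   \code{gene_a}, \code{gene_b}, \code{provenance}), \code{removed}
#'   (data.frame \code{gene_id}, \code{species}, \code{reason} in
#'   one_to_many_loser / asymmetry_trim / overlap_excluded / no_ortholog),
#'   and \code{n_links_removed}.
#' @export
resolve_region <- function(genes_a, genes_b, links) {
  genes_a <- genes_a[order(genes_a$start, genes_a$end, genes_a$gene_id), ,
                     drop = FALSE]
  genes_b <- genes_b[order(genes_b$start, genes_b$end, genes_b$gene_id), ,
                     drop = FALSE]
  removed <- data.frame(gene_id = character(0), species = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  note <- function(ids, species, reason) {
    if (length(ids))
      removed <<- rbind(removed,
                        data.frame(gene_id = ids, species = species,
                                   reason = reason, stringsAsFactors = FALSE))
  }

  ov_a <- .overlapping_genes(genes_a)
  ov_b <- .overlapping_genes(genes_b)
  note(ov_a, "A", "overlap_excluded")
  note(ov_b, "B", "overlap_excluded")
  genes_a <- genes_a[!genes_a$gene_id %in% ov_a, , drop = FALSE]
  genes_b <- genes_b[!genes_b$gene_id %in% ov_b, , drop = FALSE]

  links <- links[links$gene_a %in% genes_a$gene_id &
                   links$gene_b %in% genes_b$gene_id, , drop = FALSE]
  n_links_in <- nrow(links)

  rank_a <- stats::setNames(seq_len(nrow(genes_a)), genes_a$gene_id)
  rank_b <- stats::setNames(seq_len(nrow(genes_b)), genes_b$gene_id)

  note(setdiff(genes_a$gene_id, links$gene_a), "A", "no_ortholog")
  note(setdiff(genes_b$gene_id, links$gene_b), "B", "no_ortholog")

  # fast path: links whose endpoints both have degree one are direct pairs
  deg_a <- table(links$gene_a)
  deg_b <- table(links$gene_b)
  is_direct <- deg_a[links$gene_a] == 1L & deg_b[links$gene_b] == 1L
  direct <- links[is_direct, , drop = FALSE]
  rest <- links[!is_direct, , drop = FALSE]

  pairs <- list()
  if (nrow(direct))
    pairs[[1L]] <- data.frame(gene_a = direct$gene_a, gene_b = direct$gene_b,
                              provenance = "direct", stringsAsFactors = FALSE)
  groups <- if (nrow(rest))
    group_orthologs(genes_a$gene_id[genes_a$gene_id %in% rest$gene_a],
                    genes_b$gene_id[genes_b$gene_id %in% rest$gene_b], rest)
  else list()
  for (g in groups) {
    na <- length(g$genes_a); nb <- length(g$genes_b)
    if (na == 1L && nb == 1L) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene_a = g$genes_a, gene_b = g$genes_b,
                   provenance = "direct", stringsAsFactors = FALSE)
    } else if (na == 1L || nb == 1L) {
      red <- reduce_one_to_many(g, rank_a, rank_b)
      pairs[[length(pairs) + 1L]] <- red$pair
      note(red$losers[red$losers %in% genes_a$gene_id], "A",
           "one_to_many_loser")
      note(red$losers[red$losers %in% genes_b$gene_id], "B",
           "one_to_many_loser")
    } else {
      sym <- symmetrize_group(g)
      note(sym$removed[sym$removed %in% genes_a$gene_id], "A",
           "asymmetry_trim")
      note(sym$removed[sym$removed %in% genes_b$gene_id], "B",
           "asymmetry_trim")
      pairs[[length(pairs) + 1L]] <- split_symmetric_group(sym$group)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(gene_a = character(0), gene_b = character(0),
                           provenance = character(0), stringsAsFactors = FALSE)
  # order by species-A genomic position
  pairs <- pairs[order(rank_a[pairs$gene_a]), , drop = FALSE]
  rownames(pairs) <- NULL
  n_links_out <- sum(links$gene_a %in% pairs$gene_a &
                       links$gene_b %in% pairs$gene_b &
                       links$gene_a %in% genes_a$gene_id)
  out <- list(pairs = pairs, removed = removed,
              n_links_removed = max(0L, n_links_in - n_links_out))
  class(out) <- "resolution_report"
  out
}
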