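# Seedable synthetic genome-pair generator. Species A is laid out
# collinearly; species B starts as a structurally identical copy (identity
# permutation in every region) into which micro-rearrangements are planted:
# internal translocations (a run of B-genes relocated within its region),
# inversions (a run reversed, strands flipped), external translocations (a
# run moved into a different region) and gene duplications that create
# one-to-many / asymmetric many-to-many ortholog groups with a known
# intended survivor. Planted events are kept disjoint (with a one-gene
# buffer) and every translocated run jumps over more genes than it contains,
# so each planted event is exactly recoverable.

.sim_gap <- 20000L        # intergenic gap, bp
.sim_margin <- 5000L      # region interval margin around first/last gene
.sim_region_gap <- 1e6    # gap between regions on a chromosome
.regions_per_chrom <- 8L

.draw_lengths <- function(n, mean_bp) {
  # log-normal with the requested mean; sdlog 0.6 gives a realistic spread
  sdlog <- 0.6
  len <- round(stats::rlnorm(n, meanlog = log(mean_bp) - sdlog^2 / 2,
                             sdlog = sdlog))
  pmax(len, 200L)
}

#' Generate a collinear synthetic genome pair
#'
#' Creates \code{n_regions} syntenic regions of \code{genes_per_region}
#' one-to-one ortholog pairs each. Species A is collinear; species B is an
#' order-identical copy, so the permutation is the identity in every region
#' until \code{\link{plant_rearrangements}} is applied. Gene lengths are
#' log-normal around 59.8 kb (A) and 44.3 kb (B); link identities are drawn
#' in [60, 100].
#'
#' @param n_regions Number of syntenic regions (>= 1).
#' @param genes_per_region Ortholog pairs per region (>= 2).
#' @param seed Optional integer seed (sets the RNG).
#' @return A list of class \code{synteny_sim} with \code{genes_a},
#'   \code{genes_b}, \code{regions}, \code{orthologs} (ready for
#'   \code{\link{synteny_map}}), \code{truth} (intended pairs, planted
#'   events, intended duplication losers) and an internal \code{layout} used
#'   by the planting step.
#' @export
simulate_genome_pair <- function(n_regions = 20L, genes_per_region = 50L,
                                 seed = NULL) {
  stopifnot(n_regions >= 1L, genes_per_region >= 2L)
  if (!is.null(seed)) set.seed(seed)
  layout <- vector("list", n_regions)
  links <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    m <- genes_per_region
    a_ids <- sprintf("gA_%03d_%03d", i, seq_len(m))
    b_ids <- sprintf("gB_%03d_%03d", i, seq_len(m))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    ident <- stats::runif(m, 60, 100)
    layout[[i]] <- list(
      region_id = sprintf("R%03d", i),
      a_ids = a_ids, a_len = .draw_lengths(m, 59800), a_strand = strand,
      b_ids = b_ids, b_len = .draw_lengths(m, 44300), b_strand = strand)
    links[[i]] <- data.frame(gene_a = a_ids, gene_b = b_ids,
                             identity_ab = ident, identity_ba = ident,
                             stringsAsFactors = FALSE)
  }
  truth <- list(
    pairs = do.call(rbind, lapply(layout, function(l)
      data.frame(gene_a = l$a_ids, gene_b = l$b_ids,
                 stringsAsFactors = FALSE))),
    events = list(),
    losers = data.frame(gene_id = character(0), species = character(0),
                        survivor = character(0), stringsAsFactors = FALSE))
  sim <- list(layout = layout, orthologs = do.call(rbind, links),
              truth = truth)
  class(sim) <- "synteny_sim"
  .materialize(sim)
}

# lay out gene coordinates and region intervals from the current orders
.materialize <- function(sim) {
  lay <- sim$layout
  mk_species <- function(side) {
    ids_f <- paste0(side, "_ids"); len_f <- paste0(side, "_len")
    str_f <- paste0(side, "_strand")
    chrom_pref <- if (side == "a") "chrA_" else "chrB_"
    genes <- vector("list", length(lay))
    rint <- matrix(0, nrow = length(lay), ncol = 2)
    pos <- 1
    cur_chrom <- ""
    for (i in seq_along(lay)) {
      l <- lay[[i]]
      chrom <- paste0(chrom_pref, (i - 1L) %/% .regions_per_chrom + 1L)
      if (chrom != cur_chrom) { pos <- 1; cur_chrom <- chrom }
      len <- l[[len_f]]
      m <- length(len)
      starts <- pos + .sim_margin +
        cumsum(c(0, len[-m] + .sim_gap))
      ends <- starts + len - 1
      genes[[i]] <- data.frame(gene_id = l[[ids_f]], chromosome = chrom,
                               start = as.integer(starts),
                               end = as.integer(ends),
                               strand = l[[str_f]],
                               stringsAsFactors = FALSE)
      rint[i, ] <- c(starts[1L] - .sim_margin, ends[m] + .sim_margin)
      pos <- ends[m] + .sim_margin + .sim_region_gap
    }
    list(genes = do.call(rbind, genes),
         chrom = vapply(seq_along(lay), function(i)
           paste0(chrom_pref, (i - 1L) %/% .regions_per_chrom + 1L), ""),
         rint = rint)
  }
  A <- mk_species("a"); B <- mk_species("b")
  sim$genes_a <- A$genes
  sim$genes_b <- B$genes
  sim$regions <- data.frame(
    region_id = vapply(lay, function(l) l$region_id, ""),
    chrom_a = A$chrom, start_a = as.integer(A$rint[, 1L]),
    end_a = as.integer(A$rint[, 2L]),
    chrom_b = B$chrom, start_b = as.integer(B$rint[, 1L]),
    end_b = as.integer(B$rint[, 2L]),
    stringsAsFactors = FALSE)
  sim
}

# positions of a set of gene ids in an id vector
.pos_of <- function(ids, vec) match(ids, vec)

#' Plant micro-rearrangements into a synthetic genome pair
#'
#' Mutates species B of a \code{\link{simulate_genome_pair}} dataset.
#' Internal translocations relocate a run of at most \code{max_block_genes}
#' B-genes within their region (always jumping over more genes than the run
#' contains); with probability \code{p_inversion} an event is instead an
#' inversion: the run is reversed in place with strands flipped (a
#' single-gene inversion is relocated with its strand flipped, the only
#' observable form). External events relocate a run into a different region.
#' With probability \code{p_duplication} per region a duplication is planted:
#' either an extra B-copy forming a one-to-many group, or an extra A-gene
#' forming an asymmetric 3-vs-2 many-to-many group; identities are
#' controlled so the intended survivor/loser is known. All event footprints
#' are pairwise disjoint with a one-gene buffer.
#'
#' @param sim A \code{synteny_sim}.
#' @param n_internal,n_external Numbers of internal/external events.
#' @param max_block_genes Largest run length (default 5).
#' @param p_inversion Probability an internal event is an inversion.
#' @param p_duplication Per-region probability of one duplication event.
#' @param seed Optional integer seed.
#' @return The mutated \code{synteny_sim}; \code{$truth$events} lists each
#'   planted event (kind, member pairs, regions), \code{$truth$losers} the
#'   intended duplication losers.
#' @export
plant_rearrangements <- function(sim, n_internal = 10L, n_external = 2L,
                                 max_block_genes = 5L, p_inversion = 0.5,
                                 p_duplication = 0, seed = NULL) {
  stopifnot(inherits(sim, "synteny_sim"))
  if (!is.null(seed)) set.seed(seed)
  lay <- sim$layout
  nreg <- length(lay)
  # footprints on the original (pre-planting) pair index space, per region
  used <- lapply(lay, function(l) logical(length(l$a_ids)))
  mark <- function(r, pos) {
    pos <- pos[pos >= 1L & pos <= length(used[[r]])]
    used[[r]][pos] <<- TRUE
  }
  free <- function(r, pos) {
    pos_in <- pos[pos >= 1L & pos <= length(used[[r]])]
    length(pos_in) && !any(used[[r]][pos_in])
  }

  plan_internal <- list()
  plan_external <- list()
  plan_dup <- list()

  # ---- plan internal events -------------------------------------------------
  for (ev in seq_len(n_internal)) {
    kind <- if (stats::runif(1) < p_inversion) "inversion" else "translocation"
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      r <- sample.int(nreg, 1L)
      m <- length(lay[[r]]$a_ids)
      len <- sample.int(max_block_genes, 1L)
      if (len >= floor(m / 2)) next
      s <- sample.int(m - len + 1L, 1L)
      e <- s + len - 1L
      in_place <- kind == "inversion" && len >= 2L
      if (in_place) {
        if (!free(r, (s - 1L):(e + 1L))) next
        plan_internal[[length(plan_internal) + 1L]] <-
          list(kind = kind, region = r, s = s, e = e, t = NA_integer_)
        mark(r, (s - 1L):(e + 1L))
        placed <- TRUE
        break
      }
      # relocation: insertion slot after position t, jumping > len genes
      t_cand <- integer(0)
      if (s - len - 2L >= 0L) t_cand <- c(t_cand, 0L:(s - len - 2L))
      if (e + len + 1L <= m) t_cand <- c(t_cand, (e + len + 1L):m)
      if (!length(t_cand)) next
      t <- t_cand[sample.int(length(t_cand), 1L)]
      # need slot genes t and t+1 untouched (t = 0 means region start)
      slot <- unique(pmax(1L, c(t, t + 1L)))
      if (!free(r, (s - 1L):(e + 1L)) || !free(r, slot)) next
      plan_internal[[length(plan_internal) + 1L]] <-
        list(kind = kind, region = r, s = s, e = e, t = t)
      mark(r, (s - 1L):(e + 1L)); mark(r, slot)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("plant_rearrangements: no room for internal event %d (capacity exhausted)",
                   ev), call. = FALSE)
  }

  # ---- plan external events -------------------------------------------------
  for (ev in seq_len(n_external)) {
    if (nreg < 2L)
      stop("plant_rearrangements: external events need at least two regions",
           call. = FALSE)
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      r1 <- sample.int(nreg, 1L)
      r2 <- sample.int(nreg, 1L)
      if (r1 == r2) next
      m1 <- length(lay[[r1]]$a_ids); m2 <- length(lay[[r2]]$a_ids)
      len <- sample.int(max_block_genes, 1L)
      if (len >= m1 - 2L) next
      s <- sample.int(m1 - len + 1L, 1L)
      e <- s + len - 1L
      t2 <- sample.int(m2 - 1L, 1L)   # insert after position t2 in r2
      if (!free(r1, (s - 1L):(e + 1L)) || !free(r2, c(t2, t2 + 1L))) next
      plan_external[[length(plan_external) + 1L]] <-
        list(region_from = r1, region_to = r2, s = s, e = e, t2 = t2)
      mark(r1, (s - 1L):(e + 1L)); mark(r2, c(t2, t2 + 1L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("plant_rearrangements: no room for external event %d (capacity exhausted)",
                   ev), call. = FALSE)
  }

  # ---- plan duplications ----------------------------------------------------
  if (p_duplication > 0) {
    for (r in seq_len(nreg)) {
      if (stats::runif(1) >= p_duplication) next
      type <- sample(c("one_to_many", "many_to_many"), 1L)
      m <- length(lay[[r]]$a_ids)
      for (attempt in seq_len(200L)) {
        p <- sample.int(m - 2L, 1L) + 1L    # avoid region edges
        span <- if (type == "one_to_many") (p - 1L):(p + 1L)
                else (p - 1L):(p + 2L)
        if (!free(r, span)) next
        plan_dup[[length(plan_dup) + 1L]] <- list(type = type, region = r,
                                                  p = p)
        mark(r, span)
        break
      }
    }
  }

  # ---- apply: relocations on the current B orders, anchored by gene id ----
  # runs and anchors are taken from the pre-planting (original) index space;
  # footprint disjointness guarantees the anchor genes and run contiguity
  # survive earlier applications, so all edits are gene-id anchored
  orig <- lapply(lay, function(l) list(a = l$a_ids, b = l$b_ids))
  truth <- sim$truth
  orth <- sim$orthologs
  for (pl in plan_internal) {
    l <- lay[[pl$region]]
    run_a <- orig[[pl$region]]$a[pl$s:pl$e]
    run_b <- orig[[pl$region]]$b[pl$s:pl$e]
    if (pl$kind == "inversion" && length(run_b) >= 2L) {
      pos <- .pos_of(run_b, lay[[pl$region]]$b_ids)
      lay[[pl$region]]$b_ids[pos] <- rev(run_b)
      lay[[pl$region]]$b_len[pos] <- rev(lay[[pl$region]]$b_len[pos])
      flip <- lay[[pl$region]]$b_strand[pos]
      lay[[pl$region]]$b_strand[pos] <-
        rev(ifelse(flip == "+", "-", "+"))
    } else {
      anchor <- if (pl$t == 0L) NA_character_ else orig[[pl$region]]$b[pl$t]
      cur <- lay[[pl$region]]
      keep <- !(cur$b_ids %in% run_b)
      ids2 <- cur$b_ids[keep]; len2 <- cur$b_len[keep]
      str2 <- cur$b_strand[keep]
      at <- if (is.na(anchor)) 0L else match(anchor, ids2)
      run_len <- cur$b_len[match(run_b, cur$b_ids)]
      run_str <- cur$b_strand[match(run_b, cur$b_ids)]
      if (pl$kind == "inversion") {  # single gene, relocated + strand flip
        run_str <- ifelse(run_str == "+", "-", "+")
      }
      ins <- function(v, x, at) append(v, x, after = at)
      lay[[pl$region]]$b_ids <- ins(ids2, run_b, at)
      lay[[pl$region]]$b_len <- ins(len2, run_len, at)
      lay[[pl$region]]$b_strand <- ins(str2, run_str, at)
    }
    truth$events[[length(truth$events) + 1L]] <- list(
      kind = if (pl$kind == "inversion") "inversion"
             else "internal_translocation",
      region = l$region_id, gene_a = run_a, gene_b = run_b)
  }

  for (pl in plan_external) {
    l1 <- lay[[pl$region_from]]
    run_a <- orig[[pl$region_from]]$a[pl$s:pl$e]
    run_b <- orig[[pl$region_from]]$b[pl$s:pl$e]
    keep <- !(lay[[pl$region_from]]$b_ids %in% run_b)
    pos <- .pos_of(run_b, lay[[pl$region_from]]$b_ids)
    run_len <- lay[[pl$region_from]]$b_len[pos]
    run_str <- lay[[pl$region_from]]$b_strand[pos]
    lay[[pl$region_from]]$b_ids <- lay[[pl$region_from]]$b_ids[keep]
    lay[[pl$region_from]]$b_len <- lay[[pl$region_from]]$b_len[keep]
    lay[[pl$region_from]]$b_strand <- lay[[pl$region_from]]$b_strand[keep]
    anchor <- orig[[pl$region_to]]$b[pl$t2]
    at <- match(anchor, lay[[pl$region_to]]$b_ids)
    lay[[pl$region_to]]$b_ids <-
      append(lay[[pl$region_to]]$b_ids, run_b, after = at)
    lay[[pl$region_to]]$b_len <-
      append(lay[[pl$region_to]]$b_len, run_len, after = at)
    lay[[pl$region_to]]$b_strand <-
      append(lay[[pl$region_to]]$b_strand, run_str, after = at)
    truth$events[[length(truth$events) + 1L]] <- list(
      kind = "external_translocation",
      region_from = l1$region_id, region_to = lay[[pl$region_to]]$region_id,
      gene_a = run_a, gene_b = run_b)
  }

  for (pl in plan_dup) {
    l <- lay[[pl$region]]
    p <- pl$p
    high <- function(n) stats::runif(n, 85, 100)
    low <- function(n) stats::runif(n, 60, 80)
    if (pl$type == "one_to_many") {
      a0 <- orig[[pl$region]]$a[p]
      b0 <- truth$pairs$gene_b[match(a0, truth$pairs$gene_a)]
      dup_id <- sprintf("gB_%03d_dup%03d", pl$region, p)
      at <- match(b0, lay[[pl$region]]$b_ids)
      lay[[pl$region]]$b_ids <- append(lay[[pl$region]]$b_ids, dup_id,
                                       after = at)
      lay[[pl$region]]$b_len <- append(lay[[pl$region]]$b_len,
                                       .draw_lengths(1L, 44300), after = at)
      lay[[pl$region]]$b_strand <- append(lay[[pl$region]]$b_strand,
                                          l$a_strand[p], after = at)
      hi <- high(1L)
      orth$identity_ab[orth$gene_a == a0 & orth$gene_b == b0] <- hi
      orth$identity_ba[orth$gene_a == a0 & orth$gene_b == b0] <- hi
      lo <- low(1L)
      orth <- rbind(orth, data.frame(gene_a = a0, gene_b = dup_id,
                                     identity_ab = lo, identity_ba = lo,
                                     stringsAsFactors = FALSE))
      truth$losers <- rbind(truth$losers,
                            data.frame(gene_id = dup_id, species = "B",
                                       survivor = b0,
                                       stringsAsFactors = FALSE))
    } else {
      a1 <- orig[[pl$region]]$a[p]; a2 <- orig[[pl$region]]$a[p + 1L]
      b1 <- truth$pairs$gene_b[match(a1, truth$pairs$gene_a)]
      b2 <- truth$pairs$gene_b[match(a2, truth$pairs$gene_a)]
      dup_id <- sprintf("gA_%03d_dup%03d", pl$region, p)
      at <- match(a2, lay[[pl$region]]$a_ids)
      lay[[pl$region]]$a_ids <- append(lay[[pl$region]]$a_ids, dup_id,
                                       after = at)
      lay[[pl$region]]$a_len <- append(lay[[pl$region]]$a_len,
                                       .draw_lengths(1L, 59800), after = at)
      lay[[pl$region]]$a_strand <- append(lay[[pl$region]]$a_strand,
                                          l$a_strand[p], after = at)
      for (bb in c(b1, b2)) {
        aa <- if (bb == b1) a1 else a2
        hi <- high(1L)
        orth$identity_ab[orth$gene_a == aa & orth$gene_b == bb] <- hi
        orth$identity_ba[orth$gene_a == aa & orth$gene_b == bb] <- hi
      }
      lo <- low(2L)
      orth <- rbind(orth,
                    data.frame(gene_a = dup_id, gene_b = c(b1, b2),
                               identity_ab = lo, identity_ba = lo,
                               stringsAsFactors = FALSE))
      truth$losers <- rbind(truth$losers,
                            data.frame(gene_id = dup_id, species = "A",
                                       survivor = NA_character_,
                                       stringsAsFactors = FALSE))
    }
  }

  sim$layout <- lay
  sim$orthologs <- orth
  sim$truth <- truth
  .materialize(sim)
}

#' @export
print.synteny_sim <- function(x, ...) {
  cat(sprintf("Synthetic genome pair: %d regions, %d + %d genes, %d links\n",
              nrow(x$regions), nrow(x$genes_a), nrow(x$genes_b),
              nrow(x$orthologs)))
  if (length(x$truth$events)) {
    kinds <- table(vapply(x$truth$events, function(e) e$kind, ""))
    cat("  planted events:",
        paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  }
  if (nrow(x$truth$losers))
    cat(sprintf("  planted duplications: %d intended loser(s)\n",
                nrow(x$truth$losers)))
  invisible(x)
}

#' Evaluate recovery of planted events by a synteny map
#'
#' An internal event counts as recovered iff the map contains an internal
#' region of the same rearrangement kind whose member pair set equals the
#' planted one; an external event iff an external region carries exactly the
#' planted pairs.
#'
#' @param map A \code{\link{synteny_map}} computed on the planted dataset.
#' @param truth The \code{$truth} of a \code{synteny_sim} (or the sim
#'   itself).
#' @return Data.frame with one row per planted event: \code{kind},
#'   \code{recovered}; attribute \code{n_extra_blocks} counts derived
#'   regions not matching any planted event.
#' @export
evaluate_recovery <- function(map, truth) {
  if (inherits(truth, "synteny_sim")) truth <- truth$truth
  key <- function(ga, gb) paste(sort(paste(ga, gb, sep = "|")),
                                collapse = ";")
  det <- vapply(map$blocks, function(b) key(b$gene_a, b$gene_b), "")
  det_kind <- vapply(map$blocks, function(b)
    if (b$type == "external") "external_translocation"
    else if (b$kind == "inversion") "inversion"
    else "internal_translocation", "")
  if (!length(truth$events)) {
    out <- data.frame(kind = character(0), recovered = logical(0))
    attr(out, "n_extra_blocks") <- length(det)
    return(out)
  }
  want <- vapply(truth$events, function(e) key(e$gene_a, e$gene_b), "")
  want_kind <- vapply(truth$events, function(e) e$kind, "")
  hit <- mapply(function(w, wk) any(det == w & det_kind == wk),
                want, want_kind)
  out <- data.frame(kind = want_kind, recovered = unname(hit),
                    stringsAsFactors = FALSE)
  attr(out, "n_extra_blocks") <- sum(!det %in% want)
  out
}

#' Generate matched feature tracks for a synthetic genome pair
#'
#' Emits one weighted BED element spanning each gene. For each intended
#' ortholog pair the two weights mix a shared latent signal with independent
#' noise: \code{w = 10 + sqrt(c) L + sqrt(1 - c) e} with
#' \code{c = conservation}, so at \code{c = 1} the two species' per-gene
#' values are identical and at \code{c = 0} they are independent standard
#' normals (shifted), giving the analytic mean absolute Z-difference
#' 2/sqrt(pi). Genes outside the intended pairing get independent weights.
#'
#' @param sim A \code{synteny_sim}.
#' @param conservation Mixing level in [0, 1].
#' @param seed Optional integer seed.
#' @return List with \code{track_a}, \code{track_b} (weighted BED
#'   data.frames) and \code{chrom_sizes}.
#' @export
generate_track_pair <- function(sim, conservation, seed = NULL) {
  stopifnot(conservation >= 0, conservation <= 1)
  if (!is.null(seed)) set.seed(seed)
  ga <- sim$genes_a; gb <- sim$genes_b
  pr <- sim$truth$pairs
  L <- stats::rnorm(nrow(pr))
  ea <- stats::rnorm(nrow(pr)); eb <- stats::rnorm(nrow(pr))
  sc <- sqrt(conservation); sn <- sqrt(1 - conservation)
  w_pair_a <- 10 + sc * L + sn * ea
  w_pair_b <- 10 + sc * L + sn * eb
  wa <- stats::setNames(stats::rnorm(nrow(ga), mean = 10), ga$gene_id)
  wb <- stats::setNames(stats::rnorm(nrow(gb), mean = 10), gb$gene_id)
  wa[pr$gene_a] <- w_pair_a
  wb[pr$gene_b] <- w_pair_b
  mk <- function(genes, w) {
    tr <- data.frame(chromosome = genes$chromosome,
                     start = genes$start - 1L, end = genes$end,
                     weight = unname(w[genes$gene_id]),
                     stringsAsFactors = FALSE)
    attr(tr, "has_weights") <- TRUE
    tr
  }
  sizes_a <- tapply(ga$end, ga$chromosome, max) + 10000
  sizes_b <- tapply(gb$end, gb$chromosome, max) + 10000
  list(track_a = mk(ga, wa), track_b = mk(gb, wb),
       chrom_sizes = c(stats::setNames(as.numeric(sizes_a), names(sizes_a)),
                       stats::setNames(as.numeric(sizes_b), names(sizes_b))))
}

#' Random nucleotide sequences for the regions of a synthetic dataset
#'
#' One random DNA record per region and species, named
#' \code{<region_id>_A} / \code{<region_id>_B}; a cheap stand-in for region
#' sequences when exercising the k-mer distance.
#'
#' @param sim A \code{synteny_sim}.
#' @param bp Sequence length per record (default 5000).
#' @param seed Optional integer seed.
#' @return Named character vector of sequences.
#' @export
simulate_region_sequences <- function(sim, bp = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- as.vector(t(outer(sim$regions$region_id, c("_A", "_B"), paste0)))
  seqs <- vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T"), bp, replace = TRUE), collapse = ""),
    "")
  seqs
}

#' Write a synthetic dataset as a fixture directory
#'
#' Writes the standard TSV inputs (genes_a.tsv, genes_b.tsv, regions.tsv,
#' orthologs.tsv) and, optionally, matched BED tracks with a chromosome-sizes
#' table and a regions FASTA.
#'
#' @param sim A \code{synteny_sim}.
#' @param dir Output directory (created if needed).
#' @param tracks Optional result of \code{\link{generate_track_pair}}.
#' @param sequences Optional named sequence vector from
#'   \code{\link{simulate_region_sequences}}.
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(sim, dir, tracks = NULL, sequences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genes_a, file.path(dir, "genes_a.tsv"))
  write_gene_table(sim$genes_b, file.path(dir, "genes_b.tsv"))
  write_region_table(sim$regions, file.path(dir, "regions.tsv"))
  write_ortholog_table(sim$orthologs, file.path(dir, "orthologs.tsv"))
  if (!is.null(tracks)) {
    write_bed(tracks$track_a, file.path(dir, "track_a.bed"))
    write_bed(tracks$track_b, file.path(dir, "track_b.bed"))
    utils::write.table(
      data.frame(names(tracks$chrom_sizes),
                 format(tracks$chrom_sizes, scientific = FALSE,
                        trim = TRUE)),
      file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(sequences)) {
    con <- file(file.path(dir, "regions.fasta"), "w")
    writeLines(paste0(">", names(sequences), "\n", sequences), con)
    close(con)
  }
  invisible(dir)
}
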