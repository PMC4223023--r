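# Tabular conventions:
#  * gene / region / ortholog TSVs are 1-based, inclusive (ENSEMBL-style);
#  * BED is 0-based, half-open;
#  * '#'-prefixed lines are comments and are skipped everywhere.
# All internal arithmetic works on the 1-based inclusive representation and
# converts BED at the I/O boundary.

.read_tsv <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      quote = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop(sprintf("cannot parse %s file '%s': %s",
                                     what, path, conditionMessage(e)),
                             call. = FALSE))
  names(df) <- tolower(names(df))
  df
}

.need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df[cols]
}

# line numbers in error messages count data rows (header = row 0)
.bad_rows <- function(ok, path, why) {
  if (all(ok)) return(invisible(NULL))
  stop(sprintf("file '%s': %s at data row(s) %s", path, why,
               paste(utils::head(which(!ok), 5L), collapse = ", ")),
       call. = FALSE)
}

#' Read a per-species gene table
#'
#' Parses a tab-separated gene table with header columns
#' \code{gene_id}, \code{chromosome}, \code{start}, \code{end}, \code{strand}
#' (1-based inclusive coordinates, strand \code{+}/\code{-}).
#'
#' @param path Path to the TSV file.
#' @param species Species tag, \code{"A"} or \code{"B"}; stored as an
#'   attribute on the returned table.
#' @return A \code{data.frame} with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{strand}.
#' @export
read_gene_table <- function(path, species = c("A", "B")) {
  species <- match.arg(species)
  df <- .need_cols(.read_tsv(path, "gene table"),
                   c("gene_id", "chromosome", "start", "end", "strand"), path)
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$strand <- as.character(df$strand)
  .bad_rows(!is.na(df$start) & !is.na(df$end), path, "non-numeric coordinate")
  .bad_rows(df$strand %in% c("+", "-"), path, "strand not '+'/'-'")
  .bad_rows(df$start <= df$end, path, "start > end")
  validate_genes(df)
  attr(df, "species") <- species
  df
}

#' @rdname read_gene_table
#' @param genes A gene table as returned by \code{read_gene_table}.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[c("gene_id", "chromosome", "start", "end", "strand")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene table
#'
#' Checks start <= end, strand values and uniqueness of gene ids.
#' @param genes Gene table (data.frame).
#' @return The table, invisibly; errors on violation.
#' @export
validate_genes <- function(genes) {
  if (any(genes$start > genes$end))
    stop("gene table: start > end for gene(s) ",
         paste(utils::head(genes$gene_id[genes$start > genes$end], 5L),
               collapse = ", "), call. = FALSE)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("gene table: duplicated gene id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  invisible(genes)
}

#' Read a syntenic-region pair table
#'
#' Header columns: \code{region_id}, \code{chrom_A}, \code{start_A},
#' \code{end_A}, \code{chrom_B}, \code{start_B}, \code{end_B} (1-based
#' inclusive). Within one species, regions on the same chromosome must not
#' overlap.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} with columns \code{region_id}, \code{chrom_a},
#'   \code{start_a}, \code{end_a}, \code{chrom_b}, \code{start_b},
#'   \code{end_b}.
#' @export
read_region_table <- function(path) {
  df <- .need_cols(.read_tsv(path, "region table"),
                   c("region_id", "chrom_a", "start_a", "end_a",
                     "chrom_b", "start_b", "end_b"), path)
  df$region_id <- as.character(df$region_id)
  for (cc in c("start_a", "end_a", "start_b", "end_b"))
    df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  .bad_rows(!is.na(df$start_a) & !is.na(df$end_a) &
              !is.na(df$start_b) & !is.na(df$end_b), path,
            "non-numeric coordinate")
  .bad_rows(df$start_a <= df$end_a & df$start_b <= df$end_b, path,
            "start > end")
  validate_regions(df)
  df
}

#' @rdname read_region_table
#' @param regions Region table as returned by \code{read_region_table}.
#' @export
write_region_table <- function(regions, path) {
  out <- regions[c("region_id", "chrom_a", "start_a", "end_a",
                   "chrom_b", "start_b", "end_b")]
  names(out) <- c("region_id", "chrom_A", "start_A", "end_A",
                  "chrom_B", "start_B", "end_B")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.overlap_pairs <- function(id, chrom, start, end) {
  bad <- character(0)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- order(start[i])
    i <- i[o]
    if (length(i) > 1L) {
      hit <- which(start[i][-1L] <= end[i][-length(i)])
      if (length(hit))
        bad <- c(bad, paste(id[i][hit], id[i][hit + 1L], sep = "/"))
    }
  }
  bad
}

#' Validate a region table
#'
#' Errors if region ids are duplicated or if two regions overlap on the same
#' chromosome within either species.
#' @param regions Region table.
#' @return The table, invisibly.
#' @export
validate_regions <- function(regions) {
  dup <- unique(regions$region_id[duplicated(regions$region_id)])
  if (length(dup))
    stop("region table: duplicated region id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  bad_a <- .overlap_pairs(regions$region_id, regions$chrom_a,
                          regions$start_a, regions$end_a)
  bad_b <- .overlap_pairs(regions$region_id, regions$chrom_b,
                          regions$start_b, regions$end_b)
  if (length(bad_a) || length(bad_b))
    stop("region table: overlapping regions ",
         if (length(bad_a)) paste0("in species A: ",
                                   paste(bad_a, collapse = ", ")) else "",
         if (length(bad_a) && length(bad_b)) "; " else "",
         if (length(bad_b)) paste0("in species B: ",
                                   paste(bad_b, collapse = ", ")) else "",
         call. = FALSE)
  invisible(regions)
}

#' Read a pairwise ortholog table
#'
#' Header columns: \code{gene_A}, \code{gene_B}, \code{identity_AB},
#' \code{identity_BA} (percent identities in [0, 100]). Duplicated
#' (gene_A, gene_B) rows are collapsed keeping the maximum identity per
#' direction, with a warning.
#'
#' @param path Path to the TSV file.
#' @param genes_a,genes_b Optional gene tables; when given, links naming
#'   unknown gene ids are a validation error.
#' @return A \code{data.frame} with columns \code{gene_a}, \code{gene_b},
#'   \code{identity_ab}, \code{identity_ba}.
#' @export
read_ortholog_table <- function(path, genes_a = NULL, genes_b = NULL) {
  df <- .need_cols(.read_tsv(path, "ortholog table"),
                   c("gene_a", "gene_b", "identity_ab", "identity_ba"), path)
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$identity_ab <- suppressWarnings(as.numeric(df$identity_ab))
  df$identity_ba <- suppressWarnings(as.numeric(df$identity_ba))
  .bad_rows(!is.na(df$identity_ab) & !is.na(df$identity_ba), path,
            "non-numeric identity")
  .bad_rows(df$identity_ab >= 0 & df$identity_ab <= 100 &
              df$identity_ba >= 0 & df$identity_ba <= 100, path,
            "identity outside [0,100]")
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("ortholog table '%s': %d duplicated link row(s) merged (max identity kept)",
                    path, sum(duplicated(key))), call. = FALSE)
    df <- do.call(rbind, lapply(split(df, key), function(d)
      data.frame(gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
                 identity_ab = max(d$identity_ab),
                 identity_ba = max(d$identity_ba),
                 stringsAsFactors = FALSE)))
    df <- df[order(df$gene_a, df$gene_b), ]
    rownames(df) <- NULL
  }
  if (!is.null(genes_a)) {
    unk <- setdiff(df$gene_a, genes_a$gene_id)
    if (length(unk))
      stop("ortholog table: unknown species-A gene id(s): ",
           paste(utils::head(unk, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(genes_b)) {
    unk <- setdiff(df$gene_b, genes_b$gene_id)
    if (length(unk))
      stop("ortholog table: unknown species-B gene id(s): ",
           paste(utils::head(unk, 5L), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_ortholog_table
#' @param orthologs Ortholog table.
#' @export
write_ortholog_table <- function(orthologs, path) {
  out <- orthologs[c("gene_a", "gene_b", "identity_ab", "identity_ba")]
  names(out) <- c("gene_A", "gene_B", "identity_AB", "identity_BA")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign genes to syntenic regions by midpoint
#'
#' A gene belongs to a region iff its midpoint lies inside the region's
#' interval on the matching chromosome. Region intervals within a species do
#' not overlap, so every gene has at most one home; genes hitting no region
#' are returned as unassigned ("syntenic-block-free"). Within each region,
#' genes are ordered by start coordinate (ties: end, then id).
#'
#' @param genes Gene table for one species.
#' @param regions Region table.
#' @param species \code{"A"} or \code{"B"}: which region interval to use.
#' @return A list with \code{assigned} (data.frame \code{gene_id},
#'   \code{region_id}, \code{rank} giving the gene's genomic rank within its
#'   region) and \code{unassigned} (character vector of gene ids).
#' @export
assign_genes_to_regions <- function(genes, regions, species = c("A", "B")) {
  species <- match.arg(species)
  if (species == "A") {
    rchrom <- regions$chrom_a; rstart <- regions$start_a; rend <- regions$end_a
  } else {
    rchrom <- regions$chrom_b; rstart <- regions$start_b; rend <- regions$end_b
  }
  mid <- floor((as.numeric(genes$start) + as.numeric(genes$end)) / 2)
  region_of <- rep(NA_character_, nrow(genes))
  for (ch in unique(rchrom)) {
    gi <- which(genes$chromosome == ch)
    if (!length(gi)) next
    ri <- which(rchrom == ch)
    o <- order(rstart[ri])
    ri <- ri[o]
    # regions are non-overlapping within a species, so the midpoint falls in
    # at most one interval
    k <- findInterval(mid[gi], rstart[ri])
    inside <- k >= 1L & mid[gi] <= rend[ri][pmax(k, 1L)]
    region_of[gi[inside]] <- regions$region_id[ri[k[inside]]]
  }
  keep <- !is.na(region_of)
  assigned <- data.frame(gene_id = genes$gene_id[keep],
                         region_id = region_of[keep],
                         stringsAsFactors = FALSE)
  o <- order(assigned$region_id, genes$start[keep], genes$end[keep],
             assigned$gene_id)
  assigned <- assigned[o, ]
  assigned$rank <- stats::ave(seq_len(nrow(assigned)), assigned$region_id,
                              FUN = seq_along)
  rownames(assigned) <- NULL
  list(assigned = assigned, unassigned = genes$gene_id[!keep])
}

#' Read a BED track
#'
#' Accepts BED3, or BED4 where the fourth column is a numeric signal weight
#' on every row (0-based, half-open coordinates). Mixing weighted and
#' unweighted rows is an error.
#'
#' @param path Path to the BED file.
#' @return A \code{data.frame} with columns \code{chromosome}, \code{start},
#'   \code{end} (0-based half-open) and, if present, \code{weight}; attribute
#'   \code{has_weights} records the dialect.
#' @export
read_bed <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    tr <- data.frame(chromosome = character(0), start = integer(0),
                     end = integer(0))
    attr(tr, "has_weights") <- FALSE
    return(tr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("BED file '%s': fewer than 3 columns at line(s) %s", path,
                 paste(utils::head(which(nf < 3L), 5L), collapse = ", ")),
         call. = FALSE)
  has_w <- nf >= 4L
  if (any(has_w) && !all(has_w))
    stop(sprintf("BED file '%s': mixed weighted and unweighted rows", path),
         call. = FALSE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  .bad_rows(!is.na(start) & !is.na(end), path, "non-numeric coordinate")
  .bad_rows(start < end, path, "start >= end")
  tr <- data.frame(chromosome = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    .bad_rows(!is.na(w), path, "non-numeric weight in column 4")
    tr$weight <- w
    attr(tr, "has_weights") <- TRUE
  } else {
    attr(tr, "has_weights") <- FALSE
  }
  tr
}

#' @rdname read_bed
#' @param track Feature track as returned by \code{read_bed}.
#' @export
write_bed <- function(track, path) {
  cols <- c("chromosome", "start", "end",
            if (isTRUE(attr(track, "has_weights"))) "weight")
  utils::write.table(track[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (no header): chromosome name, length in bp.
#' @param path Path to the file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path))
    stop("chromosome-sizes file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("chromosome-sizes file must have two columns (name, length)",
         call. = FALSE)
  sizes <- as.numeric(df[[2L]])
  if (anyNA(sizes) || any(sizes <= 0))
    stop("chromosome-sizes file: lengths must be positive numbers",
         call. = FALSE)
  stats::setNames(sizes, as.character(df[[1L]]))
}

.provenance_header <- function(config = NULL) {
  hdr <- paste0("# microsynteny ",
                as.character(utils::packageVersion("microsynteny")))
  if (!is.null(config) && length(config))
    hdr <- c(hdr, paste0("# ", names(config), "=",
                         vapply(config, function(x) paste(x, collapse = ","),
                                "")))
  hdr
}

.write_table_with_header <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write refined syntenic regions
#'
#' Output file (a): one row per refined region with columns
#' \code{region_id}, \code{parent_region_id} (\code{.} for none),
#' \code{type} (original/internal/external), \code{rearrangement}
#' (none/translocation/inversion) and the region interval in both species.
#' Rows are sorted by region id then species-A coordinate; output is
#' byte-stable for identical input.
#'
#' @param map A \code{\link{synteny_map}} object (or its \code{$regions}
#'   data.frame).
#' @param path Output path.
#' @param config Optional named list echoed as '#' provenance comments.
#' @export
write_refined_regions <- function(map, path, config = NULL) {
  regions <- if (inherits(map, "synteny_map")) map$regions else map
  out <- regions[c("region_id", "parent_region_id", "type", "rearrangement",
                   "chrom_a", "start_a", "end_a",
                   "chrom_b", "start_b", "end_b")]
  out <- out[order(out$region_id, out$start_a), ]
  out$parent_region_id[is.na(out$parent_region_id)] <- "."
  .write_table_with_header(out, path, config)
}

#' Write the syntenic ortholog map
#'
#' Output file (b): one row per resolved ortholog pair with columns
#' \code{region_id}, \code{gene_A}, \code{gene_B}, \code{provenance}
#' (direct / one_to_many_reduced / order_split / external), sorted by region
#' id then species-A coordinate.
#'
#' @inheritParams write_refined_regions
#' @export
write_ortholog_map <- function(map, path, config = NULL) {
  pairs <- if (inherits(map, "synteny_map")) map$pairs else map
  out <- pairs[order(pairs$region_id, pairs$ord), ]
  out <- out[c("region_id", "gene_a", "gene_b", "provenance")]
  names(out) <- c("region_id", "gene_A", "gene_B", "provenance")
  .write_table_with_header(out, path, config)
}

#' Read back refined-region / ortholog-map output files
#'
#' Inverses of \code{\link{write_refined_regions}} and
#' \code{\link{write_ortholog_map}}.
#' @param path File written by the corresponding writer.
#' @return A data.frame.
#' @export
read_refined_regions <- function(path) {
  df <- .read_tsv(path, "refined regions")
  df$parent_region_id[df$parent_region_id == "."] <- NA_character_
  df
}

#' @rdname read_refined_regions
#' @export
read_ortholog_map <- function(path) {
  .read_tsv(path, "ortholog map")
}
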