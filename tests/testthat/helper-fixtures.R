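# Shared fixture builders and independent oracles for the test suite.

# gene table from parallel vectors
mk_genes <- function(ids, starts, ends, chrom = "chr1", strand = "+") {
  data.frame(gene_id = ids, chromosome = chrom,
             start = as.integer(starts), end = as.integer(ends),
             strand = rep_len(strand, length(ids)), stringsAsFactors = FALSE)
}

mk_links <- function(gene_a, gene_b, ident = 90) {
  data.frame(gene_a = gene_a, gene_b = gene_b,
             identity_ab = rep_len(ident, length(gene_a)),
             identity_ba = rep_len(ident, length(gene_a)),
             stringsAsFactors = FALSE)
}

# a ranked region realizing permutation pi, built through the public API
perm_region_api <- function(pi, strand_a = "+", strand_b = "+") {
  n <- length(pi)
  ga <- mk_genes(sprintf("a%02d", 1:n), (1:n) * 1000L, (1:n) * 1000L + 500L,
                 strand = strand_a)
  gb <- mk_genes(sprintf("b%02d", pi), pi * 1000L, pi * 1000L + 500L,
                 strand = strand_b)
  pairs <- data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id,
                      provenance = "direct", stringsAsFactors = FALSE)
  rank_region(pairs, ga, gb)
}

# fast direct construction of the same object (used in exhaustive sweeps);
# equivalence with perm_region_api is asserted in the rearrangement tests
perm_region <- function(pi, strand_a = "+", strand_b = "+") {
  n <- length(pi)
  pairs <- data.frame(
    gene_a = sprintf("a%02d", 1:n), gene_b = sprintf("b%02d", pi),
    provenance = "direct",
    start_a = (1:n) * 1000L, end_a = (1:n) * 1000L + 500L,
    strand_a = rep_len(strand_a, n),
    start_b = pi * 1000L, end_b = pi * 1000L + 500L,
    strand_b = rep_len(strand_b, n),
    stringsAsFactors = FALSE)
  out <- list(pairs = pairs, pi = as.integer(pi), n = n)
  class(out) <- "ranked_region"
  out
}

# all permutations of 1..n, one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

# independent naive k-mer dictionary counter
naive_kmer <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(integer(0))
  w <- substring(s, 1:(n - k + 1L), k:n)
  w <- w[!grepl("[^ACGT]", w)]
  tb <- table(w)
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

naive_kmer_dist <- function(s1, s2, k) {
  c1 <- naive_kmer(s1, k); c2 <- naive_kmer(s2, k)
  words <- union(names(c1), names(c2))
  v1 <- ifelse(words %in% names(c1), c1[words], 0L)
  v2 <- ifelse(words %in% names(c2), c2[words], 0L)
  sum(abs(as.numeric(v1) - as.numeric(v2)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# base-by-base per-gene track value
naive_gene_value <- function(gene, track) {
  weighted <- isTRUE(attr(track, "has_weights"))
  bases <- gene$start:gene$end
  el <- track[track$chromosome == gene$chromosome, , drop = FALSE]
  if (weighted) {
    acc <- numeric(length(bases))
    for (i in seq_len(nrow(el)))
      acc <- acc + el$weight[i] * (bases >= el$start[i] + 1L &
                                     bases <= el$end[i])
    mean(acc)
  } else {
    cov <- logical(length(bases))
    for (i in seq_len(nrow(el)))
      cov <- cov | (bases >= el$start[i] + 1L & bases <= el$end[i])
    mean(cov)
  }
}

# rank-sum normal approximation with tie correction, alternative "less"
ranksum_p_less <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1)))
  stats::pnorm((W - mu) / sqrt(sigma2))
}

# connected components of a bipartite link graph by breadth-first search
cc_oracle <- function(genes_a, genes_b, links) {
  nodes <- c(paste0("A:", genes_a), paste0("B:", genes_b))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(links))) {
    a <- paste0("A:", links$gene_a[i]); b <- paste0("B:", links$gene_b[i])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (v in nodes) {
    if (v %in% seen || is.null(adj[[v]])) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[[`, "", 1L))]
}

# canonical form of a group list for comparison with cc_oracle
groups_canonical <- function(groups) {
  comps <- lapply(groups, function(g)
    sort(c(paste0("A:", g$genes_a), paste0("B:", g$genes_b))))
  comps[order(vapply(comps, `[[`, "", 1L))]
}
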