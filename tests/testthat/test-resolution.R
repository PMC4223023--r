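# Ortholog-group resolution: grouping, one-to-many reduction, symmetry
# trimming, positional splitting, and the per-region pipeline.

test_that("grouping finds bipartite connected components", {
  # three disjoint 1-1 links
  g <- group_orthologs(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                       mk_links(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  expect_length(g, 3L)
  expect_true(all(vapply(g, function(x) x$class, "") == "one_internal"))

  # one-to-many: a1 linked to b1 and b2
  g <- group_orthologs(c("a1"), c("b1", "b2"),
                       mk_links(c("a1", "a1"), c("b1", "b2")))
  expect_length(g, 1L)
  expect_equal(g[[1L]]$class, "many_internal")
  expect_length(g[[1L]]$genes_b, 2L)

  # genes without links are reported separately
  g <- group_orthologs(c("a1", "a2"), c("b1", "b2"),
                       mk_links("a1", "b1"))
  expect_equal(attr(g, "no_ortholog")$a, "a2")
  expect_equal(attr(g, "no_ortholog")$b, "b2")
})

test_that("grouping matches a breadth-first-search oracle on random graphs", {
  set.seed(41)
  for (rep in 1:10) {
    na <- 10L; nb <- 10L
    ga <- sprintf("a%02d", 1:na); gb <- sprintf("b%02d", 1:nb)
    nl <- sample(5:25, 1L)
    links <- unique(mk_links(sample(ga, nl, replace = TRUE),
                             sample(gb, nl, replace = TRUE)))
    got <- group_orthologs(ga, gb, links)
    expect_identical(groups_canonical(got), cc_oracle(ga, gb, links))
  }
})

test_that("one-to-many reduction keeps the highest-identity pair", {
  g <- list(genes_a = "a1", genes_b = c("b1", "b2"),
            links = mk_links(c("a1", "a1"), c("b1", "b2"), c(90, 75)),
            class = "many_internal")
  red <- reduce_one_to_many(g)
  expect_equal(red$pair$gene_a, "a1")
  expect_equal(red$pair$gene_b, "b1")
  expect_equal(red$losers, "b2")
  expect_equal(red$pair$provenance, "one_to_many_reduced")

  # tie on identity: smaller rank distance, then id
  g$links$identity_ab <- c(80, 80); g$links$identity_ba <- c(80, 80)
  red <- reduce_one_to_many(g, rank_a = c(a1 = 2L),
                            rank_b = c(b1 = 5L, b2 = 2L))
  expect_equal(red$pair$gene_b, "b2")   # |2-2| < |2-5|
  red <- reduce_one_to_many(g)          # no ranks: lexicographic id
  expect_equal(red$pair$gene_b, "b1")

  expect_error(reduce_one_to_many(list(genes_a = c("a1", "a2"),
                                       genes_b = c("b1", "b2"),
                                       links = mk_links("a1", "b1"))),
               "not one-to-many")
})

test_that("one-vs-many reduction equals exhaustive argmax on random identities", {
  set.seed(42)
  for (rep in 1:20) {
    nb <- 5L
    idab <- runif(nb, 60, 100); idba <- runif(nb, 60, 100)
    g <- list(genes_a = "a1", genes_b = sprintf("b%d", 1:nb),
              links = data.frame(gene_a = "a1", gene_b = sprintf("b%d", 1:nb),
                                 identity_ab = idab, identity_ba = idba,
                                 stringsAsFactors = FALSE))
    red <- reduce_one_to_many(g)
    expect_equal(red$pair$gene_b,
                 sprintf("b%d", which.max((idab + idba) / 2)))
    expect_length(red$losers, nb - 1L)
  }
})

test_that("symmetry trimming removes exactly |n - m| lowest-identity genes", {
  # 3 A-genes vs 2 B-genes; a3 has the lowest average identity
  links <- data.frame(gene_a = c("a1", "a2", "a3", "a3"),
                      gene_b = c("b1", "b2", "b1", "b2"),
                      identity_ab = c(95, 92, 70, 72),
                      identity_ba = c(95, 92, 70, 72),
                      stringsAsFactors = FALSE)
  g <- list(genes_a = c("a1", "a2", "a3"), genes_b = c("b1", "b2"),
            links = links, class = "many_internal")
  sym <- symmetrize_group(g)
  expect_equal(sym$removed, "a3")
  expect_length(sym$group$genes_a, 2L)

  # already symmetric: identity
  g2 <- list(genes_a = c("a1", "a2"), genes_b = c("b1", "b2"),
             links = links[1:2, ], class = "many_internal")
  sym2 <- symmetrize_group(g2)
  expect_identical(sym2$group, g2)
  expect_length(sym2$removed, 0L)
})

test_that("5-vs-3 trimming equals an exhaustive lowest-average scan", {
  set.seed(43)
  for (rep in 1:10) {
    ga <- sprintf("a%d", 1:5); gb <- sprintf("b%d", 1:3)
    links <- expand.grid(gene_a = ga, gene_b = gb,
                         stringsAsFactors = FALSE)
    links$identity_ab <- runif(nrow(links), 60, 100)
    links$identity_ba <- runif(nrow(links), 60, 100)
    g <- list(genes_a = ga, genes_b = gb, links = links,
              class = "many_internal")
    sym <- symmetrize_group(g)
    expect_length(sym$removed, 2L)   # exactly |5 - 3|
    comb <- (links$identity_ab + links$identity_ba) / 2
    avg <- vapply(ga, function(x) mean(comb[links$gene_a == x]), 0)
    expect_setequal(sym$removed, ga[order(avg)][1:2])
  }
})

test_that("positional splitting pairs i-th with i-th by genomic order", {
  # genomic order is the vector order; links are irrelevant for the pairing
  g <- list(genes_a = c("a3", "a5"), genes_b = c("b2", "b7"),
            links = mk_links(c("a3", "a5"), c("b7", "b2")),
            class = "many_internal")
  sp <- split_symmetric_group(g)
  expect_equal(sp$gene_a, c("a3", "a5"))
  expect_equal(sp$gene_b, c("b2", "b7"))   # order, not link identity
  expect_true(all(sp$provenance == "order_split"))

  sp1 <- split_symmetric_group(list(genes_a = "a1", genes_b = "b1",
                                    links = mk_links("a1", "b1")))
  expect_equal(sp1$provenance, "direct")

  expect_error(split_symmetric_group(list(genes_a = c("a1", "a2"),
                                          genes_b = "b1",
                                          links = mk_links("a1", "b1"))),
               "asymmetric")

  # random symmetric 4x4 equals an independent sort-and-zip
  set.seed(44)
  for (rep in 1:10) {
    ga <- sample(sprintf("a%d", 1:9), 4L)   # arbitrary genomic order
    gb <- sample(sprintf("b%d", 1:9), 4L)
    g <- list(genes_a = ga, genes_b = gb, links = mk_links(ga, sample(gb)))
    sp <- split_symmetric_group(g)
    expect_equal(sp$gene_a, ga)
    expect_equal(sp$gene_b, gb)
  }
})

test_that("region resolution handles direct pairs, overlaps and mixed groups", {
  # five clean 1-1 links resolve with no removals
  ga <- mk_genes(sprintf("a%d", 1:5), (1:5) * 1000, (1:5) * 1000 + 400)
  gb <- mk_genes(sprintf("b%d", 1:5), (1:5) * 1000, (1:5) * 1000 + 400)
  rr <- resolve_region(ga, gb, mk_links(ga$gene_id, gb$gene_id))
  expect_equal(nrow(rr$pairs), 5L)
  expect_equal(nrow(rr$removed), 0L)
  expect_true(all(rr$pairs$provenance == "direct"))

  # same-species overlap excludes all participants
  ga2 <- mk_genes(c("a1", "a2", "a3"), c(1000, 1200, 5000),
                  c(2000, 2200, 6000))
  gb2 <- mk_genes(c("b1", "b2", "b3"), c(1000, 3000, 5000),
                  c(2000, 4000, 6000))
  rr2 <- resolve_region(ga2, gb2, mk_links(ga2$gene_id, gb2$gene_id))
  ov <- rr2$removed[rr2$removed$reason == "overlap_excluded", ]
  expect_setequal(ov$gene_id, c("a1", "a2"))
  expect_equal(rr2$pairs$gene_a, "a3")

  # mixed configuration: 1-1, one-to-many, 3-vs-2, and an orphan
  ga3 <- mk_genes(sprintf("a%d", 1:6), (1:6) * 1000, (1:6) * 1000 + 400)
  gb3 <- mk_genes(sprintf("b%d", 1:6), (1:6) * 1000, (1:6) * 1000 + 400)
  links <- rbind(
    mk_links("a1", "b1", 90),                    # direct
    mk_links(c("a2", "a2"), c("b2", "b3"), c(88, 70)),  # one-to-many
    # asymmetric many-to-many {a3,a4,a5} x {b4,b5}; a5 weakest
    data.frame(gene_a = c("a3", "a4", "a5", "a5"),
               gene_b = c("b4", "b5", "b4", "b5"),
               identity_ab = c(95, 93, 65, 66),
               identity_ba = c(95, 93, 65, 66), stringsAsFactors = FALSE))
  rr3 <- resolve_region(ga3, gb3, links)
  expect_equal(rr3$pairs$gene_a[rr3$pairs$gene_a %in% c("a3", "a4")],
               c("a3", "a4"))
  expect_setequal(
    rr3$removed$gene_id[rr3$removed$reason == "one_to_many_loser"], "b3")
  expect_setequal(
    rr3$removed$gene_id[rr3$removed$reason == "asymmetry_trim"], "a5")
  expect_setequal(
    rr3$removed$gene_id[rr3$removed$reason == "no_ortholog"],
    c("a6", "b6"))
  # order split pairs a3-b4, a4-b5 by genomic order
  expect_equal(rr3$pairs$gene_b[match(c("a3", "a4"), rr3$pairs$gene_a)],
               c("b4", "b5"))
})

test_that("resolution invariants hold over randomized regions", {
  set.seed(45)
  for (rep in 1:25) {
    n <- 40L
    ga <- mk_genes(sprintf("a%02d", 1:n), (1:n) * 2000, (1:n) * 2000 + 900)
    gb <- mk_genes(sprintf("b%02d", 1:n), (1:n) * 2000, (1:n) * 2000 + 900)
    nl <- sample(20:60, 1L)
    links <- unique(mk_links(sample(ga$gene_id, nl, replace = TRUE),
                             sample(gb$gene_id, nl, replace = TRUE),
                             runif(nl, 60, 100)))
    rr <- resolve_region(ga, gb, links)
    # each gene occurs in at most one pair
    expect_false(anyDuplicated(rr$pairs$gene_a) > 0)
    expect_false(anyDuplicated(rr$pairs$gene_b) > 0)
    # conservation: every gene is paired or reported removed
    rem_a <- rr$removed$gene_id[rr$removed$species == "A"]
    rem_b <- rr$removed$gene_id[rr$removed$species == "B"]
    expect_equal(sort(c(rr$pairs$gene_a, rem_a)), ga$gene_id)
    expect_equal(sort(c(rr$pairs$gene_b, rem_b)), gb$gene_id)
    # removed genes appear in no pair
    expect_length(intersect(rr$removed$gene_id,
                            c(rr$pairs$gene_a, rr$pairs$gene_b)), 0L)
    # |pairs| bounded by the smaller side
    expect_lte(nrow(rr$pairs), n)

    # idempotence: resolving the resolved pair set changes nothing
    again <- resolve_region(ga[ga$gene_id %in% rr$pairs$gene_a, ],
                            gb[gb$gene_id %in% rr$pairs$gene_b, ],
                            mk_links(rr$pairs$gene_a, rr$pairs$gene_b, 100))
    expect_equal(again$pairs$gene_a, rr$pairs$gene_a)
    expect_equal(again$pairs$gene_b, rr$pairs$gene_b)
    expect_equal(nrow(again$removed), 0L)
  }
})
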