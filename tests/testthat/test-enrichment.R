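test_that("flanking-window association handles the 1-nt boundary exactly", {
  genes <- data.frame(gene_id = "Klf4", chrom = "chr1",
                      start = 10001, end = 12000)
  hit <- data.frame(chrom = "chr1", start = 26990, end = 27005)
  miss <- data.frame(chrom = "chr1", start = 27001, end = 27100)
  expect_identical(associate_intervals(hit, genes, 15000)$associated_genes,
                   "Klf4")  # window ends at 27000: 11-nt overlap
  expect_length(associate_intervals(miss, genes, 15000)$associated_genes, 0)
  # left flank is clipped at 1 rather than going negative
  left <- data.frame(chrom = "chr1", start = 1, end = 10)
  expect_identical(associate_intervals(left, genes, 15000)$associated_genes,
                   "Klf4")
  expect_warning(
    associate_intervals(data.frame(chrom = "chrX", start = 5, end = 10),
                        genes, 1000),
    "absent from gene table")
})

test_that("interval-tree association equals the quadratic brute force", {
  genes <- toy_gene_table(n_genes = 200, seed = 13)
  peaks <- gen_interval_plant(genes, genes$gene_id[1:20],
                              n_background = 400, n_planted = 100, seed = 14)
  for (w in c(0, 500, 15000)) {
    expect_identical(associate_intervals(peaks, genes, w)$associated_genes,
                     brute_associate(peaks, genes, w))
  }
})

test_that("association frequency report compares groups to backgrounds", {
  genes <- toy_gene_table(n_genes = 100, seed = 21)
  targets <- genes$gene_id[1:20]
  peaks <- gen_interval_plant(genes, targets, n_background = 100,
                              n_planted = 150, seed = 22)
  assoc <- associate_intervals(peaks, genes, 15000, tf_label = "GR")
  rep_ <- association_frequency_report(
    assoc,
    gene_groups = list(dex_induced = targets),
    backgrounds = list(non_targets = setdiff(genes$gene_id, targets),
                       self = targets))
  row1 <- rep_[rep_$background == "non_targets", ]
  expect_lt(row1$p_value, 0.01)
  expect_gt(row1$group_freq, row1$bg_freq)
  row2 <- rep_[rep_$background == "self", ]
  expect_equal(row2$p_value, 1)  # group vs itself: no difference
  expect_true(all(rep_$group_freq >= 0 & rep_$group_freq <= 1))
  flagged <- association_frequency_report(
    assoc, list(g = targets), list(empty = character(0)))
  expect_true(flagged$flagged)
})

test_that("hypergeometric enrichment matches closed-form worked examples", {
  pop10 <- sprintf("g%02d", 1:10)
  res <- hypergeometric_enrichment(pop10[1:4], list(cat = pop10[1:5]), pop10)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)  # C(5,4)C(5,0)/C(10,4)

  pop20 <- sprintf("g%02d", 1:20)
  res2 <- hypergeometric_enrichment(pop20[1:5], list(cat = pop20[1:10]), pop20)
  expect_equal(res2$p_value, 252 / 15504, tolerance = 1e-12)  # C(10,5)/C(20,5)

  res0 <- hypergeometric_enrichment(pop10[6:9], list(cat = pop10[1:5]),
                                    pop10)
  expect_equal(res0$p_value, 1)  # k = 0: P(X >= 0)
  expect_error(hypergeometric_enrichment(c(pop10, "alien"),
                                         list(cat = pop10), pop10),
               "alien")
})

test_that("hypergeometric p equals draw-by-draw enumeration for small N", {
  for (N in c(8, 10, 12)) {
    pop <- sprintf("g%02d", seq_len(N))
    for (K in c(2, 4, N %/% 2)) {
      for (n in c(3, 5)) {
        cat_genes <- pop[seq_len(K)]  # category-first ordering
        for (k in max(0, n - (N - K)):min(K, n)) {
          smp <- c(cat_genes[seq_len(k)],
                   pop[setdiff(seq_len(N), seq_len(K))][seq_len(n - k)])
          p_pkg <- hypergeometric_enrichment(smp, list(cat = cat_genes),
                                             pop)$p_value
          expect_equal(p_pkg, enum_hyper_p(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.001, 0.2, 0.03, 0.8, 0.04)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("gene-set similarity uses the overlap coefficient", {
  cats <- list(A = c("a", "b", "c"), B = c("b", "c", "d"),
               C = c("a", "b", "c"), D = c("x", "y"))
  g <- geneset_similarity_network(cats, min_similarity = 0.6)
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_setequal(key, c("A B", "A C", "B C"))
  sim <- igraph::E(g)$similarity
  expect_equal(sort(sim), c(2 / 3, 2 / 3, 1))
  # disjoint sets never connect, even at threshold 0
  g0 <- geneset_similarity_network(list(A = "a", D = "d"), min_similarity = 0)
  expect_equal(igraph::ecount(g0), 0)
  # Jaccard option is strictly smaller for non-identical overlapping sets
  gj <- geneset_similarity_network(cats[c("A", "B")], min_similarity = 0.4,
                                   method = "jaccard")
  expect_equal(igraph::E(gj)$similarity, 2 / 4)
  expect_warning(geneset_similarity_network(list(A = "a", E = character(0)),
                                            min_similarity = 0.5),
                 "empty")
})

test_that("TF co-occurrence flags genes bound by every queried factor", {
  genes <- toy_gene_table(n_genes = 40, seed = 31)
  shared <- genes$gene_id[1:5]
  mk <- function(lbl, extra, seed) {
    associate_intervals(
      gen_interval_plant(genes, c(shared, extra), n_background = 0,
                         n_planted = 60, window_bp = 0, seed = seed,
                         label = lbl),
      genes, 0, tf_label = lbl)
  }
  a_gr <- mk("GR", genes$gene_id[6:10], 1)
  a_klf <- mk("KLF", genes$gene_id[11:15], 2)
  a_ppar <- mk("PPARg", genes$gene_id[16:20], 3)
  co <- tf_cooccurrence(list(a_gr, a_klf, a_ppar), genes)
  expect_true(all(co$cooccurrence[co$gene_id %in% shared] |
                    !co$gene_id %in% shared))
  only_gr <- setdiff(a_gr$associated_genes,
                     union(a_klf$associated_genes, a_ppar$associated_genes))
  expect_false(any(co$cooccurrence[co$gene_id %in% only_gr]))
  expect_lte(sum(co$cooccurrence), length(a_gr$associated_genes))
})

test_that("consensus scan counts IUPAC matches per window", {
  # fully matching window: all 12 defined positions of the default GRE
  res <- gre_scan("AGAACAGGGTGTTCT", both_strands = FALSE)
  expect_equal(res$match_count, 12)
  expect_equal(res$offset, 1)

  # the observed genomic site: 7 of 12 defined positions match
  res2 <- gre_scan("GGCACAGCATGTATC", min_report_matches = 7,
                   both_strands = FALSE)
  expect_equal(res2$match_count, 7)

  # the default consensus is its own reverse complement, so a hit scores
  # identically on both strands
  res3 <- gre_scan("AAGAACAGGGTGTTCTAA", min_report_matches = 12)
  expect_equal(nrow(res3), 2)
  expect_setequal(res3$strand, c("+", "-"))
  expect_equal(unique(res3$match_count), 12)
  expect_equal(unique(res3$offset), 2)

  expect_silent(gre_scan("agaacagggtgttct", both_strands = FALSE))
  expect_error(gre_scan("AGAACAXGGTGTTCT"), "non-nucleotide")
  expect_equal(nrow(gre_scan("ACGT")), 0)  # shorter than the motif
})
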