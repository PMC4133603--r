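toy_bridge_graph <- function() {
  igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("a", "c"), c("b", "c"),
    c("c", "d"),
    c("d", "e"), c("d", "f"), c("e", "f")), directed = FALSE)
}

test_that("edge betweenness matches hand values and the path-counting oracle", {
  tri <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                                     directed = FALSE)
  expect_true(all(edge_betweenness(tri) == 1))

  path <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = FALSE)
  expect_true(all(edge_betweenness(path) == 2))

  for (s in 1:20) {
    g <- random_named_gnp(6, 0.5, seed = s)
    mine <- edge_betweenness(g)
    ref <- brute_edge_betweenness(g)
    expect_equal(mine[names(ref)], ref, tolerance = 1e-10)
    # sum over edges equals the total shortest-path length over pairs
    d <- igraph::distances(g)
    expect_equal(sum(mine), sum(d[upper.tri(d)][is.finite(d[upper.tri(d)])]),
                 tolerance = 1e-10)
    # and agrees with the independent compiled implementation
    expect_equal(unname(mine), igraph::edge_betweenness(g, directed = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("Girvan-Newman cuts the bridge first and yields a true partition", {
  g <- toy_bridge_graph()
  gn <- girvan_newman(g, target_modules = 2)
  expect_equal(gn$removal_history$betweenness[1], 9)  # 3 x 3 crossing pairs
  expect_identical(gn$removal_history[1, c("from", "to")],
                   data.frame(from = "c", to = "d"))
  expect_equal(gn$n_modules, 2)
  expect_length(unique(gn$membership[c("a", "b", "c")]), 1)
  expect_length(unique(gn$membership[c("d", "e", "f")]), 1)
  expect_setequal(names(gn$membership), igraph::V(g)$name)

  # already-disconnected graph at target: identity partition, no removals
  g2 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "d")),
                                    directed = FALSE)
  gn2 <- girvan_newman(g2, target_modules = 2)
  expect_equal(gn2$n_modules, 2)
  expect_equal(nrow(gn2$removal_history), 0)
  expect_error(girvan_newman(g2, target_modules = 10), "exceeds")
})

test_that("Girvan-Newman agrees with igraph's implementation on planted graphs", {
  for (s in c(1, 2, 4)) {
    pn <- gen_planted_network(c(12, 12, 12), 0.4, 0.03, seed = s)
    mine <- girvan_newman(pn$graph, 3)$membership
    ceb <- igraph::cluster_edge_betweenness(pn$graph, weights = NULL)
    ref <- igraph::cut_at(ceb, no = 3)
    names(ref) <- igraph::V(pn$graph)$name
    expect_equal(ari(mine[names(ref)], ref), 1)
  }
})

test_that("auto stop picks the modularity-optimal partition", {
  pn <- gen_planted_network(c(10, 10), 0.8, 0.05, seed = 2)
  gn <- girvan_newman(pn$graph, "auto")
  expect_equal(gn$n_modules, 2)
  expect_gte(ari(gn$membership[names(pn$membership)], pn$membership), 0.9)
})

test_that("topology metrics match hand values and the dense-matrix oracle", {
  tri <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                                     directed = FALSE)
  rt <- topology_report(tri)
  expect_equal(rt$density, 1)
  expect_equal(rt$avg_clustering, 1)
  expect_equal(rt$heterogeneity, 0)

  star <- igraph::graph_from_edgelist(rbind(c("hub", "l1"), c("hub", "l2"),
                                            c("hub", "l3")), directed = FALSE)
  rs <- topology_report(star)
  expect_equal(rs$heterogeneity, 0.8660254 / 1.5, tolerance = 1e-6)
  pn <- rs$per_node
  expect_equal(pn$neighborhood_connectivity[pn$node == "hub"], 1)
  expect_equal(pn$neighborhood_connectivity[pn$node == "l1"], 3)

  for (s in 1:30) {
    n <- withr::with_seed(100 + s, sample(3:8, 1))
    g <- random_named_gnp(n, 0.5, seed = s)
    if (igraph::ecount(g) == 0) next
    mine <- topology_report(g)
    ref <- naive_topology(g)
    expect_equal(mine$density, ref$density, tolerance = 1e-12)
    expect_equal(mine$avg_clustering, ref$avg_clustering, tolerance = 1e-12)
    expect_equal(mine$heterogeneity, ref$heterogeneity, tolerance = 1e-12)
    expect_equal(mine$avg_neighborhood_connectivity, ref$avg_nc, tolerance = 1e-12)
    expect_equal(mine$per_node$clustering, ref$cc, tolerance = 1e-12)
    expect_equal(mine$per_node$degree, ref$deg)
    hist_mine <- as.integer(rep(as.integer(names(mine$shared_neighbor_histogram)),
                                mine$shared_neighbor_histogram))
    expect_equal(sort(hist_mine), sort(ref$shared))
  }
  single <- igraph::make_empty_graph(1, directed = FALSE)
  expect_error(topology_report(single), "at least 2")
})

test_that("hub edge fraction follows its definition and is monotone", {
  star <- igraph::graph_from_edgelist(rbind(c("hub", "l1"), c("hub", "l2"),
                                            c("hub", "l3")), directed = FALSE)
  expect_equal(hub_edge_fraction(star, 1), 1)
  tri <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                                     directed = FALSE)
  expect_equal(hub_edge_fraction(tri, 1), 2 / 3)
  g <- random_named_gnp(12, 0.3, seed = 5)
  fr <- vapply(1:12, function(k) hub_edge_fraction(g, k), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[12], 1)
  # degree-sum variant: summed hub degree over total degree
  expect_equal(hub_edge_fraction(star, 1, method = "degree_sum"), 0.5)
})

test_that("Yates chi-squared reproduces worked examples and invariances", {
  expect_equal(chi_square_yates(c(22, 403, 32, 253))$statistic, 8.05,
               tolerance = 1e-3)
  expect_equal(chi_square_yates(c(20, 80, 40, 60))$statistic,
               1900^2 * 200 / (84 * 10^6), tolerance = 1e-12)
  ind <- chi_square_yates(c(10, 10, 10, 10))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  t1 <- matrix(c(22, 403, 32, 253), 2, byrow = TRUE)
  expect_equal(chi_square_yates(t1)$statistic,
               chi_square_yates(t(t1))$statistic)
  expect_equal(chi_square_yates(t1)$statistic,
               chi_square_yates(t1[2:1, ])$statistic)
  expect_gt(chi_square_yates(10 * c(22, 403, 32, 253))$statistic,
            chi_square_yates(c(22, 403, 32, 253))$statistic)
  expect_error(chi_square_yates(c(0, 0, 5, 5)), "marginal")

  # equals the standard implementation wherever both are defined
  for (s in 1:10) {
    tab <- withr::with_seed(s, matrix(rpois(4, 30) + 1, 2))
    expect_equal(chi_square_yates(tab)$statistic,
                 unname(stats::chisq.test(tab, correct = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("module composition test flags class-aligned modules", {
  pn <- gen_planted_network(c(25, 25), 0.6, 0.05, seed = 1)
  gn <- girvan_newman(pn$graph, 2)
  cls <- setNames(pn$membership == 1, names(pn$membership))
  res <- module_composition_test(gn, cls)
  expect_equal(nrow(res), 2)
  expect_true(all(res$a + res$b + res$c + res$d == 50))
  aligned <- res[which.max(res$statistic), ]
  expect_lt(aligned$p_value, 0.001)

  # random class labels stay mostly non-significant; a 4-module partition
  # gives a stable per-seed fraction
  pn4 <- gen_planted_network(rep(15, 4), 0.6, 0.03, seed = 7)
  gn4 <- girvan_newman(pn4$graph, 4)
  frac_sig <- vapply(1:20, function(s) {
    rnd <- withr::with_seed(200 + s,
                            setNames(sample(c(TRUE, FALSE), 60, replace = TRUE),
                                     names(pn4$membership)))
    r <- module_composition_test(gn4, rnd)
    mean(r$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.1)
})
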