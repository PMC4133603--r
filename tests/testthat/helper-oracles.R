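# Independent brute-force oracles used to verify the package's
# implementations on small instances. Deliberately naive and written
# against different primitives than the implementation under test.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# exact two-sided Mann-Whitney p by enumerating all C(n+m, n) group
# assignments of the pooled ranks
enum_mw_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2L, function(i) sum(r[i])) - n * (n + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# hypergeometric upper tail by enumerating every possible draw of n genes
# from a population of N containing K category members
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # population ordered with category first
  mean(hits >= k)
}

# edge betweenness by explicit all-shortest-paths counting (igraph's path
# enumeration, not Brandes accumulation)
brute_edge_betweenness <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(pmin(nm[el[, 1L]], nm[el[, 2L]]),
               pmax(nm[el[, 1L]], nm[el[, 2L]]), sep = "|")
  eb <- stats::setNames(numeric(nrow(el)), key)
  if (n < 2L) return(eb)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$res)
      if (!length(paths)) next
      for (p in paths) {
        v <- as.integer(p)
        for (i in seq_len(length(v) - 1L)) {
          k <- paste(min(nm[v[i]], nm[v[i + 1L]]),
                     max(nm[v[i]], nm[v[i + 1L]]), sep = "|")
          eb[k] <- eb[k] + 1 / length(paths)
        }
      }
    }
  }
  eb
}

# dense-matrix reference for every topology metric
naive_topology <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  nc <- vapply(seq_len(n), function(v) {
    if (deg[v] == 0) NA_real_ else mean(deg[A[v, ] == 1])
  }, numeric(1L))
  shared <- (A %*% A)[upper.tri(A)]
  list(density = sum(A) / (n * (n - 1)),
       avg_clustering = mean(cc),
       heterogeneity = sqrt(mean((deg - mean(deg))^2)) / mean(deg),
       avg_nc = mean(nc, na.rm = TRUE),
       cc = unname(cc), nc = unname(nc), deg = unname(deg),
       shared = as.integer(shared))
}

# quadratic all-pairs reference for the flanking-window association rule
brute_associate <- function(peaks, genes, window_bp) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(peaks$chrom == genes$chrom[i] &
          peaks$start <= genes$end[i] + window_bp &
          peaks$end >= max(1, genes$start[i] - window_bp))
  }, logical(1L))
  sort(genes$gene_id[hit])
}

random_named_gnp <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

# small reusable gene table on the 2 x 10 Mb synthetic genome
toy_gene_table <- function(n_genes = 50, seed = 42) {
  withr::with_seed(seed, {
    chrom <- sample(c("chr1", "chr2"), n_genes, replace = TRUE)
    start <- sort(sample.int(9.9e6, n_genes))
    data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
               chrom = chrom, start = start,
               end = start + sample(2000:20000, n_genes, replace = TRUE),
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
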