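# Internal graph plumbing: integer edge list + adjacency, BFS components,
# and Brandes-style edge betweenness. Pure connectivity; weights ignored.

graph_nodes <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  nm
}

# adjacency as list of integer neighbor vectors, from an m x 2 edge matrix
build_adj <- function(el, n) {
  adj <- vector("list", n)
  if (nrow(el)) {
    both <- rbind(el, el[, 2:1, drop = FALSE])
    spl <- split(both[, 2L], factor(both[, 1L], levels = seq_len(n)))
    adj <- unname(spl)
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj
}

components_int <- function(adj, n) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Brandes accumulation of shortest-path edge betweenness (unweighted BFS).
# Returns, per edge, the sum over unordered node pairs of the fraction of
# shortest paths between the pair that pass through the edge.
brandes_edge_betweenness <- function(el, n, sources = seq_len(n)) {
  m <- nrow(el)
  eb <- numeric(m)
  if (!m) return(eb)
  # adjacency carrying edge ids alongside neighbors
  both <- rbind(cbind(el, seq_len(m)), cbind(el[, 2:1, drop = FALSE], seq_len(m)))
  f <- factor(both[, 1L], levels = seq_len(n))
  adj_v <- unname(split(both[, 2L], f))
  adj_e <- unname(split(both[, 3L], f))
  for (s in sources) {
    if (!length(adj_v[[s]])) next
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    qhead <- 1L; qtail <- 1L
    order_v <- integer(0)
    pred_v <- vector("list", n)
    pred_e <- vector("list", n)
    while (qhead <= qtail) {
      v <- queue[qhead]; qhead <- qhead + 1L
      order_v <- c(order_v, v)
      nbs <- adj_v[[v]]
      eids <- adj_e[[v]]
      for (j in seq_along(nbs)) {
        w <- nbs[j]
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          qtail <- qtail + 1L
          queue[qtail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred_v[[w]] <- c(pred_v[[w]], v)
          pred_e[[w]] <- c(pred_e[[w]], eids[j])
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_v)) {
      pv <- pred_v[[v]]
      if (!length(pv)) next
      contrib <- sigma[pv] / sigma[v] * (1 + delta[v])
      pe <- pred_e[[v]]
      for (j in seq_along(pv)) {
        eb[pe[j]] <- eb[pe[j]] + contrib[j]
        delta[pv[j]] <- delta[pv[j]] + contrib[j]
      }
    }
  }
  # each unordered pair counted once per endpoint when sources = all nodes
  eb / 2
}

#' Shortest-path edge betweenness
#'
#' For each edge, the sum over unordered node pairs of the fraction of
#' shortest paths between the pair that pass through that edge, computed by
#' Brandes-style accumulation over unweighted BFS distances. This is the
#' removal criterion of the Girvan-Newman community algorithm.
#'
#' @param g Undirected simple [igraph::igraph] graph (weights, if any, are
#'   ignored).
#' @return Named numeric vector, one entry per edge, named
#'   `"u|v"` with endpoint names sorted.
#' @examples
#' g <- igraph::make_ring(3)          # triangle: every edge scores 1
#' edge_betweenness(g)
#' @export
edge_betweenness <- function(g) {
  nm <- graph_nodes(g)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  eb <- brandes_edge_betweenness(el, n)
  if (nrow(el)) {
    names(eb) <- paste(pmin(nm[el[, 1L]], nm[el[, 2L]]),
                       pmax(nm[el[, 1L]], nm[el[, 2L]]), sep = "|")
  }
  eb
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the largest edge betweenness,
#' recalculates betweenness on the remaining graph, and repeats -- either
#' until the component count reaches `target_modules`, or (with `"auto"`)
#' scanning the whole removal sequence and keeping the partition with
#' maximal Newman modularity Q on the original graph. Partitioning uses
#' connectivity only; edge weights are disregarded. Betweenness ties are
#' broken by lexicographic edge id so the removal history is reproducible.
#'
#' @param g Undirected simple [igraph::igraph] graph.
#' @param target_modules Integer number of modules, or `"auto"` for the
#'   modularity-optimal cut. A numeric target must be at least the current
#'   number of components and at most the node count.
#' @return A `community_partition` list: `membership` (named integer
#'   vector), `n_modules`, `modularity`, and `removal_history` (data frame
#'   `step`, `from`, `to`, `betweenness`).
#' @examples
#' # two triangles joined by a bridge: the bridge falls first
#' g <- igraph::graph_from_edgelist(rbind(
#'   c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
#'   c("d", "e"), c("d", "f"), c("e", "f")), directed = FALSE)
#' girvan_newman(g, target_modules = 2)$removal_history
#' @export
girvan_newman <- function(g, target_modules = 3) {
  nm <- graph_nodes(g)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  m <- nrow(el)
  auto <- identical(target_modules, "auto")
  active <- rep(TRUE, m)
  comp <- components_int(build_adj(el, n), n)
  if (!auto) {
    target <- as.integer(target_modules)
    if (target > n) stop("target_modules exceeds the number of nodes")
    if (target < max(comp)) {
      stop(sprintf("graph already has %d components, more than target %d",
                   max(comp), target))
    }
  }
  hist_from <- character(0)
  hist_to <- character(0)
  hist_eb <- numeric(0)
  best_q <- -Inf
  best_comp <- comp
  if (auto) {
    best_q <- igraph::modularity(g, comp)
  }
  repeat {
    if (!auto && max(comp) >= target) break
    if (!any(active)) break
    sub <- el[active, , drop = FALSE]
    eb_active <- brandes_edge_betweenness(sub, n)
    mx <- max(eb_active)
    cand <- which(eb_active >= mx - 1e-9 * max(mx, 1))
    cand_glob <- which(active)[cand]
    key1 <- pmin(nm[el[cand_glob, 1L]], nm[el[cand_glob, 2L]])
    key2 <- pmax(nm[el[cand_glob, 1L]], nm[el[cand_glob, 2L]])
    pick_i <- order(key1, key2)[1L]
    pick <- cand_glob[pick_i]
    active[pick] <- FALSE
    hist_from <- c(hist_from, key1[pick_i])
    hist_to <- c(hist_to, key2[pick_i])
    hist_eb <- c(hist_eb, eb_active[cand[pick_i]])
    comp <- components_int(build_adj(el[active, , drop = FALSE], n), n)
    if (auto) {
      q <- igraph::modularity(g, comp)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_comp <- comp
      }
    }
  }
  final <- if (auto) best_comp else comp
  membership <- stats::setNames(final, nm)
  structure(list(membership = membership,
                 n_modules = max(final),
                 modularity = igraph::modularity(g, final),
                 removal_history = data.frame(
                   step = seq_along(hist_eb),
                   from = hist_from, to = hist_to,
                   betweenness = hist_eb,
                   stringsAsFactors = FALSE)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d modules over %d nodes (Q = %.4f), %d edges removed\n",
              x$n_modules, length(x$membership), x$modularity,
              nrow(x$removal_history)))
  invisible(x)
}

#' Network topology report
#'
#' Network-wide and node-specific topology statistics in the
#' NetworkAnalyzer convention: density `2E / (N(N-1))`; per-node clustering
#' coefficient `2 triangles / (deg (deg - 1))` (0 when deg < 2) and its
#' average; heterogeneity as the coefficient of variation of the degree
#' distribution (population sd / mean); neighborhood connectivity of a node
#' as the mean degree of its neighbors (averaged over nodes with at least
#' one neighbor); and the histogram of shared-neighbor counts over all node
#' pairs.
#'
#' @param g Undirected simple [igraph::igraph] graph with at least 2 nodes.
#' @return A `topology_report` list: `density`, `avg_clustering`,
#'   `heterogeneity`, `avg_neighborhood_connectivity`,
#'   `shared_neighbor_histogram` (named counts) and `per_node` (data frame
#'   `node`, `degree`, `clustering`, `neighborhood_connectivity`).
#' @export
topology_report <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("topology report needs at least 2 nodes")
  nm <- graph_nodes(g)
  deg <- igraph::degree(g)
  dens <- igraph::edge_density(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  knn <- suppressWarnings(igraph::knn(g)$knn)
  avg_nc <- mean(knn[is.finite(knn)])
  shared <- igraph::cocitation(g)
  counts <- table(shared[upper.tri(shared)])
  structure(list(density = dens,
                 avg_clustering = mean(cc),
                 heterogeneity = pop_sd(deg) / mean(deg),
                 avg_neighborhood_connectivity = avg_nc,
                 shared_neighbor_histogram = counts,
                 per_node = data.frame(node = nm, degree = as.integer(deg),
                                       clustering = cc,
                                       neighborhood_connectivity = as.numeric(knn),
                                       row.names = NULL)),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0("Topology: density %.3f, avg clustering %.3f, ",
                     "heterogeneity %.3f, avg neighborhood connectivity %.3f\n"),
              x$density, x$avg_clustering, x$heterogeneity,
              x$avg_neighborhood_connectivity))
  invisible(x)
}

#' Fraction of edges accounted for by the top-connected nodes
#'
#' The hub statistic: the fraction of all edges incident to at least one of
#' the `top_n` highest-degree nodes (ties broken by node id for
#' determinism). `method = "degree_sum"` reports the alternative reading,
#' the summed degree of the hub set over the total degree.
#'
#' @param g Undirected simple [igraph::igraph] graph.
#' @param top_n Size of the hub set, at most the node count.
#' @param method `"incident"` (default; hub-hub edges counted once) or
#'   `"degree_sum"`.
#' @return A fraction in `[0, 1]`.
#' @export
hub_edge_fraction <- function(g, top_n, method = c("incident", "degree_sum")) {
  method <- match.arg(method)
  n <- igraph::vcount(g)
  if (top_n > n) stop("top_n exceeds the number of nodes")
  if (top_n < 1L) return(0)
  nm <- graph_nodes(g)
  deg <- igraph::degree(g)
  hubs <- order(-deg, nm)[seq_len(top_n)]
  if (method == "degree_sum") {
    return(sum(deg[hubs]) / sum(deg))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) return(0)
  mean(el[, 1L] %in% hubs | el[, 2L] %in% hubs)
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' `chi2 = n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' continuity correction floored at zero when `|ad - bc| < n/2`; df = 1.
#'
#' @param table 2x2 numeric matrix of non-negative counts, or a length-4
#'   vector `(a, b, c, d)` read row-wise.
#' @return List `statistic`, `df`, `p_value`, `method`.
#' @examples
#' # 22/425 vs 32/285 gene-expression-related categories
#' chi_square_yates(c(22, 403, 32, 253))$statistic  # ~ 8.05
#' @export
chi_square_yates <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    x <- as.numeric(t(table))
  } else {
    stopifnot(length(table) == 4L)
    x <- as.numeric(table)
  }
  if (any(x < 0) || all(x == 0)) {
    stop("counts must be non-negative with at least one positive entry")
  }
  a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("chi-squared statistic undefined: zero marginal")
  corr <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * corr^2 / prod(marg)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       method = "Pearson chi-squared with Yates continuity correction")
}

#' Module composition tests
#'
#' Per module, builds the 2x2 table (in module vs out) x (in class vs out)
#' and applies the Yates-corrected chi-squared test: are modules enriched
#' for a node class (e.g. hormone-induced genes)? Modules smaller than 2
#' nodes are reported but skipped.
#'
#' @param partition A `community_partition` from [girvan_newman()] or a
#'   named membership vector.
#' @param node_class Named logical (or two-level) vector covering the
#'   partition's nodes: is each node in the class of interest?
#' @return Data frame: `module`, `size`, `a`, `b`, `c`, `d`, `statistic`,
#'   `p_value`, `skipped`.
#' @export
module_composition_test <- function(partition, node_class) {
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    partition
  }
  if (!all(names(membership) %in% names(node_class))) {
    stop("node_class must cover every node of the partition")
  }
  cls <- node_class[names(membership)]
  if (!is.logical(cls)) {
    lev <- unique(cls)
    if (length(lev) != 2L) stop("node_class must have exactly two levels")
    cls <- cls == lev[1L]
  }
  rows <- lapply(sort(unique(membership)), function(mod) {
    inmod <- membership == mod
    a <- sum(inmod & cls); b <- sum(inmod & !cls)
    c_ <- sum(!inmod & cls); d <- sum(!inmod & !cls)
    skipped <- sum(inmod) < 2L
    stat <- p <- NA_real_
    if (!skipped) {
      res <- tryCatch(chi_square_yates(c(a, b, c_, d)), error = function(e) NULL)
      if (is.null(res)) {
        skipped <- TRUE
      } else {
        stat <- res$statistic
        p <- res$p_value
      }
    }
    data.frame(module = mod, size = sum(inmod), a = a, b = b, c = c_, d = d,
               statistic = stat, p_value = p, skipped = skipped)
  })
  do.call(rbind, rows)
}
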