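#' Row-wise Z-score transform of an expression matrix
#'
#' Converts each gene's (optionally log2-transformed) expression profile to
#' Z-scores: `z = (x - mean(x)) / sd(x)` across conditions, with the sample
#' (n-1) standard deviation. Z-scoring removes magnitude so that clustering
#' acts on expression shape only. Rows with zero variance carry no shape
#' information; they are flagged constant and excluded.
#'
#' @param m Numeric genes x conditions matrix (linear scale), e.g. from
#'   [read_expression_tsv()] or [gen_expression()].
#' @param log2_transform Log2-transform before standardizing (default);
#'   set `FALSE` if `m` already holds log2 values.
#' @param pseudocount Added before the log2 transform; with the default 0,
#'   any non-positive value is an error.
#' @param groups Optional named vector mapping condition ids to replicate
#'   groups; replicate columns are averaged (on the log2 scale) before
#'   Z-scoring so that clustering sees one value per condition.
#' @return A `zscore_matrix` list: `z` (rows: non-constant genes),
#'   `gene_ids`, `condition_ids`, `constant` (flagged gene ids).
#' @examples
#' m <- rbind(g1 = 2^c(1, 2, 3, 4), g2 = c(5, 5, 5, 5))
#' colnames(m) <- c("U", "D", "L", "LD")
#' zscore_rows(m)
#' @export
zscore_rows <- function(m, log2_transform = TRUE, pseudocount = 0,
                        groups = NULL) {
  validate_expression_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 conditions to Z-score")
  x <- m
  if (log2_transform) {
    x <- x + pseudocount
    if (any(x <= 0)) {
      stop("non-positive values cannot be log2-transformed; ",
           "set a pseudocount or pass log2_transform = FALSE")
    }
    x <- log2(x)
  }
  if (!is.null(groups)) {
    if (is.null(names(groups)) || !all(colnames(x) %in% names(groups))) {
      stop("'groups' must be named by the condition columns of 'm'")
    }
    glev <- unique(unname(groups[colnames(x)]))
    cols <- lapply(glev, function(g) {
      rowMeans(x[, colnames(x)[groups[colnames(x)] == g], drop = FALSE])
    })
    x <- matrix(unlist(cols), nrow = nrow(x),
                dimnames = list(rownames(x), glev))
  }
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  constant <- !is.finite(s) | s < 1e-12
  z <- (x[!constant, , drop = FALSE] - mu[!constant]) / s[!constant]
  structure(list(z = z,
                 gene_ids = rownames(z),
                 condition_ids = colnames(x),
                 constant = rownames(x)[constant]),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("Z-score matrix: %d genes x %d conditions (%d constant rows excluded)\n",
              nrow(x$z), ncol(x$z), length(x$constant)))
  invisible(x)
}

#' One-way ANOVA filter for differentially expressed genes
#'
#' Per gene, a one-way ANOVA F statistic across condition groups computed on
#' log2 values: `F = (SSB/dfB) / (SSW/dfW)`. Genes with `p <= alpha` are
#' flagged as retained. The per-gene sums of squares are computed in a
#' vectorized pass over the matrix; the result is identical to per-gene
#' `aov()` fits.
#'
#' @param m Numeric genes x conditions-with-replicates matrix.
#' @param groups Named vector mapping each column of `m` to its condition
#'   group; every group needs at least 2 replicate columns.
#' @param alpha Retention threshold on the ANOVA p-value.
#' @inheritParams zscore_rows
#' @return Data frame `gene_id`, `f_statistic`, `p_value`, `retained`.
#' @export
anova_filter <- function(m, groups, alpha = 0.05, log2_transform = TRUE,
                         pseudocount = 0) {
  validate_expression_matrix(m)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (is.null(names(groups)) || !all(colnames(m) %in% names(groups))) {
    stop("'groups' must map every column of 'm' to a group")
  }
  grp <- factor(unname(groups[colnames(m)]))
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  sizes <- table(grp)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 replicate columns; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  x <- m
  if (log2_transform) {
    x <- x + pseudocount
    if (any(x <= 0)) stop("non-positive values cannot be log2-transformed")
    x <- log2(x)
  }
  gm <- rowMeans(x)
  k <- nlevels(grp)
  n <- ncol(x)
  group_means <- vapply(levels(grp), function(g) {
    rowMeans(x[, grp == g, drop = FALSE])
  }, numeric(nrow(x)))
  ssb <- as.vector((group_means - gm)^2 %*% as.numeric(sizes))
  sst <- rowSums((x - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- k - 1L
  df_w <- n - k
  f <- (ssb / df_b) / (ssw / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  data.frame(gene_id = rownames(m), f_statistic = f, p_value = p,
             retained = p <= alpha, row.names = NULL)
}

#' k-means clustering of Z-scored expression profiles
#'
#' Lloyd's algorithm with Euclidean distance, keeping the best of `n_init`
#' seeded random initializations by total within-cluster sum of squares.
#' Initializations that collapse a cluster are discarded.
#'
#' @param z A `zscore_matrix` from [zscore_rows()] or a plain numeric
#'   matrix.
#' @param k Number of clusters, `2 <= k <= n_genes`.
#' @param n_init Number of random initializations.
#' @param seed Integer seed; fixes the initializations.
#' @param init_centers Optional list of centroid matrices used as extra
#'   (deterministic) starting points, e.g. warm starts from a smaller k.
#' @return A `clustering_result` list: `k`, `labels` (named integer
#'   vector), `centroids`, `wss` (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(z, k, n_init = 25, seed = 1, init_centers = NULL) {
  zm <- if (inherits(z, "zscore_matrix")) z$z else z
  stopifnot(is.matrix(zm), is.numeric(zm))
  if (k > nrow(zm)) stop("k must not exceed the number of genes")
  if (k < 2L && nrow(zm) > 1L) stop("k must be >= 2")
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_init), function(i) {
      zm[sample(nrow(zm), k), , drop = FALSE]
    })
  })
  starts <- c(starts, init_centers)
  best <- NULL
  for (centers in starts) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(zm, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all k-means initializations failed")
  structure(list(k = as.integer(k),
                 labels = stats::setNames(best$cluster, rownames(zm)),
                 centroids = best$centers,
                 wss = best$tot.withinss),
            class = "clustering_result")
}

#' Elbow selection of the number of clusters
#'
#' Scans `k` over `k_range`, recording the total within-cluster sum of
#' squares (wss), and selects the interior `k` maximizing the discrete
#' second difference `wss(k-1) - 2 wss(k) + wss(k+1)` -- the reproducible
#' operationalization of reading the "elbow" off the wss-vs-k curve. Each
#' scan step is warm-started from the previous solution (previous centroids
#' plus the point farthest from its centroid), which guarantees a
#' non-increasing wss curve. A flat curve (maximum second difference below
#' 5% of the first wss value) is flagged as having no distinct elbow.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Integer pair `c(k_min, k_max)`; needs width >= 3 so an
#'   interior point exists. The classical scan for this data type is 8..14.
#' @return List: `k` (selected), `wss_by_k` (named numeric),
#'   `second_diff`, `no_elbow` flag, and `fits` (per-k
#'   `clustering_result`s).
#' @export
elbow_select_k <- function(z, k_range = c(8, 14), n_init = 25, seed = 1) {
  zm <- if (inherits(z, "zscore_matrix")) z$z else z
  ks <- seq.int(k_range[1L], k_range[2L])
  if (length(ks) < 3L) stop("k_range must span at least 3 values (no interior point)")
  if (ks[1L] < 2L || ks[length(ks)] > nrow(zm)) {
    stop("k_range must lie within [2, n_genes]")
  }
  fits <- vector("list", length(ks))
  names(fits) <- ks
  prev <- NULL
  for (i in seq_along(ks)) {
    warm <- NULL
    if (!is.null(prev)) {
      # split the previous solution: old centroids + the worst-fit point
      d2 <- rowSums((zm - prev$centroids[prev$labels, , drop = FALSE])^2)
      far <- which.max(d2)
      warm <- list(rbind(prev$centroids, zm[far, , drop = FALSE]))
    }
    fits[[i]] <- kmeans_cluster(zm, ks[i], n_init = n_init,
                                seed = seed + ks[i], init_centers = warm)
    prev <- fits[[i]]
  }
  wss <- vapply(fits, `[[`, numeric(1L), "wss")
  inner <- seq(2L, length(ks) - 1L)
  d2 <- wss[inner - 1L] - 2 * wss[inner] + wss[inner + 1L]
  names(d2) <- ks[inner]
  no_elbow <- max(d2) < 0.05 * wss[1L]
  list(k = ks[inner][which.max(d2)],
       wss_by_k = wss,
       second_diff = d2,
       no_elbow = no_elbow,
       fits = fits)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The p-value is exact (full enumeration
#' of the U distribution) when `n + m <= 20` and there are no ties, and a
#' normal approximation with tie and continuity corrections otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List `statistic` (U for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    # all observations identical: U at its null mean, no evidence either way
    return(list(statistic = n * m / 2, p_value = 1,
                method = "degenerate (all values equal)"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n + m) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       method = if (exact) "exact enumeration" else "normal approximation")
}

#' Per-cluster condition-contrast report
#'
#' For each cluster and each condition contrast, runs a Mann-Whitney test on
#' the per-gene expression values of the two conditions and assigns
#' significance stars at 0.05 / 0.01 / 0.001. Clusters with fewer than 3
#' genes are reported but flagged underpowered.
#'
#' @param m Numeric genes x conditions matrix (linear scale).
#' @param labels Named cluster assignment (gene -> cluster), e.g.
#'   `kmeans_cluster(...)$labels`.
#' @param contrasts List of condition-id pairs, e.g.
#'   `list(c("U", "D"), c("L", "LD"))`.
#' @return Data frame: `cluster`, `contrast`, `n_genes`, `statistic`,
#'   `p_value`, `stars`, `underpowered`.
#' @export
cluster_condition_report <- function(m, labels, contrasts) {
  validate_expression_matrix(m)
  if (!all(names(labels) %in% rownames(m))) {
    stop("labels refer to genes absent from the matrix")
  }
  bad <- unlist(contrasts)[!unlist(contrasts) %in% colnames(m)]
  if (length(bad)) stop("unknown condition(s): ", paste(unique(bad), collapse = ", "))
  rows <- list()
  for (cl in sort(unique(labels))) {
    genes <- names(labels)[labels == cl]
    for (ct in contrasts) {
      res <- mann_whitney_u(m[genes, ct[1L]], m[genes, ct[2L]])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl,
        contrast = paste(ct, collapse = "-"),
        n_genes = length(genes),
        statistic = res$statistic,
        p_value = res$p_value,
        stars = p_stars(res$p_value),
        underpowered = length(genes) < 3L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
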