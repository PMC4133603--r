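#' Cluster template for synthetic expression data
#'
#' A template describes one planted co-regulation cluster: its log2 mean per
#' condition, the number of genes drawn from it, a between-gene baseline
#' spread and a residual noise level. Expression noise is Normal on the log2
#' scale (multiplicative on the linear scale), matching RNA-seq dispersion
#' behaviour at typical RPKM magnitudes.
#'
#' @param template_id Short identifier.
#' @param condition_means Named numeric vector of log2 means, one per
#'   condition (e.g. `c(U = 5, D = 8, L = 5, LD = 8)`).
#' @param n_genes Number of genes drawn from the template.
#' @param gene_sd Between-gene baseline spread (log2 units); a per-gene
#'   constant offset, removed by row Z-scoring.
#' @param noise_sd Residual per-cell noise (log2 units).
#' @return A `cluster_template` list.
#' @export
cluster_template <- function(template_id, condition_means, n_genes,
                             gene_sd = 0.4, noise_sd = 0.25) {
  stopifnot(is.character(template_id), length(template_id) == 1L)
  if (is.null(names(condition_means))) {
    stop("condition_means must be named by condition id")
  }
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (gene_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  structure(list(template_id = template_id,
                 condition_means = condition_means,
                 n_genes = as.integer(n_genes),
                 gene_sd = gene_sd, noise_sd = noise_sd),
            class = "cluster_template")
}

#' Default macrophage-like cluster templates
#'
#' Twelve templates over the four conditions U (untreated), D
#' (dexamethasone), L (LPS) and LD (both), emulating the canonical
#' co-regulation patterns of an acute 1-h stimulation: independent LPS or
#' Dex induction, additive and synergistic co-activation, LPS induction
#' antagonized by Dex, Dex repression, and LPS downregulation.
#'
#' @return List of [cluster_template()] objects.
#' @export
macrophage_cluster_templates <- function() {
  cond <- function(u, d, l, ld) c(U = u, D = d, L = l, LD = ld)
  list(
    cluster_template("additive_up",        cond(5.0, 6.5, 6.5, 8.0), 40),
    cluster_template("lps_induced",        cond(4.0, 4.0, 8.0, 8.0), 35),
    cluster_template("lps_high_basal",     cond(6.0, 5.0, 8.5, 8.0), 45),
    cluster_template("lps_strong_lowbase", cond(2.0, 2.0, 7.0, 6.5), 30),
    cluster_template("lps_dex_repressed",  cond(3.0, 3.0, 7.0, 5.0), 30),
    cluster_template("synergy_up",         cond(4.0, 5.0, 5.0, 8.0), 20),
    cluster_template("dex_induced",        cond(4.0, 7.5, 4.0, 7.5), 35),
    cluster_template("dex_repressed",      cond(6.0, 4.0, 6.0, 4.2), 20),
    cluster_template("dex_up_lps_down",    cond(4.0, 7.0, 3.5, 6.0), 15),
    cluster_template("down_both",          cond(7.0, 6.0, 6.0, 5.0), 25),
    cluster_template("lps_down_antag",     cond(6.0, 6.0, 4.0, 5.5), 40),
    cluster_template("lps_down_potent",    cond(6.0, 5.8, 4.5, 4.0), 30)
  )
}

#' Well-separated 4-template fixture
#'
#' Four templates with mutually distant Z-score shapes, used for clustering
#' recovery checks (adjusted Rand index and elbow selection of k = 4).
#'
#' @param n_genes Genes per template.
#' @return List of four [cluster_template()] objects.
#' @export
separation_templates <- function(n_genes = 50) {
  cond <- function(u, d, l, ld) c(U = u, D = d, L = l, LD = ld)
  list(
    cluster_template("dex_up", cond(5, 9, 5, 9), n_genes, gene_sd = 0.5, noise_sd = 0.25),
    cluster_template("lps_up", cond(5, 5, 9, 9), n_genes, gene_sd = 0.5, noise_sd = 0.25),
    cluster_template("dex_dn", cond(9, 5, 9, 5), n_genes, gene_sd = 0.5, noise_sd = 0.25),
    cluster_template("lps_dn", cond(9, 9, 5, 5), n_genes, gene_sd = 0.5, noise_sd = 0.25)
  )
}

#' Generate a synthetic expression matrix with planted clusters
#'
#' For gene g of template T and condition c the log2 value is
#' `b_g + T$condition_means[c] + eps`, with `b_g ~ N(0, gene_sd)` and
#' `eps ~ N(0, noise_sd)`; the returned matrix is `2^x` (linear scale).
#'
#' @param templates List of [cluster_template()] objects sharing one
#'   condition set.
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @return List with `expression` (linear-scale matrix, genes x conditions)
#'   and `labels` (named character vector of true template ids).
#' @export
gen_expression <- function(templates, seed = 1) {
  if (!length(templates)) stop("need at least one cluster template")
  conds <- names(templates[[1L]]$condition_means)
  same <- vapply(templates, function(t) identical(names(t$condition_means), conds),
                 logical(1L))
  if (!all(same)) stop("all templates must share one condition set")
  withr::with_seed(seed, {
    rows <- lapply(templates, function(t) {
      b <- stats::rnorm(t$n_genes, 0, t$gene_sd)
      eps <- matrix(stats::rnorm(t$n_genes * length(conds), 0, t$noise_sd),
                    nrow = t$n_genes)
      x <- outer(b, rep(1, length(conds))) +
        matrix(t$condition_means, t$n_genes, length(conds), byrow = TRUE) + eps
      rownames(x) <- sprintf("%s_g%03d", t$template_id, seq_len(t$n_genes))
      x
    })
    logmat <- do.call(rbind, rows)
  })
  colnames(logmat) <- conds
  labels <- rep(vapply(templates, `[[`, character(1L), "template_id"),
                vapply(templates, `[[`, integer(1L), "n_genes"))
  names(labels) <- rownames(logmat)
  list(expression = 2^logmat, labels = labels)
}

#' Generate replicated noisy FFL fold-change time courses
#'
#' Simulates the I1-FFL target `z(t)` under `params` and multiplies each
#' replicate by lognormal noise with a given coefficient of variation
#' (fold-change error from RT-qPCR-style measurement is multiplicative).
#' The lognormal is mean-1 parameterized, so replicate means stay on the
#' model curve; basal expression is 1 by construction.
#'
#' @param params [ffl_params()] object.
#' @param times Non-negative sorted time grid, hours. The default is the
#'   0-9 h sampling grid used throughout.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return List with `time`, `mean`, `sem` (standard error of the mean),
#'   `replicates` (times x n_rep matrix), `model` (noiseless curve) and
#'   `params`.
#' @export
gen_ffl_timecourse <- function(params, times = c(0, 0.5, 1, 2, 3, 5, 7, 9),
                               noise_cv = 0.05, n_rep = 3, seed = 1) {
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times)) stop("times must be sorted")
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  stopifnot(n_rep >= 1L)
  z <- simulate_i1ffl(params, times)$z
  sdlog <- sqrt(log1p(noise_cv^2))
  reps <- withr::with_seed(seed, {
    noise <- matrix(stats::rlnorm(length(times) * n_rep,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = length(times))
    z * noise
  })
  rownames(reps) <- format(times)
  list(time = times,
       mean = rowMeans(reps),
       sem = apply(reps, 1L, stats::sd) / sqrt(n_rep),
       replicates = reps,
       model = z,
       params = params)
}

#' Generate a planted-partition (stochastic block model) graph
#'
#' Within-community node pairs are joined with probability `p_in`, between
#' pairs with probability `p_out`; the true community membership is
#' returned for recovery tests.
#'
#' @param sizes Integer vector of community sizes.
#' @param p_in,p_out Edge probabilities, `0 <= p_out <= p_in <= 1`.
#' @param seed Integer seed.
#' @return List with `graph` (igraph, nodes named `n001`, ...) and
#'   `membership` (named integer vector of true communities).
#' @export
gen_planted_network <- function(sizes, p_in, p_out, seed = 1) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  k <- length(sizes)
  pref <- matrix(p_out, k, k)
  diag(pref) <- p_in
  n <- sum(sizes)
  g <- withr::with_seed(seed, {
    igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  })
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  membership <- stats::setNames(rep(seq_along(sizes), sizes),
                                igraph::V(g)$name)
  list(graph = g, membership = membership)
}

#' Generate binding-site intervals with planted proximity enrichment
#'
#' Background intervals are placed uniformly on the synthetic genome;
#' planted intervals are placed so that each overlaps the `window_bp`
#' neighbourhood of a randomly chosen target gene, emulating TF peaks
#' enriched near a co-regulated gene cluster.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param target_genes Character vector of gene ids to plant peaks near;
#'   must all appear in `genes`.
#' @param n_background,n_planted Interval counts.
#' @param window_bp Flanking window (bp) used for planting, symmetric
#'   around the gene body.
#' @param peak_width Width of each interval (bp).
#' @param genome Data frame `chrom`, `length` describing the synthetic
#'   genome (default two 10-Mb chromosomes, small enough for exhaustive
#'   overlap oracles).
#' @param label Interval label (TF/dataset name).
#' @param seed Integer seed.
#' @return Data frame of 1-based closed intervals
#'   (`chrom`, `start`, `end`, `label`).
#' @export
gen_interval_plant <- function(genes, target_genes, n_background = 1000,
                               n_planted = 200, window_bp = 15000,
                               peak_width = 200, genome = default_genome(),
                               label = "TF", seed = 1) {
  validate_gene_table(genes)
  stopifnot(n_background >= 0L, n_planted >= 0L, window_bp >= 0L,
            peak_width >= 1L)
  missing <- setdiff(target_genes, genes$gene_id)
  if (length(missing)) {
    stop("target gene(s) absent from gene table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  chrom_len <- stats::setNames(genome$length, genome$chrom)
  withr::with_seed(seed, {
    bg <- NULL
    if (n_background > 0L) {
      chr <- sample(genome$chrom, n_background, replace = TRUE,
                    prob = genome$length)
      start <- floor(stats::runif(n_background, 1, chrom_len[chr] - peak_width + 1))
      bg <- data.frame(chrom = chr, start = as.integer(start),
                       end = as.integer(start + peak_width - 1L),
                       label = label, stringsAsFactors = FALSE)
    }
    pl <- NULL
    if (n_planted > 0L) {
      idx <- match(sample(target_genes, n_planted, replace = TRUE),
                   genes$gene_id)
      g <- genes[idx, , drop = FALSE]
      lo <- pmax(1L, g$start - window_bp - peak_width + 1L)
      hi <- pmin(g$end + window_bp, chrom_len[g$chrom] - peak_width + 1L)
      start <- floor(stats::runif(n_planted, lo, hi + 1))
      pl <- data.frame(chrom = g$chrom, start = as.integer(start),
                       end = as.integer(start + peak_width - 1L),
                       label = label, stringsAsFactors = FALSE)
    }
    out <- rbind(bg, pl)
  })
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

#' @rdname gen_interval_plant
#' @export
default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(1e7, 1e7))
}

#' Generate a random gene-set annotation table with planted categories
#'
#' Random categories draw members uniformly from the gene universe; planted
#' categories carry the supplied (overrepresented) gene subsets. Categories
#' that end up empty are dropped with a warning. The result is GMT-writable
#' with [write_gmt()].
#'
#' @param genes Character vector: the gene universe.
#' @param n_categories Number of random categories.
#' @param planted Named list mapping category name to a gene subset.
#' @param min_size,max_size Size range of random categories.
#' @param seed Integer seed.
#' @return Named list of character vectors of gene ids.
#' @export
gen_annotations <- function(genes, n_categories = 30, planted = list(),
                            min_size = 5, max_size = 40, seed = 1) {
  stopifnot(length(genes) >= 1L, n_categories >= 0L,
            min_size >= 1L, max_size >= min_size)
  bad <- unlist(lapply(planted, setdiff, y = genes))
  if (length(bad)) {
    stop("planted gene(s) not in universe: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sets <- withr::with_seed(seed, {
    sizes <- sample(min_size:max_size, n_categories, replace = TRUE)
    out <- lapply(sizes, function(s) sample(genes, min(s, length(genes))))
    names(out) <- sprintf("cat%03d", seq_len(n_categories))
    out
  })
  sets <- c(sets, lapply(planted, unique))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropped %d empty categor%s", sum(empty),
                    if (sum(empty) == 1L) "y" else "ies"))
    sets <- sets[!empty]
  }
  sets
}
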