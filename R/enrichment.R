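#' Associate binding-site intervals with genes (flanking-window rule)
#'
#' A gene is associated with a peak set if at least one interval overlaps,
#' by at least one nucleotide, the region spanning the gene body plus
#' `window_bp` of flanking sequence on each side (symmetric; strand is
#' ignored). Coordinates are 1-based closed; the left flank is clipped at
#' position 1. Overlap is computed with an interval-tree query
#' (GenomicRanges), which equals the all-pairs brute force.
#'
#' @param peaks Data frame of intervals (`chrom`, `start`, `end`,
#'   optionally `label`), e.g. from [read_bed()] or [gen_interval_plant()].
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp Flanking window in bp (default 15000).
#' @param tf_label Label for the association set; defaults to the peaks'
#'   `label` column when unique, else `"peaks"`.
#' @return A `gene_association` list: `tf_label`, `associated_genes`
#'   (sorted character vector), `window_bp`, `n_peaks`.
#' @examples
#' genes <- data.frame(gene_id = "Klf4", chrom = "chr1",
#'                     start = 10001, end = 12000)
#' peaks <- data.frame(chrom = "chr1", start = 26990, end = 27005)
#' associate_intervals(peaks, genes, window_bp = 15000)$associated_genes
#' @export
associate_intervals <- function(peaks, genes, window_bp = 15000,
                                tf_label = NULL) {
  validate_intervals(peaks)
  validate_gene_table(genes)
  if (window_bp < 0) stop("window_bp must be >= 0")
  orphan <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(orphan)) {
    warning("peaks on chromosome(s) absent from gene table counted unassociated: ",
            paste(orphan, collapse = ", "))
  }
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(window_bp)),
                     genes$end + as.integer(window_bp)))
  gr_peaks <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start, peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_peaks, gr_genes))
  assoc <- sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
  label <- tf_label %||% {
    labs <- unique(peaks$label)
    if (length(labs) == 1L && !is.null(labs)) labs else "peaks"
  }
  structure(list(tf_label = label, associated_genes = assoc,
                 window_bp = window_bp, n_peaks = nrow(peaks)),
            class = "gene_association")
}

#' @export
print.gene_association <- function(x, ...) {
  cat(sprintf("%s: %d genes associated (window +/- %d bp, %d peaks)\n",
              x$tf_label, length(x$associated_genes), x$window_bp, x$n_peaks))
  invisible(x)
}

#' Split genes into expression tiers
#'
#' The standard RPKM backgrounds for binding-frequency comparisons:
#' non-expressors (RPKM < 1), low expressors (1 < RPKM < 10) and all
#' expressing genes (RPKM > 1), based on the mean expression across
#' conditions.
#'
#' @param m Numeric genes x conditions matrix (linear RPKM-like scale).
#' @return Named list of gene-id vectors: `non_expressors`,
#'   `low_expressors`, `expressed`.
#' @export
expression_tiers <- function(m) {
  validate_expression_matrix(m)
  avg <- rowMeans(m)
  list(non_expressors = rownames(m)[avg < 1],
       low_expressors = rownames(m)[avg > 1 & avg < 10],
       expressed = rownames(m)[avg > 1])
}

#' Binding-association frequencies of gene groups vs backgrounds
#'
#' For each TF association set and each gene group, the fraction of genes
#' with at least one associated binding site is compared with each
#' background tier by the Yates-corrected chi-squared test. A gene counts
#' once per TF regardless of peak multiplicity.
#'
#' @param assocs A `gene_association` or list of them.
#' @param gene_groups Named list of gene-id vectors (e.g. expression
#'   clusters).
#' @param backgrounds Named list of gene-id vectors (e.g.
#'   [expression_tiers()]).
#' @return Data frame: `tf`, `group`, `background`, group and background
#'   hit counts/sizes and frequencies, `statistic`, `p_value`, `flagged`
#'   (empty group or background).
#' @export
association_frequency_report <- function(assocs, gene_groups, backgrounds) {
  if (inherits(assocs, "gene_association")) assocs <- list(assocs)
  stopifnot(length(gene_groups) >= 1L, length(backgrounds) >= 1L)
  rows <- list()
  for (as_ in assocs) {
    hit <- as_$associated_genes
    for (gname in names(gene_groups)) {
      grp <- unique(gene_groups[[gname]])
      k1 <- sum(grp %in% hit)
      n1 <- length(grp)
      for (bname in names(backgrounds)) {
        bg <- unique(backgrounds[[bname]])
        k2 <- sum(bg %in% hit)
        n2 <- length(bg)
        flagged <- n1 == 0L || n2 == 0L
        stat <- p <- NA_real_
        if (!flagged) {
          if (isTRUE(all.equal(k1 / n1, k2 / n2))) {
            stat <- 0; p <- 1  # equal frequencies: nothing to test
          } else {
            res <- chi_square_yates(c(k1, n1 - k1, k2, n2 - k2))
            stat <- res$statistic
            p <- res$p_value
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          tf = as_$tf_label, group = gname, background = bname,
          group_hits = k1, group_size = n1,
          group_freq = if (n1) k1 / n1 else NA_real_,
          bg_hits = k2, bg_size = n2,
          bg_freq = if (n2) k2 / n2 else NA_real_,
          statistic = stat, p_value = p, flagged = flagged,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric gene-set overrepresentation test
#'
#' For each category, the one-sided upper-tail probability of observing at
#' least `k` category genes in a sample of size `n` drawn without
#' replacement from a population of `N` genes containing `K` category
#' genes, with Benjamini-Hochberg q-values across categories. Categories
#' with no gene in the population are dropped.
#'
#' @param sample Character vector of sample gene ids (must be contained in
#'   `population`).
#' @param annotations Named list mapping category to gene-id vector (e.g.
#'   from [read_gmt()] or [gen_annotations()]).
#' @param population Character vector: the gene universe. Defaults to the
#'   union of all annotated genes.
#' @return Data frame sorted by p-value: `category`, `N`, `K`, `n`, `k`,
#'   `p_value`, `q_value`.
#' @examples
#' pop <- sprintf("g%02d", 1:10)
#' hypergeometric_enrichment(pop[1:4], list(half = pop[1:5]), pop)
#' @export
hypergeometric_enrichment <- function(sample, annotations,
                                      population = unique(unlist(annotations))) {
  sample <- unique(sample)
  population <- unique(population)
  offenders <- setdiff(sample, population)
  if (length(offenders)) {
    stop("sample gene(s) outside the population: ",
         paste(utils::head(offenders, 5L), collapse = ", "))
  }
  N <- length(population)
  n <- length(sample)
  K <- vapply(annotations, function(g) sum(unique(g) %in% population), integer(1L))
  keep <- K >= 1L
  ann <- annotations[keep]
  K <- K[keep]
  k <- vapply(ann, function(g) sum(unique(g) %in% sample), integer(1L))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = names(ann), N = N, K = K, n = n, k = k,
                    p_value = p, q_value = bh_fdr(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min over j >= i of m p_(j) / j`, clipped at 1, mapped back to
#' input order -- false discovery rate control for the enrichment tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set similarity network
#'
#' Nodes are categories; two categories are connected when their overlap
#' coefficient `|A intersect B| / min(|A|, |B|)` (the fraction of shared
#' genes relative to the smaller set, Enrichment Map practice) reaches
#' `min_similarity`. Jaccard similarity is available as an option. Empty
#' categories are dropped.
#'
#' @param categories Named list of gene-id vectors.
#' @param min_similarity Edge threshold in `[0, 1]`.
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @return An [igraph::igraph] with a `similarity` edge attribute.
#' @export
geneset_similarity_network <- function(categories, min_similarity = 0.5,
                                       method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  stopifnot(length(categories) >= 1L, !is.null(names(categories)))
  assert_scalar_number(min_similarity, "min_similarity", lower = 0, upper = 1)
  categories <- lapply(categories, unique)
  empty <- lengths(categories) == 0L
  if (any(empty)) {
    warning(sprintf("dropped %d empty categor%s", sum(empty),
                    if (sum(empty) == 1L) "y" else "ies"))
    categories <- categories[!empty]
  }
  nm <- names(categories)
  edges <- list()
  if (length(nm) >= 2L) {
    for (i in seq_len(length(nm) - 1L)) {
      for (j in seq.int(i + 1L, length(nm))) {
        inter <- length(intersect(categories[[i]], categories[[j]]))
        sim <- if (method == "overlap") {
          inter / min(length(categories[[i]]), length(categories[[j]]))
        } else {
          inter / length(union(categories[[i]], categories[[j]]))
        }
        if (sim >= min_similarity && inter > 0L) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = nm[i], to = nm[j], similarity = sim,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(edges)) {
    igraph::graph_from_data_frame(do.call(rbind, edges), directed = FALSE,
                                  vertices = nm)
  } else {
    igraph::make_empty_graph(n = length(nm), directed = FALSE) +
      igraph::vertices(nm)
  }
}

#' Transcription-factor co-occurrence at genes
#'
#' Given association sets for two or more TFs (each built with
#' [associate_intervals()] at the same flanking window), reports, per
#' gene, which TFs have at least one associated site, and flags genes
#' associated with all queried TFs as co-occurrence loci.
#'
#' @param assocs List of two or more `gene_association` objects.
#' @param genes Gene table (`gene_id`, ...).
#' @return Data frame: `gene_id`, `tfs` (comma-separated), `n_tfs`,
#'   `cooccurrence`.
#' @export
tf_cooccurrence <- function(assocs, genes) {
  stopifnot(length(assocs) >= 2L)
  validate_gene_table(genes)
  labels <- vapply(assocs, `[[`, character(1L), "tf_label")
  hitmat <- vapply(assocs, function(a) genes$gene_id %in% a$associated_genes,
                   logical(nrow(genes)))
  tfs <- apply(hitmat, 1L, function(h) paste(labels[h], collapse = ","))
  data.frame(gene_id = genes$gene_id,
             tfs = tfs,
             n_tfs = rowSums(hitmat),
             cooccurrence = rowSums(hitmat) == length(assocs),
             row.names = NULL, stringsAsFactors = FALSE)
}

# IUPAC nucleotide codes -> matching bases
IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

#' Scan a sequence for a degenerate consensus motif
#'
#' Slides an IUPAC consensus (default the canonical pseudo-palindromic
#' 15-mer glucocorticoid response element, `AGAACANNNTGTTCT`) across the
#' sequence and counts, per window, how many non-N consensus positions are
#' matched (IUPAC-aware; an N in the sequence matches nothing). Windows
#' reaching `min_report_matches` are reported; the reverse strand is
#' scanned when requested, with offsets mapped back to the forward strand.
#'
#' @param sequence DNA string over `A C G T N`, case-insensitive.
#' @param consensus IUPAC consensus string.
#' @param min_report_matches Minimum matched (non-N) positions for a
#'   window to be reported. The permissive default 7 captures degenerate
#'   GRE-like half-site matches; raise it toward the number of defined
#'   positions (12 for the default consensus) for strict hits.
#' @param both_strands Scan the reverse complement too.
#' @return Data frame: `offset` (1-based forward-strand window start),
#'   `strand`, `match_count`.
#' @examples
#' gre_scan("AAGAACAGGGTGTTCTAA", both_strands = FALSE)
#' @export
gre_scan <- function(sequence, consensus = "AGAACANNNTGTTCT",
                     min_report_matches = 7, both_strands = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seqU <- toupper(sequence)
  schars <- strsplit(seqU, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(schars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("non-nucleotide character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  consU <- toupper(consensus)
  cchars <- strsplit(consU, "", fixed = TRUE)[[1L]]
  if (!length(cchars) || !all(cchars %in% names(IUPAC_MAP))) {
    stop("consensus must be a non-empty IUPAC string")
  }
  w <- length(cchars)
  scan_one <- function(chars) {
    L <- length(chars)
    if (L < w) return(integer(0))
    n_off <- L - w + 1L
    mc <- integer(n_off)
    offs <- seq_len(n_off)
    for (j in seq_len(w)) {
      if (cchars[j] == "N") next  # undefined position, never counted
      mc <- mc + (chars[offs + j - 1L] %in% IUPAC_MAP[[cchars[j]]])
    }
    mc
  }
  fwd <- scan_one(schars)
  hits <- data.frame(offset = integer(0), strand = character(0),
                     match_count = integer(0), stringsAsFactors = FALSE)
  if (length(fwd)) {
    keep <- which(fwd >= min_report_matches)
    hits <- rbind(hits, data.frame(offset = keep, strand = "+",
                                   match_count = fwd[keep],
                                   stringsAsFactors = FALSE))
  }
  if (both_strands) {
    rcc <- rev(chartr("ACGTN", "TGCAN", schars))
    rv <- scan_one(rcc)
    if (length(rv)) {
      keep <- which(rv >= min_report_matches)
      L <- length(schars)
      # window at rc offset o covers forward positions (L-o-w+2)..(L-o+1)
      hits <- rbind(hits, data.frame(offset = L - keep - w + 2L, strand = "-",
                                     match_count = rv[keep],
                                     stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}
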