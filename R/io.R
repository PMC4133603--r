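#' Read a genes x conditions expression table
#'
#' Reads a TSV whose first column holds gene ids and whose remaining columns
#' hold condition-wise expression values (RPKM-like). Values are stored on
#' the linear scale; files containing log2 values are exponentiated on read.
#'
#' @param path Path to a tab-separated file with a header row of condition
#'   ids and gene ids in the first column.
#' @param log2_input If `TRUE` the file stores log2 values which are
#'   converted back to the linear scale (`2^x`).
#' @return A numeric matrix with gene ids as rownames and condition ids as
#'   colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tU\tD", "Klf2\t1.0\t8.0", "Per1\t2.0\t4.0"), tf)
#' read_expression_tsv(tf)
#' @export
read_expression_tsv <- function(path, log2_input = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("expression table needs a gene id column plus at least one condition column")
  }
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene id(s) in expression table: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  cell <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cell), dim = dim(cell)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric value '%s' at gene '%s' (row %d), column '%s'",
                 cell[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 bad[1L, 1L], colnames(cell)[bad[1L, 2L]]))
  }
  if (log2_input) vals <- 2^vals
  dimnames(vals) <- list(gene_ids, colnames(cell))
  validate_expression_matrix(vals)
  vals
}

#' Read and write BED intervals
#'
#' BED coordinates are 0-based half-open; internally intervals are 1-based
#' closed (mm9 annotation style), so `start` is incremented on read and the
#' conversion is reversed on write. The two functions are exact inverses on
#' valid intervals.
#'
#' @param path Path to a BED3+ file (tab-separated, no header).
#' @return `read_bed()`: a data frame with columns `chrom`, `start`, `end`
#'   (1-based closed) and `label` (BED name column, `"."` when absent).
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t26989\t27005\tpeak1", tf)
#' read_bed(tf)  # chr1:26990-27005, width 16
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED input needs at least 3 columns")
  start0 <- raw[[2L]]
  end0 <- raw[[3L]]
  if (!is.numeric(start0) || !is.numeric(end0)) {
    stop("BED start/end columns must be numeric")
  }
  empty <- which(end0 <= start0)
  if (length(empty)) {
    stop(sprintf("empty or inverted BED interval at line %d: start %d, end %d",
                 empty[1L], start0[empty[1L]], end0[empty[1L]]))
  }
  out <- data.frame(chrom = as.character(raw[[1L]]),
                    start = as.integer(start0 + 1L),
                    end = as.integer(end0),
                    label = if (ncol(raw) >= 4L) as.character(raw[[4L]]) else ".",
                    stringsAsFactors = FALSE)
  validate_intervals(out)
  out
}

#' @rdname read_bed
#' @param intervals Data frame of 1-based closed intervals
#'   (`chrom`, `start`, `end`, optionally `label`).
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  out <- data.frame(intervals$chrom,
                    intervals$start - 1L,
                    intervals$end,
                    intervals$label %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; coordinates 1-based closed, strand `+` or `-`. Strand is
#'   stored but not used by the symmetric flanking window logic.
#' @return Data frame with those columns.
#' @export
read_gene_table <- function(path) {
  genes <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_gene_table(genes)
  if ("strand" %in% names(genes) && !all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes
}

#' Read a two/three-column edge list into an undirected simple graph
#'
#' Self-loops are dropped with a warning and duplicate edges are collapsed.
#' An optional third column is parsed as an edge `weight` attribute, which
#' is retained as an annotation only: community detection and all topology
#' statistics use connectivity alone.
#'
#' @param path TSV with two node-id columns and an optional numeric weight
#'   column, no header.
#' @return An [igraph::igraph] object.
#' @export
read_edge_list <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("edge list needs two node columns per line")
  short <- which(is.na(raw[[2L]]) | raw[[2L]] == "")
  if (length(short)) {
    stop(sprintf("edge list line %d has a single column", short[1L]))
  }
  df <- data.frame(from = raw[[1L]], to = raw[[2L]], stringsAsFactors = FALSE)
  if (ncol(raw) >= 3L) df$weight <- suppressWarnings(as.numeric(raw[[3L]]))
  loops <- df$from == df$to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "first", "ignore"))
}

#' Read and write GMT-like gene-set annotation files
#'
#' Each line is `category<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return `read_gmt()`: a named list of character vectors of gene ids, with
#'   a `description` attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields (category, description, genes...)",
                 bad[1L]))
  }
  sets <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    attr(genes, "description") <- p[2L]
    genes
  })
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate category names in GMT file")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
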