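`%||%` <- function(a, b) if (is.null(a)) b else a

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# significance stars at the conventional 0.05 / 0.01 / 0.001 cutpoints
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

# expression matrix validator: genes x conditions, non-negative, unique ids
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression data must be a numeric matrix (genes x conditions)",
         call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene ids as rownames and condition ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression values must be finite and non-negative (linear RPKM-like scale)",
         call. = FALSE)
  }
  invisible(m)
}

# gene table validator: 1-based closed coordinates, mm9 annotation style
validate_gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stop("gene table must be a data frame with columns gene_id, chrom, start, end",
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in gene table", call. = FALSE)
  if (any(genes$start < 1) || any(genes$end < genes$start)) {
    stop("gene coordinates must satisfy start >= 1 and end >= start (1-based closed)",
         call. = FALSE)
  }
  invisible(genes)
}

validate_intervals <- function(x) {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("intervals must be a data frame with columns chrom, start, end", call. = FALSE)
  }
  if (any(x$start < 1) || any(x$end < x$start)) {
    stop("intervals must satisfy start >= 1 and end >= start (1-based closed)",
         call. = FALSE)
  }
  invisible(x)
}
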