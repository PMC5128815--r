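#' Expression matrix container
#'
#' A genes-by-samples abundance matrix with a scale marker that is tracked
#' through every transformation. Values on scale `"raw"` are non-negative
#' abundances (e.g. expected counts); after [normalize_log_cpm()] the scale
#' marker is `"log2"`.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames), no missing values.
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `expr_matrix`: the matrix with a `scale`
#'   attribute.
#' @export
expr_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (scale == "raw" && any(values < 0)) {
    stop("raw abundances must be non-negative")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(m) attr(m, "scale") %||% "raw"

# Subset preserving class/scale.
expr_subset <- function(m, genes = NULL, samples = NULL) {
  v <- unclass(m)
  attr(v, "scale") <- NULL
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expr_matrix(v, scale = expr_scale(m))
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers.
#'
#' @param path file path.
#' @return An [expr_matrix()] with scale `"raw"`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >=1 sample")
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric expression value at row ", bad,
           ", column '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expr_matrix(m, scale = "raw")
}

#' Write an expression matrix to TSV
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize raw abundances to log2 counts-per-million
#'
#' Computes `log2(1e6 * x / sample_total + 1)` per sample. The +1 offset keeps
#' zeros finite; after normalization the per-sample totals of `2^value - 1`
#' equal one million.
#'
#' @param m an [expr_matrix()] on the raw scale.
#' @return An [expr_matrix()] on the log2 scale.
#' @export
normalize_log_cpm <- function(m) {
  if (!inherits(m, "expr_matrix")) stop("not an expr_matrix")
  if (expr_scale(m) != "raw") stop("normalize_log_cpm expects scale = raw")
  totals <- colSums(m)
  zero <- colnames(m)[totals <= 0]
  if (length(zero)) {
    stop("sample(s) with zero total abundance: ", paste(zero, collapse = ", "))
  }
  v <- log2(sweep(unclass(m), 2L, totals, "/") * 1e6 + 1)
  attr(v, "scale") <- NULL
  expr_matrix(v, scale = "log2")
}
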