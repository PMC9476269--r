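#' Construct an expression matrix object
#'
#' An `ExpressionMatrix` is a genes x samples numeric matrix carrying a
#' declared measurement scale. Deconvolution requires linear-scale values
#' (TPM, FPKM, exponentiated microarray intensities); log2 matrices must be
#' converted with [to_linear()] first.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param scale `"linear"` or `"log2"`. Linear values must be non-negative.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from a delimited text file
#'
#' The first column holds gene identifiers and the header row sample
#' identifiers. Duplicated gene rows are collapsed by keeping the row with
#' the maximum mean expression (the usual microarray probe-collapse
#' convention); a message reports the collapsed identifiers.
#'
#' @param path path to a TSV/CSV file.
#' @param scale declared scale of the stored values (`"linear"` or `"log2"`).
#' @param delimiter field delimiter, default tab.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   delimiter = "\t") {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a gene-id column plus >= 1 sample column")
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L], bad[2L]], genes[bad[1L]], samples[bad[2L]]))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup), " duplicated gene id(s) by maximum ",
            "mean expression: ", paste(dup, collapse = ", "))
    keep <- vapply(split(seq_along(genes), genes)[unique(genes)],
                   function(idx) idx[which.max(rowMeans(num[idx, , drop = FALSE]))],
                   integer(1))
    num <- num[sort(keep), , drop = FALSE]
  }
  expression_matrix(num, scale)
}

#' Write an expression matrix to a delimited text file
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param delimiter field delimiter, default tab.
#' @param header_comment optional character vector written as `#`-prefixed
#'   lines before the table.
#' @export
write_expression_matrix <- function(m, path, delimiter = "\t",
                                    header_comment = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a log2 expression matrix to linear scale
#'
#' Microarray intensities are usually reported on log2 scale; deconvolution
#' operates on linear values, so log2 values are exponentiated (v -> 2^v).
#' Calling this on an already-linear matrix is an error to prevent silent
#' double exponentiation.
#'
#' @param m an [expression_matrix()] with `scale = "log2"`.
#' @return the matrix on linear scale.
#' @export
to_linear <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2")
    stop("matrix is already on linear scale; refusing to exponentiate again")
  expression_matrix(2^m$values, "linear")
}

#' Mean-center and standardize a numeric vector
#'
#' Standardization (mean 0, sample standard deviation 1, n-1 denominator)
#' is applied to each sample's signature-gene vector and to each signature
#' column before robust regression, which makes the deconvolution invariant
#' to overall expression scale.
#'
#' @param v numeric vector of length >= 2.
#' @return standardized vector.
#' @export
standardize_vector <- function(v) {
  if (!is.numeric(v) || length(v) < 2) stop("need a numeric vector of length >= 2")
  if (anyNA(v)) stop("vector contains NA")
  s <- stats::sd(v)
  if (s == 0 || !is.finite(s))
    stop("zero variance: vector is constant over the signature genes")
  (v - mean(v)) / s
}

#' Align an expression matrix to a signature's gene space
#'
#' Rows are subset and reordered to the signature's gene order. Signature
#' genes missing from the matrix are dropped from the run (reported via the
#' `dropped_genes` attribute); if fewer than `min_overlap_fraction` of the
#' signature genes are present the alignment fails.
#'
#' @param m a linear-scale [expression_matrix()].
#' @param sig a [signature_matrix] object.
#' @param min_overlap_fraction minimum fraction of signature genes that must
#'   be present in `m` (default 0.8).
#' @return an `ExpressionMatrix` restricted to the overlapping signature
#'   genes, in signature order, with attribute `dropped_genes`.
#' @export
align_to_signature <- function(m, sig, min_overlap_fraction = 0.8) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sig, "signature_matrix"))
  if (m$scale != "linear")
    stop("matrix must be on linear scale (use to_linear() first)")
  sig_genes <- rownames(sig$profiles)
  present <- sig_genes %in% rownames(m$values)
  missing <- sig_genes[!present]
  if (mean(present) < min_overlap_fraction)
    stop(sprintf(paste0("only %d of %d signature genes present ",
                        "(< %.0f%% overlap); missing: %s"),
                 sum(present), length(sig_genes),
                 100 * min_overlap_fraction,
                 paste(missing, collapse = ", ")))
  out <- expression_matrix(m$values[sig_genes[present], , drop = FALSE], "linear")
  attr(out, "dropped_genes") <- missing
  out
}
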