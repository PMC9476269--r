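#' Construct a subtype signature matrix
#'
#' A signature matrix holds, for each selected subtype-specific gene, the
#' median linear expression in each of the three RCC subtypes. It is the
#' design matrix of the deconvolution.
#'
#' @param profiles numeric matrix (3k genes x 3 subtypes) of median linear
#'   expression; columns named `ccRCC`, `pRCC`, `chRCC`.
#' @param per_subtype named list mapping each subtype to its k member genes.
#' @return an object of class `signature_matrix`.
#' @export
signature_matrix <- function(profiles, per_subtype) {
  if (!is.matrix(profiles) || !identical(colnames(profiles), RCC_SUBTYPES))
    stop("`profiles` must be a matrix with columns ", paste(RCC_SUBTYPES, collapse = ", "))
  if (is.null(rownames(profiles))) stop("`profiles` must have gene rownames")
  if (any(profiles < 0)) stop("median linear expression must be non-negative")
  if (!identical(sort(names(per_subtype)), sort(RCC_SUBTYPES)))
    stop("`per_subtype` must be named by the three subtypes")
  per_subtype <- per_subtype[RCC_SUBTYPES]
  sizes <- lengths(per_subtype)
  if (length(unique(sizes)) != 1L)
    stop("per-subtype gene sets must have equal size")
  all_genes <- unlist(per_subtype, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("per-subtype gene sets must be disjoint")
  if (!setequal(all_genes, rownames(profiles)) ||
      nrow(profiles) != length(all_genes))
    stop("profile rows must be exactly the union of the per-subtype sets")
  structure(list(profiles = profiles[all_genes, , drop = FALSE],
                 per_subtype = per_subtype, k = sizes[[1L]]),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes (%d per subtype) x 3 subtypes\n",
              nrow(x$profiles), x$k))
  invisible(x)
}

.check_labels <- function(labels, samples, min_per_subtype = 3L) {
  labels <- as.character(labels)
  if (length(labels) != length(samples))
    stop("need one subtype label per sample")
  bad <- setdiff(unique(labels), RCC_SUBTYPES)
  if (length(bad)) stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  n <- table(factor(labels, levels = RCC_SUBTYPES))
  if (any(n < min_per_subtype))
    stop("need >= ", min_per_subtype, " samples per subtype; got ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  labels
}

#' Select subtype-specific genes from a labeled training cohort
#'
#' A gene is specific to a subtype when its median linear expression exceeds
#' the median in *each* of the other two subtypes by at least `min_fold`
#' (a pseudocount of 1e-6 guards the denominators), and a one-sided
#' Wilcoxon rank-sum test against each other subtype is significant at
#' `alpha` after Holm correction. The Holm family is, per pairwise
#' contrast, the set of genes that passed the fold filter for that subtype.
#' Genes are ranked by the smaller of their two pairwise fold changes,
#' descending; ties break lexicographically by gene identifier.
#'
#' @param train linear-scale [expression_matrix()] of the training cohort.
#' @param labels subtype label per training sample (see [rcc_subtypes()]),
#'   at least 3 samples per subtype.
#' @param min_fold minimum pairwise median fold change (default 2).
#' @param alpha significance level for the Holm-corrected rank-sum filter
#'   (default 0.05).
#' @return named list (`ccRCC`, `pRCC`, `chRCC`) of ranked gene identifier
#'   vectors, each carrying the ranking fold changes as attribute
#'   `min_fold_change`. Empty vectors are legal.
#' @export
select_subtype_specific_genes <- function(train, labels, min_fold = 2,
                                          alpha = 0.05) {
  stopifnot(inherits(train, "ExpressionMatrix"))
  if (train$scale != "linear") stop("training matrix must be on linear scale")
  labels <- .check_labels(labels, colnames(train$values))
  eps <- 1e-6
  x <- train$values
  med <- sapply(RCC_SUBTYPES, function(s)
    apply(x[, labels == s, drop = FALSE], 1L, stats::median))
  out <- stats::setNames(vector("list", 3L), RCC_SUBTYPES)
  for (s in RCC_SUBTYPES) {
    others <- setdiff(RCC_SUBTYPES, s)
    fc <- pmin(med[, s] / (med[, others[1L]] + eps),
               med[, s] / (med[, others[2L]] + eps))
    cand <- rownames(x)[fc >= min_fold]
    if (length(cand)) {
      keep <- rep(TRUE, length(cand))
      for (o in others) {
        p <- vapply(cand, function(g)
          suppressWarnings(stats::wilcox.test(
            x[g, labels == s], x[g, labels == o],
            alternative = "greater", exact = FALSE)$p.value),
          numeric(1))
        keep <- keep & holm_adjust(p) < alpha
      }
      cand <- cand[keep]
    }
    key <- fc[cand]
    ord <- order(-key, cand)  # fold descending, gene id as tie-break
    ranked <- cand[ord]
    attr(ranked, "min_fold_change") <- unname(key[ord])
    out[[s]] <- ranked
  }
  out
}

#' Build the median-expression signature matrix
#'
#' Takes the top `k` ranked genes per subtype and records, for every
#' selected gene, the median linear expression over the training samples of
#' each subtype.
#'
#' @param train linear-scale [expression_matrix()] of the training cohort.
#' @param labels subtype label per training sample.
#' @param selected ranked per-subtype gene lists from
#'   [select_subtype_specific_genes()].
#' @param k genes per subtype; the resulting matrix has `3 * k` rows.
#' @return a [signature_matrix()].
#' @export
build_signature_matrix <- function(train, labels, selected, k) {
  stopifnot(inherits(train, "ExpressionMatrix"), k >= 1)
  labels <- .check_labels(labels, colnames(train$values))
  short <- names(selected)[lengths(selected) < k]
  if (length(short))
    stop("fewer than k = ", k, " ranked genes available for subtype(s): ",
         paste(short, collapse = ", "))
  per_subtype <- lapply(selected[RCC_SUBTYPES], function(g) as.character(g[seq_len(k)]))
  genes <- unlist(per_subtype, use.names = FALSE)
  x <- train$values[genes, , drop = FALSE]
  profiles <- sapply(RCC_SUBTYPES, function(s)
    apply(x[, labels == s, drop = FALSE], 1L, stats::median))
  rownames(profiles) <- genes
  signature_matrix(profiles, per_subtype)
}

#' Iteratively choose the signature size on a tuning cohort
#'
#' Candidate signatures with k = `start_k`, `start_k + step`, ... genes per
#' subtype are built from the training cohort and each is used to
#' deconvolve the tuning cohort. The change score of a candidate is the
#' mean per-sample L1 distance between the subtype proportions it assigns
#' and those of its predecessor. The selected signature is the largest k
#' whose change score still reaches `change_tol` (the last size at which
#' adding genes substantially moved the deconvolution); if no step moves
#' it, the smallest candidate is kept.
#'
#' @param train,labels training cohort and subtype labels.
#' @param tuning linear-scale [expression_matrix()] deconvolved by each
#'   candidate.
#' @param start_k,step,max_k size grid (defaults 2, 2, 100). The grid is
#'   truncated where a subtype runs out of ranked genes.
#' @param change_tol minimum mean L1 proportion shift counted as a
#'   substantial change (default 0.01).
#' @param min_fold,alpha passed to [select_subtype_specific_genes()].
#' @return the selected [signature_matrix()], with attributes `k` and
#'   `trace` (data frame of k and change score Delta).
#' @export
iterative_signature_selection <- function(train, labels, tuning,
                                          start_k = 2L, step = 2L,
                                          max_k = 100L, change_tol = 0.01,
                                          min_fold = 2, alpha = 0.05) {
  if (start_k < 2L) stop("start_k must be >= 2")
  if (max_k < start_k) stop("max_k must be >= start_k")
  selected <- select_subtype_specific_genes(train, labels, min_fold, alpha)
  k_cap <- min(lengths(selected))
  if (k_cap < start_k)
    stop("fewer than start_k = ", start_k, " genes selected for some subtype")
  ks <- seq.int(start_k, min(max_k, k_cap), by = step)
  sigs <- vector("list", length(ks))
  props <- vector("list", length(ks))
  delta <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    sigs[[i]] <- build_signature_matrix(train, labels, selected, ks[i])
    props[[i]] <- .cohort_proportions(tuning, sigs[[i]])
    if (i > 1L) {
      ok <- stats::complete.cases(props[[i]]) & stats::complete.cases(props[[i - 1L]])
      delta[i] <- mean(rowSums(abs(props[[i]][ok, , drop = FALSE] -
                                   props[[i - 1L]][ok, , drop = FALSE])))
    }
  }
  sel <- which(delta >= change_tol)
  pick <- if (length(sel)) max(sel) else 1L
  out <- sigs[[pick]]
  attr(out, "trace") <- data.frame(k = ks, delta = delta)
  out
}

# Deconvolve every sample of a cohort (no permutation test) and return an
# n x 3 matrix of proportions; failed samples become NA rows.
.cohort_proportions <- function(m, sig, min_overlap_fraction = 0.8) {
  al <- align_to_signature(m, sig, min_overlap_fraction)
  prof <- sig$profiles[rownames(al$values), , drop = FALSE]
  t(apply(al$values, 2L, function(v) {
    tryCatch(normalize_weights(.deconvolve_core(v, prof)$raw_weights),
             error = function(e) rep(NA_real_, 3L))
  }))
}

#' Write a signature matrix to TSV
#'
#' Columns: `gene_id`, `subtype` (the set the gene belongs to), and the
#' three median expression columns `median_ccRCC`, `median_pRCC`,
#' `median_chRCC`.
#'
#' @param sig a [signature_matrix()].
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  membership <- rep(names(sig$per_subtype), lengths(sig$per_subtype))
  names(membership) <- unlist(sig$per_subtype, use.names = FALSE)
  df <- data.frame(gene_id = rownames(sig$profiles),
                   subtype = unname(membership[rownames(sig$profiles)]),
                   median_ccRCC = sig$profiles[, "ccRCC"],
                   median_pRCC = sig$profiles[, "pRCC"],
                   median_chRCC = sig$profiles[, "chRCC"],
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix from TSV
#'
#' @param path TSV written by [write_signature()] (or a compatible file,
#'   e.g. a published gene list reformatted to the same columns).
#' @return a [signature_matrix()].
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "subtype", "median_ccRCC", "median_pRCC", "median_chRCC")
  if (!all(need %in% colnames(df)))
    stop("signature file must have columns: ", paste(need, collapse = ", "))
  profiles <- as.matrix(df[, c("median_ccRCC", "median_pRCC", "median_chRCC")])
  if (anyNA(profiles)) stop("signature file contains non-numeric medians")
  colnames(profiles) <- RCC_SUBTYPES
  rownames(profiles) <- df$gene_id
  per_subtype <- split(df$gene_id, factor(df$subtype, levels = RCC_SUBTYPES))
  signature_matrix(profiles, per_subtype)
}
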