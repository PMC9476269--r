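# FNV-1a hash of a string, as 8 hex digits; used to fingerprint a run
# configuration in output headers.
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Configuration of an end-to-end PSA run
#'
#' @param matrix_path expression matrix file (gene ids in the first column,
#'   sample ids in the header).
#' @param scale declared scale of the matrix (`"linear"` or `"log2"`;
#'   log2 input is exponentiated before deconvolution).
#' @param signature_path signature TSV (see [read_signature()]).
#' @param outdir output directory (created if absent).
#' @param seed integer seed; mandatory, drives every stochastic step.
#' @param survival_path optional survival TSV with columns `sample_id`,
#'   `time_years` (or `time`), `event`; enables risk-group discovery.
#' @param delimiter matrix field delimiter.
#' @param n_permutations permutations per sample for the PSA P-value.
#' @param p_cutoff,heterogeneity_threshold PSA call thresholds, in (0, 1).
#' @return a list of class `run_config`.
#' @export
run_config <- function(matrix_path, scale = c("linear", "log2"),
                       signature_path, outdir, seed,
                       survival_path = NULL, delimiter = "\t",
                       n_permutations = 999L, p_cutoff = 0.05,
                       heterogeneity_threshold = 0.95) {
  scale <- match.arg(scale)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  for (th in c(p_cutoff, heterogeneity_threshold))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  structure(list(matrix_path = matrix_path, scale = scale,
                 signature_path = signature_path, outdir = outdir,
                 seed = as.integer(seed), survival_path = survival_path,
                 delimiter = delimiter,
                 n_permutations = as.integer(n_permutations),
                 p_cutoff = p_cutoff,
                 heterogeneity_threshold = heterogeneity_threshold),
            class = "run_config")
}

#' Run the full PSA pipeline
#'
#' Reads and scale-converts the expression matrix, deconvolves every sample
#' against the signature ([psa_cohort()]), scores the ccRCC proportion with
#' the published prognostic model ([rccr_model()]), and — when survival
#' records are supplied — discovers risk-group cutpoints on the prognostic
#' index and assigns a risk group per sample. Writes `psa.tsv`,
#' `scored.tsv`, optionally `risk_groups.tsv`, and `run.log` to the output
#' directory; every table carries a header with the package version, seed,
#' and a configuration hash.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list of output paths and the in-memory tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$matrix_path, cfg$signature_path, cfg$survival_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("rccpsa"))
  hash <- .fnv1a(paste(deparse(unclass(cfg)), collapse = ""))
  meta <- c(sprintf("rccpsa %s", ver), sprintf("seed: %d", cfg$seed),
            sprintf("config: %s", hash))
  log_lines <- c(meta, sprintf("matrix: %s (%s scale)", cfg$matrix_path,
                               cfg$scale),
                 sprintf("signature: %s", cfg$signature_path),
                 sprintf("permutations: %d", cfg$n_permutations),
                 sprintf("thresholds: p_psa %.3g, heterogeneity %.3g",
                         cfg$p_cutoff, cfg$heterogeneity_threshold))

  m <- read_expression_matrix(cfg$matrix_path, cfg$scale, cfg$delimiter)
  if (m$scale == "log2") m <- to_linear(m)
  sig <- tryCatch(read_signature(cfg$signature_path),
                  error = function(e)
                    stop("stage signature: ", conditionMessage(e)))
  tab <- tryCatch(
    psa_cohort(m, sig, cfg$n_permutations, cfg$seed,
               cfg$heterogeneity_threshold, cfg$p_cutoff),
    error = function(e) stop("stage deconvolution: ", conditionMessage(e)))
  psa_path <- file.path(cfg$outdir, "psa.tsv")
  .write_tsv(tab, psa_path, meta)

  scored <- tab
  ok <- !is.na(scored$prop_cc)
  scored$pi <- NA_real_
  scored$pi[ok] <- prognostic_index(scored$prop_cc[ok])
  scored$hr <- hazard_ratio(ifelse(is.na(scored$pi), 0, scored$pi))
  scored$hr[!ok] <- NA_real_
  scored$risk_group <- NA_character_

  groups <- NULL
  if (!is.null(cfg$survival_path)) {
    sv <- utils::read.table(cfg$survival_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    tcol <- intersect(c("time_years", "time"), colnames(sv))[1L]
    if (is.na(tcol) || !all(c("sample_id", "event") %in% colnames(sv)))
      stop("stage survival: need columns sample_id, time_years (or time), event")
    idx <- match(scored$sample_id, sv$sample_id)
    use <- which(ok & !is.na(idx) & scored$p_psa <= cfg$p_cutoff)
    rec <- survival_records(sv[[tcol]][idx[use]], sv$event[idx[use]],
                            scored$sample_id[use])
    groups <- find_risk_cutpoints(scored$pi[use], rec)
    scored$risk_group[ok] <- assign_risk_group(scored$pi[ok], groups)
    gdf <- data.frame(interval = seq_along(groups$labels),
                      lower = c(-Inf, groups$cutpoints),
                      upper = c(groups$cutpoints, Inf),
                      label = groups$labels,
                      n = as.integer(groups$group_sizes),
                      hazard_ratio_vs_good =
                        unname(groups$hazard_ratio[groups$labels]),
                      stringsAsFactors = FALSE)
    .write_tsv(gdf, file.path(cfg$outdir, "risk_groups.tsv"), meta)
    log_lines <- c(log_lines,
                   sprintf("risk groups: %d (cutpoints: %s)",
                           length(groups$labels),
                           paste(sprintf("%.4g", groups$cutpoints),
                                 collapse = ", ")))
  }
  scored_path <- file.path(cfg$outdir, "scored.tsv")
  .write_tsv(scored, scored_path, meta)
  log_lines <- c(log_lines,
                 sprintf("samples: %d; significant: %d; heterogeneous: %d",
                         nrow(tab), sum(tab$p_psa <= cfg$p_cutoff, na.rm = TRUE),
                         sum(tab$call == "heterogeneous", na.rm = TRUE)))
  writeLines(log_lines, file.path(cfg$outdir, "run.log"))
  invisible(list(psa = psa_path, scored = scored_path,
                 risk_groups = if (is.null(groups)) NULL
                               else file.path(cfg$outdir, "risk_groups.tsv"),
                 log = file.path(cfg$outdir, "run.log"),
                 psa_table = tab, scored_table = scored, groups = groups))
}
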