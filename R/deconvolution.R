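#' Control parameters for the robust regression
#'
#' @param psi loss function: `"huber"` (default, tuning constant 1.345) or
#'   `"bisquare"` (Tukey, tuning constant 4.685).
#' @param k tuning constant; default depends on `psi`.
#' @param tol relative convergence tolerance of the IRLS iterations.
#' @param maxit maximum IRLS iterations. The default is generous because
#'   re-estimating the MAD residual scale each iteration makes the tail of
#'   the iteration geometric but slow on noisy samples.
#' @return a list of class `huber_control`.
#' @export
huber_control <- function(psi = c("huber", "bisquare"), k = NULL,
                          tol = 1e-8, maxit = 1000L) {
  psi <- match.arg(psi)
  if (is.null(k)) k <- if (psi == "huber") 1.345 else 4.685
  stopifnot(k > 0, tol > 0, maxit >= 1)
  structure(list(psi = psi, k = k, tol = tol, maxit = maxit),
            class = "huber_control")
}

# Core fit: standardize the linear sample vector and the signature columns,
# regress by Huber IRLS without intercept, and map the coefficients back to
# the linear mixing scale. For y = sum_i a_i * col_i the standardized
# regression has theta_i = a_i * sd(col_i) / sd(y), so the linear-scale
# weights are theta_i * sd(y) / sd(col_i); without the back-transformation
# the column scales would leak into the proportions.
.deconvolve_core <- function(sample, profiles, control = huber_control()) {
  if (length(sample) != nrow(profiles))
    stop("sample vector and signature gene space differ in length")
  y <- standardize_vector(sample)
  X <- apply(profiles, 2L, standardize_vector)
  if (qr(X)$rank < ncol(X))
    stop("singular design: signature columns are collinear after standardization")
  if (control$psi == "huber") {
    fit <- .huber_fit_cpp(X, y, k = control$k, tol = control$tol,
                          maxit = control$maxit)
    if (!fit$converged)
      stop("IRLS did not converge in ", fit$iterations, " iterations")
    w <- as.numeric(fit$coefficients)
    fitted <- as.numeric(fit$fitted)
  } else {
    fit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = control$k,
                     maxit = control$maxit, acc = control$tol)
    if (!fit$converged)
      stop("IRLS (bisquare) did not converge in ", control$maxit, " iterations")
    w <- unname(stats::coef(fit))
    fitted <- as.numeric(X %*% w)
  }
  w <- w * stats::sd(sample) / apply(profiles, 2L, stats::sd)
  names(w) <- colnames(profiles)
  fs <- suppressWarnings(stats::cor(fitted, y))
  list(raw_weights = w, fit_stat = if (is.finite(fs)) fs else 0,
       X = X, y = y)
}

#' Deconvolve one sample against a signature matrix
#'
#' The sample's linear expression over the signature genes and each
#' signature column are mean-centered and standardized, then the sample is
#' regressed on the three subtype columns by Huber M-estimation without
#' intercept (IRLS). The coefficients are mapped back to the linear mixing
#' scale (multiplied by `sd(sample) / sd(column)`), so a sample built as a
#' convex combination of signature columns returns exactly its mixing
#' coefficients. The goodness of fit is the Pearson correlation between
#' the fitted and the observed standardized vector.
#'
#' @param sample numeric vector of linear expression over the signature
#'   genes, in signature row order (see [align_to_signature()]).
#' @param sig a [signature_matrix()].
#' @param control a [huber_control()].
#' @return list with `raw_weights` (named length-3 regression coefficients)
#'   and `fit_stat` (correlation in `[-1, 1]`).
#' @export
deconvolve_sample <- function(sample, sig, control = huber_control()) {
  stopifnot(inherits(sig, "signature_matrix"))
  res <- .deconvolve_core(sample, sig$profiles, control)
  res[c("raw_weights", "fit_stat")]
}

#' Normalize regression weights into subtype proportions
#'
#' Negative weights are truncated to zero and the remainder rescaled to sum
#' to one, giving the proportional subtype composition (c, p, h).
#'
#' @param raw_weights numeric length-3 vector of regression weights.
#' @return named numeric vector `(c, p, h)` on the simplex.
#' @export
normalize_weights <- function(raw_weights) {
  if (length(raw_weights) != 3L || !is.numeric(raw_weights))
    stop("`raw_weights` must be a numeric vector of length 3")
  w <- pmax(raw_weights, 0)
  if (sum(w) <= 0)
    stop("non-decomposable sample: no positive subtype weight")
  stats::setNames(w / sum(w), c("c", "p", "h"))
}

#' Proportional subtype assignment of one sample
#'
#' Runs the robust deconvolution, normalizes the weights into proportions,
#' and attaches a permutation P-value: the sample's standardized
#' signature-gene values are permuted across gene positions
#' `n_permutations` times, each permuted vector is deconvolved, and the
#' null statistic is its fit correlation. The add-one estimator
#' `(1 + #(null >= observed)) / (n_permutations + 1)` guarantees p > 0.
#'
#' @param sample numeric vector of linear expression over the signature
#'   genes, in signature row order.
#' @param sig a [signature_matrix()].
#' @param n_permutations number of permutations, >= 99 (default 999).
#' @param seed integer seed for the permutations.
#' @param heterogeneity_threshold maximum-proportion cutoff below which the
#'   sample is called heterogeneous (default 0.95).
#' @param sample_id identifier carried into the result.
#' @param control a [huber_control()].
#' @return an object of class `psa_result`: `sample_id`, `raw_weights`,
#'   `proportions` (c, p, h), `fit_stat`, `p_psa`, `max_proportion`,
#'   `heterogeneous`, `n_permutations`, `seed`.
#' @export
psa <- function(sample, sig, n_permutations = 999L, seed = 1L,
                heterogeneity_threshold = 0.95, sample_id = "sample",
                control = huber_control()) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  core <- .deconvolve_core(sample, sig$profiles, control)
  # A sample with no positive weight (typically pure noise) still gets a
  # permutation P-value; its proportions are undefined and reported as NA.
  props <- tryCatch(normalize_weights(core$raw_weights),
                    error = function(e)
                      stats::setNames(rep(NA_real_, 3L), c("c", "p", "h")))
  n <- length(core$y)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(b) core$y[sample.int(n)], numeric(n))
  null_stats <- if (control$psi == "huber") {
    as.numeric(.huber_fit_stat_batch_cpp(
      core$X, perm, k = control$k, tol = control$tol, maxit = control$maxit))
  } else {
    apply(perm, 2L, function(yb) {
      fit <- MASS::rlm(core$X, yb, psi = MASS::psi.bisquare, c = control$k,
                       maxit = control$maxit, acc = control$tol)
      fs <- suppressWarnings(stats::cor(as.numeric(core$X %*% stats::coef(fit)), yb))
      if (is.finite(fs)) fs else 0
    })
  }
  p_psa <- (1 + sum(null_stats >= core$fit_stat)) / (n_permutations + 1)
  structure(list(sample_id = sample_id,
                 raw_weights = core$raw_weights,
                 proportions = props,
                 fit_stat = core$fit_stat,
                 p_psa = p_psa,
                 max_proportion = if (anyNA(props)) NA_real_ else max(props),
                 heterogeneous = if (anyNA(props)) NA
                                 else max(props) < heterogeneity_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA %s: c=%.3f p=%.3f h=%.3f  fit=%.3f  p_psa=%.4g%s\n",
              x$sample_id, x$proportions["c"], x$proportions["p"],
              x$proportions["h"], x$fit_stat, x$p_psa,
              if (x$heterogeneous) "  [heterogeneous]" else ""))
  invisible(x)
}

#' Classify a sample from its PSA result
#'
#' Samples whose permutation P-value exceeds `p_cutoff` are set aside as
#' `non-significant`; otherwise a sample is `unambiguous-<subtype>` when
#' its maximum proportion reaches `threshold`, and `heterogeneous` below.
#'
#' @param result a `psa_result` from [psa()].
#' @param threshold unique-assignment cutoff on the maximum proportion
#'   (default 0.95).
#' @param p_cutoff significance cutoff on the permutation P-value
#'   (default 0.05).
#' @return one of `"unambiguous-ccRCC"`, `"unambiguous-pRCC"`,
#'   `"unambiguous-chRCC"`, `"heterogeneous"`, `"non-significant"`, or
#'   `"non-decomposable"` (significant fit but no positive subtype weight).
#' @export
classify_heterogeneity <- function(result, threshold = 0.95, p_cutoff = 0.05) {
  stopifnot(inherits(result, "psa_result"))
  if (result$p_psa > p_cutoff) return("non-significant")
  if (is.na(result$max_proportion)) return("non-decomposable")
  if (result$max_proportion >= threshold) {
    s <- RCC_SUBTYPES[which.max(result$proportions)]
    return(paste0("unambiguous-", s))
  }
  "heterogeneous"
}

#' Proportional subtype assignment of a cohort
#'
#' Applies [psa()] to every sample of a linear-scale expression matrix.
#' Per-sample permutation seeds are derived deterministically from the
#' master seed and the sample index, so the result is reproducible and
#' independent of evaluation order. Per-sample failures (e.g. a constant
#' expression vector) are recorded in the `error` column rather than
#' aborting the run.
#'
#' @param m linear-scale [expression_matrix()].
#' @param sig a [signature_matrix()].
#' @param n_permutations permutations per sample (default 999).
#' @param seed master integer seed.
#' @param heterogeneity_threshold,p_cutoff cutoffs for the call column.
#' @param min_overlap_fraction passed to [align_to_signature()].
#' @param control a [huber_control()].
#' @return data frame with one row per sample: `sample_id`, `w_cc`, `w_p`,
#'   `w_h`, `prop_cc`, `prop_p`, `prop_h`, `fit_stat`, `p_psa`, `call`,
#'   `error`.
#' @export
psa_cohort <- function(m, sig, n_permutations = 999L, seed = 1L,
                       heterogeneity_threshold = 0.95, p_cutoff = 0.05,
                       min_overlap_fraction = 0.8,
                       control = huber_control()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "linear") stop("cohort matrix must be on linear scale")
  if (ncol(m$values) == 0L) stop("empty expression matrix")
  al <- align_to_signature(m, sig, min_overlap_fraction)
  sub_sig <- sig
  sub_sig$profiles <- sig$profiles[rownames(al$values), , drop = FALSE]
  ids <- colnames(al$values)
  rows <- lapply(seq_along(ids), function(i) {
    seed_i <- (as.integer(seed) + i) %% .Machine$integer.max
    tryCatch({
      r <- psa(al$values[, i], sub_sig, n_permutations, seed_i,
               heterogeneity_threshold, sample_id = ids[i], control = control)
      data.frame(sample_id = ids[i],
                 w_cc = r$raw_weights[["ccRCC"]],
                 w_p = r$raw_weights[["pRCC"]],
                 w_h = r$raw_weights[["chRCC"]],
                 prop_cc = r$proportions[["c"]],
                 prop_p = r$proportions[["p"]],
                 prop_h = r$proportions[["h"]],
                 fit_stat = r$fit_stat, p_psa = r$p_psa,
                 call = classify_heterogeneity(r, heterogeneity_threshold,
                                               p_cutoff),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample_id = ids[i], w_cc = NA_real_, w_p = NA_real_,
                 w_h = NA_real_, prop_cc = NA_real_, prop_p = NA_real_,
                 prop_h = NA_real_, fit_stat = NA_real_, p_psa = NA_real_,
                 call = NA_character_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error)))
    stop("deconvolution failed for every sample; first error: ", out$error[1L])
  n_sig <- sum(out$p_psa <= p_cutoff, na.rm = TRUE)
  n_het <- sum(out$call == "heterogeneous", na.rm = TRUE)
  message(sprintf("PSA: %d/%d samples significant (p_psa <= %.2g), %d heterogeneous",
                  n_sig, nrow(out), p_cutoff, n_het))
  out
}
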