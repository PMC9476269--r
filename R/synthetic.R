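#' Configuration of the synthetic RCC cohort generator
#'
#' The generator emulates the structure the deconvolution assumes: a shared
#' lognormal expression baseline, subtype-specific marker genes up-regulated
#' by a common fold, multiplicative lognormal measurement noise, a cohort
#' that mixes pure-subtype samples with Dirichlet-distributed composite
#' samples, and survival times whose hazard follows the prognostic index of
#' the ccRCC proportion.
#'
#' @param n_genes total genes including non-informative background
#'   (default 2000).
#' @param k_specific marker genes per subtype (default 58, the published
#'   signature size).
#' @param fold_effect up-regulation fold of a marker in its own subtype
#'   (default 8).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (default 0.05).
#' @param n_samples samples per simulated cohort (default 300).
#' @param mixed_fraction fraction of composite (Dirichlet-mixed) samples in
#'   a mixture cohort (default 0.3, echoing the reported share of
#'   molecularly heterogeneous tumors).
#' @param dirichlet_alpha Dirichlet concentration for composite samples
#'   (default `c(2, 2, 0.3)`: mixtures mostly of clear-cell and papillary
#'   character).
#' @param censoring_rate target fraction of censored survival records
#'   (default 0.3); must be < 1.
#' @param baseline_hazard baseline event rate per year (default 0.1);
#'   must be > 0.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, k_specific = 58L, fold_effect = 8,
                       noise_cv = 0.05, n_samples = 300L,
                       mixed_fraction = 0.3, dirichlet_alpha = c(2, 2, 0.3),
                       censoring_rate = 0.3, baseline_hazard = 0.1,
                       seed = 1L) {
  stopifnot(n_genes >= 3, k_specific >= 1, n_samples >= 3,
            fold_effect > 0, noise_cv >= 0,
            mixed_fraction >= 0, mixed_fraction <= 1,
            length(dirichlet_alpha) == 3L, all(dirichlet_alpha > 0))
  if (3L * k_specific > n_genes)
    stop("3 * k_specific exceeds n_genes: no room for background genes")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 k_specific = as.integer(k_specific),
                 fold_effect = fold_effect, noise_cv = noise_cv,
                 n_samples = as.integer(n_samples),
                 mixed_fraction = mixed_fraction,
                 dirichlet_alpha = dirichlet_alpha,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Multiplicative lognormal noise factors with mean 1 and the requested CV.
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a labeled reference cohort with planted subtype markers
#'
#' Background genes share a lognormal baseline across subtypes; each
#' subtype's `k_specific` marker genes are multiplied by `fold_effect` in
#' samples of that subtype only. Samples are split as evenly as possible
#' across the three subtypes.
#'
#' @param cfg a [sim_config()].
#' @return list: `expr` (linear [expression_matrix()]), `labels` (subtype
#'   per sample), `marker_sets` (ground-truth marker genes per subtype).
#' @export
simulate_reference_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  marker_sets <- list(
    ccRCC = genes[seq_len(cfg$k_specific)],
    pRCC = genes[cfg$k_specific + seq_len(cfg$k_specific)],
    chRCC = genes[2L * cfg$k_specific + seq_len(cfg$k_specific)])
  n_per <- diff(round(seq(0, cfg$n_samples, length.out = 4L)))
  labels <- rep(RCC_SUBTYPES, times = n_per)
  baseline <- stats::rlnorm(cfg$n_genes, meanlog = 3, sdlog = 1)
  vals <- matrix(baseline, nrow = cfg$n_genes, ncol = cfg$n_samples)
  for (s in RCC_SUBTYPES) {
    idx <- which(genes %in% marker_sets[[s]])
    vals[idx, labels == s] <- vals[idx, labels == s] * cfg$fold_effect
  }
  noise <- matrix(.lognormal_noise(length(vals), cfg$noise_cv),
                  nrow = nrow(vals))
  vals <- vals * noise
  dimnames(vals) <- list(genes, sprintf("R%03d", seq_len(cfg$n_samples)))
  list(expr = expression_matrix(vals, "linear"), labels = labels,
       marker_sets = marker_sets)
}

#' Simulate a mixture cohort from a signature matrix
#'
#' Each sample's signature-gene vector is the convex combination
#' `c * ccRCC + p * pRCC + h * chRCC` of the signature columns, multiplied
#' elementwise by lognormal noise. A fraction `1 - mixed_fraction` of the
#' samples are pure subtypes (point masses cycled over the three
#' subtypes); the rest draw (c, p, h) from the configured Dirichlet.
#' Optionally, non-informative background genes are appended so that
#' alignment to the signature has work to do.
#'
#' @param cfg a [sim_config()].
#' @param sig a [signature_matrix()].
#' @param proportions optional n x 3 matrix of (c, p, h) overriding the
#'   mixture law (rows must sum to 1).
#' @param include_background append `n_genes - nrow(sig)` background genes
#'   (default TRUE).
#' @return list: `expr` (linear [expression_matrix()]) and `proportions`
#'   (data frame `sample_id`, `c`, `p`, `h` of the true compositions).
#' @export
simulate_mixture_cohort <- function(cfg, sig, proportions = NULL,
                                    include_background = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sig, "signature_matrix"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  if (is.null(proportions)) {
    n_mixed <- round(n * cfg$mixed_fraction)
    n_pure <- n - n_mixed
    pure <- diag(3)[rep_len(seq_len(3L), n_pure), , drop = FALSE]
    mixed <- if (n_mixed > 0L) .rdirichlet(n_mixed, cfg$dirichlet_alpha)
             else matrix(numeric(0), ncol = 3L)
    proportions <- rbind(pure, mixed)[sample.int(n), , drop = FALSE]
  } else {
    proportions <- as.matrix(proportions)
    if (nrow(proportions) != n || ncol(proportions) != 3L)
      stop("`proportions` must be n_samples x 3")
    if (any(abs(rowSums(proportions) - 1) > 1e-8) || any(proportions < 0))
      stop("`proportions` rows must be non-negative and sum to 1")
  }
  colnames(proportions) <- c("c", "p", "h")
  vals <- sig$profiles %*% t(proportions)
  noise <- matrix(.lognormal_noise(length(vals), cfg$noise_cv),
                  nrow = nrow(vals))
  vals <- vals * noise
  ids <- sprintf("M%03d", seq_len(n))
  colnames(vals) <- ids
  if (include_background) {
    n_bg <- max(0L, cfg$n_genes - nrow(sig$profiles))
    if (n_bg > 0L) {
      bg <- matrix(stats::rlnorm(n_bg, meanlog = 3, sdlog = 1),
                   nrow = n_bg, ncol = n) *
        matrix(.lognormal_noise(n_bg * n, cfg$noise_cv), nrow = n_bg)
      rownames(bg) <- sprintf("bg%05d", seq_len(n_bg))
      colnames(bg) <- ids
      vals <- rbind(vals, bg)
    }
  }
  list(expr = expression_matrix(vals, "linear"),
       proportions = data.frame(sample_id = ids, proportions,
                                stringsAsFactors = FALSE))
}

#' Simulate cancer-specific survival driven by the prognostic index
#'
#' Event times are exponential with per-sample rate
#' `baseline_hazard * exp(PI(c))` where PI is the published cubic model
#' ([rccr_model()]). Independent uniform censoring on `(0, c_max)` is
#' applied, with `c_max` solved numerically so the expected censored
#' fraction matches `censoring_rate`.
#'
#' @param true_c ccRCC proportions in `[0, 1]`, one per sample.
#' @param cfg a [sim_config()].
#' @param model prognostic model mapping c to PI (default [rccr_model()]).
#' @return a [survival_records()] table with attribute `true_rate`.
#' @export
simulate_survival <- function(true_c, cfg, model = rccr_model()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(true_c < 0 | true_c > 1)) stop("true_c must lie in [0, 1]")
  set.seed(cfg$seed + 2L)
  rate <- cfg$baseline_hazard * hazard_ratio(prognostic_index(true_c, model))
  n <- length(true_c)
  event_time <- stats::rexp(n, rate)
  if (cfg$censoring_rate == 0) {
    rec <- survival_records(event_time, rep(1L, n))
  } else {
    # P(censored | rate r, C ~ U(0, cmax)) = (1 - exp(-r cmax)) / (r cmax)
    expected_cens <- function(cmax)
      mean((1 - exp(-rate * cmax)) / (rate * cmax))
    f <- function(log_cmax) expected_cens(exp(log_cmax)) - cfg$censoring_rate
    sol <- stats::uniroot(f, lower = log(1e-6), upper = log(1e6),
                          extendInt = "yes")
    cmax <- exp(sol$root)
    cens_time <- stats::runif(n, 0, cmax)
    rec <- survival_records(pmin(event_time, cens_time),
                            as.integer(event_time <= cens_time))
  }
  attr(rec, "true_rate") <- rate
  rec
}
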