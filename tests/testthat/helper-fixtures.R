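# Shared fixtures, built in code.

# 9-gene toy with three marker genes per subtype and n_per samples per
# subtype. Marker folds decrease within each subtype block (g1 > g2 > g3,
# ...), so top-k truncation is deterministic. A small deterministic jitter
# breaks rank ties in the rank-sum tests.
toy_marker_matrix <- function(n_per = 6, base_fold = 8, jitter_sd = 0.01,
                              seed = 301) {
  set.seed(seed)
  genes <- paste0("g", 1:9)
  labels <- rep(rcc_subtypes(), each = n_per)
  baseline <- 10
  vals <- matrix(baseline, nrow = 9, ncol = 3 * n_per,
                 dimnames = list(genes, paste0("s", seq_len(3 * n_per))))
  folds <- base_fold + c(2, 1, 0)  # within-subtype ranking
  for (j in 1:3) {
    s <- rcc_subtypes()[j]
    rows <- (j - 1) * 3 + 1:3
    for (i in 1:3) vals[rows[i], labels == s] <- baseline * folds[i]
  }
  vals <- vals * exp(matrix(rnorm(length(vals), 0, jitter_sd), nrow = 9))
  list(expr = expression_matrix(vals, "linear"), labels = labels)
}

# Small synthetic signature built through the package's own pipeline.
make_test_signature <- function(k = 10, n_genes = 400, n_samples = 60,
                                seed = 77) {
  cfg <- sim_config(n_genes = n_genes, k_specific = k, n_samples = n_samples,
                    seed = seed)
  ref <- simulate_reference_profiles(cfg)
  sel <- select_subtype_specific_genes(ref$expr, ref$labels)
  build_signature_matrix(ref$expr, ref$labels, sel, k)
}

# The packaged 174-gene synthetic signature.
packaged_signature <- function() {
  read_signature(system.file("extdata", "signature_synthetic_174.tsv",
                             package = "rccpsa"))
}

# Noiseless linear mixture of signature columns.
mix_sample <- function(sig, props) {
  as.numeric(sig$profiles %*% props)
}

# Efron partial log-likelihood for a single covariate, used as the
# brute-force oracle against the coxph-based fits.
efron_loglik_1d <- function(beta, x, time, event) {
  eta <- beta * x
  ll <- 0
  for (t in unique(time[event == 1])) {
    d_idx <- which(event == 1 & time == t)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_r <- sum(exp(eta[r_idx]))
    sum_d <- sum(exp(eta[d_idx]))
    ll <- ll + sum(eta[d_idx]) -
      sum(log(sum_r - (seq_len(d) - 1) / d * sum_d))
  }
  ll
}

# Synthetic psa_result for classification tests.
fake_psa_result <- function(props, p_psa, threshold = 0.95) {
  structure(list(sample_id = "x",
                 raw_weights = stats::setNames(props, rcc_subtypes()),
                 proportions = stats::setNames(props, c("c", "p", "h")),
                 fit_stat = 0.9, p_psa = p_psa,
                 max_proportion = max(props),
                 heterogeneous = max(props) < threshold,
                 n_permutations = 999L, seed = 1L),
            class = "psa_result")
}
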