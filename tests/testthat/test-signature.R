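test_that("planted subtype markers are recovered exactly", {
  toy <- toy_marker_matrix()
  sel <- select_subtype_specific_genes(toy$expr, toy$labels, min_fold = 2)
  expect_setequal(sel$ccRCC, paste0("g", 1:3))
  expect_setequal(sel$pRCC, paste0("g", 4:6))
  expect_setequal(sel$chRCC, paste0("g", 7:9))
})

test_that("a constant matrix and one-sided contrasts yield no selections", {
  vals <- matrix(7, nrow = 5, ncol = 9,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:9)))
  m <- expression_matrix(vals, "linear")
  labels <- rep(rcc_subtypes(), each = 3)
  sel <- select_subtype_specific_genes(m, labels, min_fold = 2)
  expect_true(all(lengths(sel) == 0L))

  # 8-fold up in ccRCC vs pRCC but equal to chRCC: specific to nothing
  toy <- toy_marker_matrix()
  vals2 <- toy$expr$values
  vals2["g1", toy$labels == "chRCC"] <- vals2["g1", toy$labels == "ccRCC"]
  sel2 <- select_subtype_specific_genes(expression_matrix(vals2, "linear"),
                                        toy$labels, min_fold = 2)
  expect_false("g1" %in% unlist(sel2))
})

test_that("selection needs >= 3 samples per subtype", {
  toy <- toy_marker_matrix()
  keep <- toy$labels != "chRCC" | seq_along(toy$labels) %in% which(toy$labels == "chRCC")[1:2]
  m <- expression_matrix(toy$expr$values[, keep], "linear")
  expect_error(select_subtype_specific_genes(m, toy$labels[keep]), ">= 3 samples")
})

test_that("signature building takes medians of the top-k ranked genes", {
  toy <- toy_marker_matrix()
  sel <- select_subtype_specific_genes(toy$expr, toy$labels, min_fold = 2)
  sig <- build_signature_matrix(toy$expr, toy$labels, sel, 2)
  expect_equal(nrow(sig$profiles), 6L)
  # folds decrease g1 > g2 > g3 within each subtype block
  expect_setequal(rownames(sig$profiles), paste0("g", c(1, 2, 4, 5, 7, 8)))
  # median check on a hand-built matrix
  vals <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("gA", paste0("s", 1:3)))
  vals <- rbind(gA = c(1, 2, 3, 8, 8, 8, 9, 9, 9),
                gB = c(1, 1, 1, 5, 6, 7, 2, 2, 2),
                gC = c(1, 1, 1, 2, 2, 2, 30, 40, 50))
  colnames(vals) <- paste0("s", 1:9)
  m <- expression_matrix(vals, "linear")
  labels <- rep(rcc_subtypes(), each = 3)
  sig2 <- build_signature_matrix(m, labels,
                                 list(ccRCC = "gA", pRCC = "gB", chRCC = "gC"),
                                 k = 1)
  expect_equal(unname(sig2$profiles["gA", ]), c(2, 8, 9))
  expect_equal(unname(sig2$profiles["gB", ]), c(1, 6, 2))
  expect_equal(unname(sig2$profiles["gC", ]), c(1, 2, 40))
  expect_error(build_signature_matrix(m, labels,
                                      list(ccRCC = "gA", pRCC = "gB",
                                           chRCC = "gC"), k = 2),
               "fewer than k")
})

test_that("selection is invariant to sample order and global scaling", {
  toy <- toy_marker_matrix()
  sel <- select_subtype_specific_genes(toy$expr, toy$labels)
  perm <- sample(ncol(toy$expr$values))
  m2 <- expression_matrix(toy$expr$values[, perm], "linear")
  sel2 <- select_subtype_specific_genes(m2, toy$labels[perm])
  expect_identical(lapply(sel, as.character), lapply(sel2, as.character))
  m3 <- expression_matrix(toy$expr$values * 37.5, "linear")
  sel3 <- select_subtype_specific_genes(m3, toy$labels)
  expect_identical(lapply(sel, as.character), lapply(sel3, as.character))
})

test_that("per-subtype gene sets of any signature are disjoint", {
  sig <- make_test_signature(k = 5, n_genes = 200, n_samples = 45, seed = 5)
  all_genes <- unlist(sig$per_subtype)
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_equal(nrow(sig$profiles), 15L)
})

test_that("iterative size selection stops at the start size on noiseless data", {
  cfg <- sim_config(n_genes = 200, k_specific = 12, n_samples = 45,
                    noise_cv = 0, seed = 9)
  ref <- simulate_reference_profiles(cfg)
  sel <- select_subtype_specific_genes(ref$expr, ref$labels)
  # tuning mixtures built noiselessly over the union of all candidate genes:
  # every candidate matrix explains them exactly, so no size step changes
  # the deconvolution
  sig_full <- build_signature_matrix(ref$expr, ref$labels, sel, 8)
  cfg_mix <- sim_config(n_genes = 24, k_specific = 8, n_samples = 30,
                        noise_cv = 0, seed = 10)
  mix <- simulate_mixture_cohort(cfg_mix, sig_full, include_background = FALSE)
  out <- iterative_signature_selection(ref$expr, ref$labels, mix$expr,
                                       start_k = 2, step = 2, max_k = 8,
                                       change_tol = 0.01)
  expect_equal(out$k, 2L)
  tr <- attr(out, "trace")
  expect_true(all(tr$delta[-1] < 0.01))
})

test_that("the size grid is enumerated as specified", {
  cfg <- sim_config(n_genes = 100, k_specific = 6, n_samples = 45, seed = 12)
  ref <- simulate_reference_profiles(cfg)
  sel <- select_subtype_specific_genes(ref$expr, ref$labels)
  sig_full <- build_signature_matrix(ref$expr, ref$labels, sel, 4)
  cfg_mix <- sim_config(n_genes = 12, k_specific = 4, n_samples = 30,
                        seed = 12)
  mix <- simulate_mixture_cohort(cfg_mix, sig_full, include_background = FALSE)
  out <- iterative_signature_selection(ref$expr, ref$labels, mix$expr,
                                       start_k = 2, step = 2, max_k = 4)
  tr <- attr(out, "trace")
  expect_equal(tr$k, c(2, 4))          # exactly two candidates
  expect_equal(sum(!is.na(tr$delta)), 1L)  # one Delta reported
  expect_error(iterative_signature_selection(ref$expr, ref$labels, mix$expr,
                                             start_k = 4, max_k = 2),
               "max_k")
})

test_that("signatures round-trip through the TSV serialization", {
  sig <- make_test_signature(k = 4, n_genes = 150, n_samples = 45, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$profiles, sig$profiles)
  expect_identical(back$per_subtype, sig$per_subtype)
})
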