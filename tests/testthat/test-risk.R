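test_that("the published cubic prognostic model evaluates correctly", {
  expect_equal(prognostic_index(0), -1.46)
  expect_equal(prognostic_index(1), 0, tolerance = 1e-12)
  expect_equal(prognostic_index(0.5), 1.05625)
  expect_error(prognostic_index(1.2), "out of")
  expect_error(prognostic_index(-0.1), "out of")
  # risk peaks at an interior mixed composition
  opt <- optimize(prognostic_index, c(0, 1), maximum = TRUE)
  expect_gt(opt$maximum, 0.3)
  expect_lt(opt$maximum, 0.5)
  expect_gt(prognostic_index(1), prognostic_index(0))
})

test_that("hazard ratios exponentiate the prognostic index", {
  expect_equal(hazard_ratio(0), 1)
  expect_equal(hazard_ratio(log(2)), 2)
  expect_equal(hazard_ratio(-1.46), exp(-1.46))
  expect_equal(hazard_ratio(2.5, 2.5), 1)
})

test_that("Holm adjustment matches the step-down hand computation", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("the RCS basis is linear beyond the boundary knots", {
  knots <- c(0.1, 0.4, 0.6, 0.9)
  x <- seq(1.5, 3, by = 0.1)  # beyond the last knot
  B <- rcs_basis(x, knots)
  for (j in seq_len(ncol(B))) {
    d2 <- diff(diff(B[, j]))
    expect_lt(max(abs(d2)), 1e-10)
  }
  expect_equal(ncol(B), 3L)
  expect_error(rcs_basis(x, c(0.5, 0.1)), "increasing")
})

test_that("Cox fitting matches a brute-force partial-likelihood grid", {
  set.seed(42)
  n <- 10
  x <- rnorm(n)
  time <- rexp(n, exp(0.8 * x))
  time <- time + seq_len(n) * 1e-4  # distinct times
  sv <- survival_records(time, rep(1, n))
  cand <- cox_candidate("lin", x, form = "linear")
  fit <- rccpsa:::.fit_candidate(cand, sv)
  grid <- optimize(function(b) efron_loglik_1d(b, x, sv$time, sv$event),
                   c(-5, 5), maximum = TRUE, tol = 1e-8)
  expect_equal(fit$beta, grid$maximum, tolerance = 1e-3)
  expect_equal(fit$loglik, grid$objective, tolerance = 1e-6)
  # internal fixed-lp likelihood agrees with coxph at the fitted coefficients
  expect_equal(rccpsa:::.efron_loglik(fit$beta * x, sv$time, sv$event),
               fit$loglik, tolerance = 1e-8)
})

test_that("score models center the PI and reject degenerate inputs", {
  set.seed(7)
  cfg <- sim_config(n_samples = 400, seed = 7)
  cvals <- runif(400)
  sv <- simulate_survival(cvals, cfg)
  m <- fit_cox_score_model(cvals, sv)
  expect_equal(mean(prognostic_index(cvals, m)), 0, tolerance = 1e-10)
  expect_length(m$coefficients, 3L)
  expect_error(fit_cox_score_model(cvals, survival_records(sv$time, rep(0, 400))),
               "no events")
  expect_error(fit_cox_score_model(rep(0.5, 400), sv), "constant")
  mr <- fit_cox_score_model(cvals, sv, "restricted_cubic_spline")
  expect_length(mr$coefficients, 3L)  # 4 knots -> 3 basis terms
  expect_equal(mean(prognostic_index(cvals, mr)), 0, tolerance = 1e-10)
})

test_that("null scores produce coefficients indistinguishable from zero", {
  set.seed(16)
  n <- 500
  cvals <- runif(n)
  sv <- survival_records(rexp(n, 0.2), rbinom(n, 1, 0.7))
  m <- fit_cox_score_model(cvals, sv)
  expect_true(all(abs(m$coefficients) <= 2 * attr(m, "se")))
})

test_that("analysis of deviance behaves on identical and nested models", {
  set.seed(23)
  cfg <- sim_config(n_samples = 800, seed = 23)
  cvals <- runif(800)
  sv <- simulate_survival(cvals, cfg)
  cub <- cox_candidate("cubic", cvals, "cubic_polynomial")
  nul <- cox_candidate("null", NULL)
  same <- compare_nested_models(cub, cub, sv)
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$df, 0L)
  expect_equal(same$p_value, 1)
  lrt <- compare_nested_models(nul, cub, sv)
  expect_equal(lrt$df, 3L)  # constant not counted
  expect_lt(lrt$p_value, 0.01)
  lin <- cox_candidate("other", rnorm(800), "linear")
  expect_error(compare_nested_models(lin, cub, sv), "not nested")
})

test_that("cross-validated comparison prefers the generating model", {
  set.seed(31)
  cfg <- sim_config(n_samples = 400, seed = 31)
  cvals <- runif(400)
  sv <- simulate_survival(cvals, cfg)
  cands <- list(cox_candidate("cubic", cvals, "cubic_polynomial"),
                cox_candidate("null", NULL))
  tab <- compare_models_cv(cands, sv, folds = 10, repeats = 2, seed = 99)
  expect_equal(tab$candidate[1], "cubic")
  expect_gt(tab$cv_loglik[tab$candidate == "cubic"],
            tab$cv_loglik[tab$candidate == "null"])
  expect_gt(tab$cindex[tab$candidate == "cubic"], 0.5)
  expect_lt(tab$aic[tab$candidate == "cubic"],
            tab$aic[tab$candidate == "null"])
  # identical specs with the same seed give identical metrics
  tab2 <- compare_models_cv(list(cox_candidate("a", cvals, "cubic_polynomial"),
                                 cox_candidate("b", cvals, "cubic_polynomial")),
                            sv, folds = 5, repeats = 1, seed = 4)
  expect_equal(tab2$cv_loglik[1], tab2$cv_loglik[2])
  expect_equal(tab2$cindex[1], tab2$cindex[2])
})

test_that("leave-one-out on tiny all-event data stays finite", {
  set.seed(3)
  n <- 12
  x <- rnorm(n)
  sv <- survival_records(rexp(n, exp(0.5 * x)), rep(1, n))
  tab <- compare_models_cv(list(cox_candidate("lin", x, "linear")), sv,
                           folds = n, repeats = 1, seed = 2)
  expect_true(all(is.finite(unlist(tab[, c("cv_loglik", "cindex", "aic")]))))
})

test_that("cutpoint discovery finds planted strata and honors null data", {
  set.seed(51)
  pi3 <- runif(600, -2, 2)
  b <- c(-0.75, 0.75)
  rate <- 0.1 * c(1, 4, 10)[findInterval(pi3, b) + 1]
  tm <- rexp(600, rate)
  cens <- runif(600, 0, 15)
  sv <- survival_records(pmin(tm, cens), as.integer(tm <= cens))
  g <- find_risk_cutpoints(pi3, sv)
  expect_length(g$cutpoints, 2L)
  expect_lt(max(abs(g$cutpoints - b)), 0.15)
  expect_identical(g$labels, c("good", "intermediate", "poor"))
  expect_true(all(diff(g$hazard_ratio[c("good", "intermediate", "poor")]) > 0))
  # survival independent of PI: no split
  sv0 <- survival_records(rexp(600, 0.2), rbinom(600, 1, 0.8))
  expect_message(g0 <- find_risk_cutpoints(runif(600, -2, 2), sv0),
                 "single risk group")
  expect_true(g0$single_group)
  expect_length(g0$cutpoints, 0L)
})

test_that("risk-group assignment sends boundaries to the lower-risk side", {
  g <- structure(list(cutpoints = c(-1, 1),
                      labels = c("good", "intermediate", "poor"),
                      group_sizes = c(good = 10L, intermediate = 10L, poor = 10L),
                      hazard_ratio = c(good = 1, intermediate = 3, poor = 9),
                      split_p = c(0.001, 0.01),
                      crude_hazard = c(good = 0.1, intermediate = 0.3,
                                       poor = 0.9),
                      single_group = FALSE), class = "risk_groups")
  expect_equal(assign_risk_group(c(-2, 0, 2), g),
               c("good", "intermediate", "poor"))
  expect_equal(assign_risk_group(c(-1, 1), g), c("good", "intermediate"))
})

test_that("log-rank machinery is calibrated and powered", {
  # type-I error under identical exponential arms
  set.seed(61)
  reps <- 1000
  hits <- 0L
  for (i in seq_len(reps)) {
    sv <- survival_records(rexp(200, 0.3), rep(1, 200))
    p <- km_logrank(rep(c("A", "B"), each = 100), sv)$logrank$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
  # power under a 3x hazard difference
  set.seed(62)
  detect <- 0L
  for (i in 1:200) {
    tm <- c(rexp(200, 0.2), rexp(200, 0.6))
    sv <- survival_records(tm, rep(1, 400))
    p <- km_logrank(rep(c("A", "B"), each = 200), sv)$logrank$p_value
    if (p < 0.001) detect <- detect + 1L
  }
  expect_gte(detect / 200, 0.95)
})

test_that("the KM estimator without censoring equals the empirical survival", {
  set.seed(71)
  tm <- rexp(50, 0.5)
  sv <- survival_records(tm, rep(1, 50))
  expect_warning(km_logrank(rep("A", 50), sv), ">= 2")
  km <- suppressWarnings(km_logrank(rep("A", 50), sv)$km)
  emp <- sapply(km$time, function(t) mean(tm > t))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  # per-group hazard ratios against the stated reference
  sv2 <- survival_records(c(rexp(100, 0.2), rexp(100, 0.6)), rep(1, 200))
  res <- km_logrank(rep(c("A", "B"), each = 100), sv2, reference = "A")
  expect_equal(unname(res$hazard_ratio["A"]), 1)
  expect_gt(unname(res$hazard_ratio["B"]), 1.5)
})
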