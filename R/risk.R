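#' Survival records
#'
#' Validates a cancer-specific-survival table: follow-up time (years from
#' surgery) and an event indicator (1 = cancer-specific death; deaths from
#' other causes are censored at the time of death, i.e. event = 0).
#'
#' @param time non-negative follow-up times in years.
#' @param event 0/1 (or logical) event indicators.
#' @param sample_id optional identifiers (default `s1`, `s2`, ...).
#' @return data frame of class `survival_records` with columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_records <- function(time, event, sample_id = NULL) {
  event <- as.integer(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop("survival records contain NA")
  if (any(time < 0)) stop("follow-up times must be >= 0")
  if (!all(event %in% c(0L, 1L))) stop("event indicator must be 0 or 1")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_along(time))
  structure(data.frame(sample_id = as.character(sample_id), time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' The published RCC-R prognostic model
#'
#' The fixed cubic-polynomial mapping from the assigned ccRCC proportion c
#' (the RCC-R score, on the 0-1 scale) to the prognostic index:
#' PI = 14.71 c - 25.46 c^2 + 12.21 c^3 - 1.46. The PI is the linear
#' predictor of a Cox model, so exp(PI) is a hazard ratio against the
#' cohort average.
#'
#' @return a `prognostic_model` of form `cubic_polynomial`.
#' @export
rccr_model <- function() {
  prognostic_model(form = "cubic_polynomial",
                   coefficients = c(c = 14.71, c2 = -25.46, c3 = 12.21),
                   constant = -1.46, covariate = "ccRCC proportion")
}

#' Construct a prognostic model
#'
#' @param form `"cubic_polynomial"` (coefficients for c, c^2, c^3) or
#'   `"restricted_cubic_spline"` (coefficients for the truncated-power RCS
#'   basis; `knots` required, strictly increasing).
#' @param coefficients named numeric coefficients of the basis terms.
#' @param constant additive centering constant of the linear predictor.
#' @param covariate description of the score the model consumes.
#' @param knots RCS knot locations (ignored for the cubic form).
#' @return an object of class `prognostic_model`.
#' @export
prognostic_model <- function(form = c("cubic_polynomial",
                                      "restricted_cubic_spline"),
                             coefficients, constant = 0, covariate = "score",
                             knots = NULL) {
  form <- match.arg(form)
  if (form == "cubic_polynomial") {
    if (length(coefficients) != 3L)
      stop("cubic form needs exactly 3 basis coefficients (c, c^2, c^3)")
  } else {
    if (is.null(knots) || length(knots) < 3L || is.unsorted(knots, strictly = TRUE))
      stop("RCS form needs >= 3 strictly increasing knots")
    if (length(coefficients) != length(knots) - 1L)
      stop("RCS with k knots has k - 1 basis coefficients")
  }
  structure(list(form = form, coefficients = coefficients,
                 constant = constant, covariate = covariate, knots = knots),
            class = "prognostic_model")
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("prognostic_model (%s) on %s\n", x$form, x$covariate))
  cat("  coefficients:", paste(sprintf("%s=%.4g", names(x$coefficients),
                                       x$coefficients), collapse = ", "),
      sprintf(" constant=%.4g\n", x$constant))
  invisible(x)
}

#' Restricted cubic spline basis (truncated power form)
#'
#' Harrell's parameterization: the first column is x itself, followed by
#' k - 2 nonlinear terms that are linear beyond the boundary knots; scaled
#' by the squared knot span.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot locations (>= 3).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || is.unsorted(knots, strictly = TRUE))
    stop("need >= 3 strictly increasing knots")
  pos3 <- function(u) pmax(u, 0)^3
  scale2 <- (knots[k] - knots[1L])^2
  nl <- sapply(seq_len(k - 2L), function(j) {
    (pos3(x - knots[j]) -
       pos3(x - knots[k - 1L]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1L]) +
       pos3(x - knots[k]) * (knots[k - 1L] - knots[j]) / (knots[k] - knots[k - 1L])) /
      scale2
  })
  out <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(out) <- c("x", paste0("x'", seq_len(k - 2L)))
  out
}

# Default Harrell quantile positions for RCS knots.
.rcs_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         stop("supported knot counts: 3, 4, 5"))
}

# Design matrix for a score vector under a model form.
.score_design <- function(scores, form, knots = NULL) {
  if (form == "cubic_polynomial") {
    X <- cbind(c = scores, c2 = scores^2, c3 = scores^3)
  } else {
    X <- rcs_basis(scores, knots)
  }
  X
}

#' Prognostic index of a ccRCC proportion
#'
#' Evaluates a prognostic model at score value(s) `c`. The default model is
#' the published fixed cubic [rccr_model()].
#'
#' @param c numeric score(s) in `[0, 1]` (a subtype proportion).
#' @param model a [prognostic_model()].
#' @return numeric prognostic index (log relative hazard).
#' @export
prognostic_index <- function(c, model = rccr_model()) {
  stopifnot(inherits(model, "prognostic_model"))
  if (!is.numeric(c) || anyNA(c)) stop("scores must be numeric without NA")
  if (any(c < 0 | c > 1))
    stop("score out of [0, 1]: the RCC-R score is a proportion")
  X <- .score_design(c, model$form, model$knots)
  as.numeric(X %*% model$coefficients + model$constant)
}

#' Hazard ratio of a prognostic index
#'
#' @param pi prognostic index value(s).
#' @param pi_reference reference index (default 0, the cohort average under
#'   a mean-centered PI).
#' @return `exp(pi - pi_reference)`.
#' @export
hazard_ratio <- function(pi, pi_reference = 0) {
  stopifnot(is.numeric(pi), is.numeric(pi_reference),
            all(is.finite(pi)), all(is.finite(pi_reference)))
  exp(pi - pi_reference)
}

#' Fit a Cox prognostic model on a subtype score
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) of survival
#' on a polynomial or restricted-cubic-spline transform of the score, and
#' returns a [prognostic_model()] whose constant is chosen so the fitted
#' prognostic index has mean zero over the training samples. If the partial
#' likelihood is monotone (perfect separation) the fit falls back to a
#' lightly ridge-penalized model with a warning.
#'
#' @param scores numeric score per sample (e.g. the ccRCC proportion).
#' @param survival a [survival_records()] table aligned with `scores`.
#' @param form `"cubic_polynomial"` (default) or
#'   `"restricted_cubic_spline"`.
#' @param knots number of RCS knots (default 4, placed at the Harrell
#'   quantiles 0.05/0.35/0.65/0.95 of the scores).
#' @return a `prognostic_model` with attributes `fit` (the `coxph` object)
#'   and `se` (coefficient standard errors).
#' @export
fit_cox_score_model <- function(scores, survival,
                                form = c("cubic_polynomial",
                                         "restricted_cubic_spline"),
                                knots = 4L) {
  form <- match.arg(form)
  stopifnot(inherits(survival, "survival_records"))
  if (length(scores) != nrow(survival))
    stop("scores and survival records differ in length")
  if (sum(survival$event) == 0L) stop("no events: Cox model cannot be fit")
  if (sum(survival$event) < 10L) stop("need >= 10 events to fit the score model")
  if (stats::sd(scores) == 0) stop("scores are constant")
  knot_loc <- if (form == "restricted_cubic_spline")
    unname(stats::quantile(scores, .rcs_quantiles(knots))) else NULL
  X <- .score_design(scores, form, knot_loc)
  y <- survival::Surv(survival$time, survival$event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(y ~ X, ties = "efron", control = ctrl),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || any(!is.finite(stats::coef(fit)))) {
    warning("monotone partial likelihood detected; refitting with a small ridge penalty")
    fit <- survival::coxph(y ~ survival::ridge(X, theta = 1e-4),
                           ties = "efron", control = ctrl)
  }
  beta <- unname(stats::coef(fit))
  if (any(!is.finite(beta))) stop("Cox fit did not converge")
  coefs <- stats::setNames(beta, colnames(X))
  constant <- -sum(beta * colMeans(X))  # center the PI on the cohort
  out <- prognostic_model(form, coefs, constant,
                          covariate = deparse(substitute(scores)),
                          knots = knot_loc)
  attr(out, "fit") <- fit
  attr(out, "se") <- sqrt(diag(stats::vcov(fit)))
  out
}

#' Specify a Cox model candidate for comparison
#'
#' @param name label used in comparison tables.
#' @param scores score vector, or NULL for the null (intercept-only) model.
#' @param form model form for the score (ignored for the null model);
#'   `"linear"` uses the raw score as single covariate.
#' @param knots RCS knot count.
#' @return a list of class `cox_candidate` carrying the design matrix.
#' @export
cox_candidate <- function(name, scores = NULL,
                          form = c("cubic_polynomial", "linear",
                                   "restricted_cubic_spline"),
                          knots = 4L) {
  form <- match.arg(form)
  X <- NULL
  if (!is.null(scores)) {
    X <- if (form == "linear") cbind(c = scores)
         else .score_design(scores, form,
                            if (form == "restricted_cubic_spline")
                              unname(stats::quantile(scores, .rcs_quantiles(knots)))
                            else NULL)
    colnames(X) <- paste0(name, ".", colnames(X))
  }
  structure(list(name = name, design = X), class = "cox_candidate")
}

# Efron partial log-likelihood of a null Cox model (all linear predictors 0).
.null_cox_loglik <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ll <- 0
  for (t in unique(time[event == 1L])) {
    d <- sum(event == 1L & time == t)
    r <- sum(time >= t)
    ll <- ll - sum(log(r - seq_len(d) + 1L))
  }
  ll
}

# Fit a candidate on (a subset of) the data; returns loglik, beta, nparams.
.fit_candidate <- function(cand, survival, idx = seq_len(nrow(survival))) {
  y <- survival::Surv(survival$time[idx], survival$event[idx])
  if (is.null(cand$design))
    return(list(loglik = .null_cox_loglik(survival$time[idx],
                                          survival$event[idx]),
                beta = numeric(0), nparams = 0L))
  X <- cand$design[idx, , drop = FALSE]
  fit <- survival::coxph(y ~ X, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- unname(stats::coef(fit))
  if (any(!is.finite(beta))) stop("candidate '", cand$name, "' did not converge")
  list(loglik = fit$loglik[2L], beta = beta, nparams = ncol(X))
}

# Efron partial log-likelihood at fixed linear predictors.
.efron_loglik <- function(lp, time, event) {
  elp <- exp(lp)
  ll <- 0
  for (t in unique(time[event == 1L])) {
    d_idx <- which(event == 1L & time == t)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_r <- sum(elp[r_idx])
    sum_d <- sum(elp[d_idx])
    ll <- ll + sum(lp[d_idx]) -
      sum(log(sum_r - (seq_len(d) - 1L) / d * sum_d))
  }
  ll
}

#' Compare Cox model candidates by repeated cross-validation
#'
#' Candidates (see [cox_candidate()]) are compared by repeated k-fold
#' cross-validation with fold assignment stratified by event status.
#' The held-out partial log-likelihood uses the Verweij-van Houwelingen
#' construction (full-data likelihood at the fold's coefficients minus the
#' training-fold likelihood), which remains defined down to leave-one-out
#' folds; the C-index is Harrell's concordance of the pooled held-out
#' linear predictors. The full-data AIC (-2 logPL + 2 parameters) is
#' reported alongside.
#'
#' @param candidates list of [cox_candidate()] objects.
#' @param survival a [survival_records()] table.
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed for the fold assignments.
#' @param criterion ranking criterion: `"cv_loglik"`, `"cindex"`, `"aic"`.
#' @return data frame, one row per candidate, ranked best first; candidates
#'   failing on more than 20% of folds are dropped with a warning.
#' @export
compare_models_cv <- function(candidates, survival, folds = 10L,
                              repeats = 10L, seed = 1L,
                              criterion = c("cv_loglik", "cindex", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(survival, "survival_records"))
  n <- nrow(survival)
  if (sum(survival$event) < folds)
    stop("need at least as many events as folds")
  set.seed(seed)
  assign_folds <- function() {
    f <- integer(n)
    for (grp in split(seq_len(n), survival$event))
      f[grp] <- sample(rep_len(seq_len(folds), length(grp)))
    f
  }
  fold_sets <- replicate(repeats, assign_folds(), simplify = FALSE)
  rows <- lapply(candidates, function(cand) {
    cvll <- c(); cvc <- c(); fails <- 0L; total <- 0L
    for (f in fold_sets) {
      rep_ll <- 0
      lp_pooled <- rep(NA_real_, n)
      rep_ok <- TRUE
      for (j in seq_len(folds)) {
        test <- which(f == j); train <- which(f != j)
        if (length(test) == 0L) next
        total <- total + 1L
        res <- tryCatch({
          ft <- .fit_candidate(cand, survival, train)
          lp_all <- if (ft$nparams == 0L) rep(0, n)
                    else as.numeric(cand$design %*% ft$beta)
          ll <- .efron_loglik(lp_all, survival$time, survival$event) -
            .efron_loglik(lp_all[train], survival$time[train],
                          survival$event[train])
          list(ll = ll, lp_test = lp_all[test])
        }, error = function(e) NULL)
        if (is.null(res)) { fails <- fails + 1L; rep_ok <- FALSE }
        else { rep_ll <- rep_ll + res$ll; lp_pooled[test] <- res$lp_test }
      }
      if (rep_ok) {
        cvll <- c(cvll, rep_ll)
        cvc <- c(cvc, if (is.null(cand$design) || stats::sd(lp_pooled) == 0) 0.5
                 else survival::concordance(
                   survival::Surv(survival$time, survival$event) ~ lp_pooled,
                   reverse = TRUE)$concordance)
      }
    }
    if (total > 0L && fails / total > 0.2) {
      warning("candidate '", cand$name, "' failed on ", fails, "/", total,
              " folds; excluded")
      return(NULL)
    }
    full <- .fit_candidate(cand, survival)
    data.frame(candidate = cand$name, n_params = full$nparams,
               cv_loglik = mean(cvll), cindex = mean(cvc),
               aic = -2 * full$loglik + 2 * full$nparams,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no candidate could be evaluated")
  ord <- switch(criterion,
                cv_loglik = order(-out$cv_loglik),
                cindex = order(-out$cindex),
                aic = order(out$aic))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analysis of deviance for nested Cox models
#'
#' Likelihood-ratio comparison of two nested candidates: the statistic is
#' twice the gain in Efron partial log-likelihood, with degrees of freedom
#' equal to the difference in parameter count.
#'
#' @param small,large [cox_candidate()] objects; every design column of
#'   `small` must appear in `large`.
#' @param survival a [survival_records()] table.
#' @return list with `statistic`, `df`, `p_value`, and the two partial
#'   log-likelihoods.
#' @export
compare_nested_models <- function(small, large, survival) {
  stopifnot(inherits(small, "cox_candidate"), inherits(large, "cox_candidate"))
  small_cols <- colnames(small$design)
  large_cols <- colnames(large$design)
  if (!is.null(small$design)) {
    if (is.null(large$design) || !all(small_cols %in% large_cols))
      stop("models are not nested: '", small$name,
           "' has terms absent from '", large$name, "'")
    if (!isTRUE(all.equal(small$design,
                          large$design[, small_cols, drop = FALSE],
                          check.attributes = FALSE)))
      stop("models are not nested: shared terms differ in values")
  }
  fs <- .fit_candidate(small, survival)
  fl <- .fit_candidate(large, survival)
  stat <- max(0, 2 * (fl$loglik - fs$loglik))
  df <- fl$nparams - fs$nparams
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       loglik_small = fs$loglik, loglik_large = fl$loglik)
}

# Best log-rank split of pi[idx]: candidates are midpoints between
# consecutive distinct values leaving >= min_leaf on each side; the best
# split's asymptotic chi-square(1) P is Bonferroni-adjusted over the number
# of candidates evaluated.
.best_logrank_split <- function(pi, survival, idx, min_leaf) {
  v <- sort(unique(pi[idx]))
  if (length(v) < 2L) return(NULL)
  cuts <- (v[-1L] + v[-length(v)]) / 2
  ok <- vapply(cuts, function(ct) {
    nl <- sum(pi[idx] <= ct)
    nl >= min_leaf && (length(idx) - nl) >= min_leaf
  }, logical(1))
  cuts <- cuts[ok]
  if (!length(cuts)) return(NULL)
  y <- survival::Surv(survival$time[idx], survival$event[idx])
  stats <- vapply(cuts, function(ct) {
    g <- factor(pi[idx] <= ct)
    sd <- tryCatch(survival::survdiff(y ~ g), error = function(e) NULL)
    if (is.null(sd)) NA_real_ else sd$chisq
  }, numeric(1))
  if (all(is.na(stats))) return(NULL)
  best <- which.max(stats)
  p <- stats::pchisq(stats[best], df = 1, lower.tail = FALSE)
  list(cut = cuts[best], statistic = stats[best],
       p_adjusted = min(1, p * sum(!is.na(stats))))
}

#' Discover risk-group cutpoints on the prognostic index
#'
#' Conditional-inference-style recursive partitioning of the PI with a
#' survival endpoint: at each node the candidate binary split maximizing
#' the two-sample log-rank statistic is accepted only if its
#' Bonferroni-adjusted asymptotic P-value (over the candidate splits of
#' that node) is below `alpha`. The tree is grown to at most three leaves
#' (after the root split, only the child with the stronger significant
#' split is split again), with a minimum leaf size of `min_leaf`. Leaves
#' are ordered into good / intermediate / poor by their crude hazard
#' (events per person-year).
#'
#' @param pi numeric prognostic index per sample (>= 50 samples).
#' @param survival a [survival_records()] table (>= 10 events).
#' @param alpha split significance level (default 0.05).
#' @param min_leaf minimum samples per leaf (default 20).
#' @return object of class `risk_groups`: `cutpoints` (increasing PI
#'   thresholds), `labels` (risk label per PI interval, lowest interval
#'   first), `group_sizes`, `hazard_ratio` (per group vs the good group),
#'   `split_p` (adjusted P-value per accepted split), `crude_hazard`.
#'   A single-group result (no significant split) is returned flagged, not
#'   an error.
#' @export
find_risk_cutpoints <- function(pi, survival, alpha = 0.05, min_leaf = 20L) {
  stopifnot(inherits(survival, "survival_records"))
  if (length(pi) != nrow(survival)) stop("pi and survival differ in length")
  if (length(pi) < 50L) stop("need >= 50 samples for cutpoint discovery")
  if (sum(survival$event) < 10L) stop("need >= 10 events for cutpoint discovery")
  cutpoints <- numeric(0)
  split_p <- numeric(0)
  root <- .best_logrank_split(pi, survival, seq_along(pi), min_leaf)
  if (!is.null(root) && root$p_adjusted < alpha) {
    cutpoints <- root$cut
    split_p <- root$p_adjusted
    left <- which(pi <= root$cut)
    right <- which(pi > root$cut)
    child_splits <- list(.best_logrank_split(pi, survival, left, min_leaf),
                         .best_logrank_split(pi, survival, right, min_leaf))
    ps <- vapply(child_splits, function(s)
      if (is.null(s)) Inf else s$p_adjusted, numeric(1))
    if (min(ps) < alpha) {
      s2 <- child_splits[[which.min(ps)]]
      cutpoints <- sort(c(cutpoints, s2$cut))
      split_p <- c(split_p, s2$p_adjusted)
    }
  }
  interval <- findInterval(pi, cutpoints) + 1L  # 1..(#cuts + 1), PI order
  n_groups <- length(cutpoints) + 1L
  crude <- vapply(seq_len(n_groups), function(g) {
    idx <- interval == g
    sum(survival$event[idx]) / max(sum(survival$time[idx]), .Machine$double.eps)
  }, numeric(1))
  label_sets <- list("good", c("good", "poor"),
                     c("good", "intermediate", "poor"))
  labels_by_hazard <- label_sets[[n_groups]]
  # label per PI interval: the g-th lowest-hazard interval gets the g-th label
  labels <- character(n_groups)
  labels[order(crude)] <- labels_by_hazard
  hr <- stats::setNames(rep(1, n_groups), labels)
  if (n_groups > 1L) {
    grp <- factor(labels[interval], levels = labels_by_hazard)
    cx <- survival::coxph(survival::Surv(survival$time, survival$event) ~ grp,
                          ties = "efron")
    hr <- stats::setNames(c(1, exp(unname(stats::coef(cx)))), labels_by_hazard)
  }
  if (n_groups == 1L)
    message("no significant PI split: returning a single risk group")
  structure(list(cutpoints = cutpoints, labels = labels,
                 group_sizes = stats::setNames(tabulate(interval, n_groups),
                                               labels),
                 hazard_ratio = hr, split_p = split_p,
                 crude_hazard = stats::setNames(crude, labels),
                 single_group = n_groups == 1L),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  cat("risk_groups:", length(x$labels), "group(s)\n")
  if (length(x$cutpoints))
    cat("  PI cutpoints:", paste(sprintf("%.4g", x$cutpoints), collapse = ", "), "\n")
  cat("  interval labels (low PI first):", paste(x$labels, collapse = " | "), "\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Assign risk-group labels to prognostic index values
#'
#' Interval membership against the learned cutpoints; a value exactly at a
#' cutpoint is assigned to the lower-risk side of the two adjacent
#' intervals (documented convention).
#'
#' @param pi numeric prognostic index values.
#' @param groups a `risk_groups` object from [find_risk_cutpoints()].
#' @return character vector of labels.
#' @export
assign_risk_group <- function(pi, groups) {
  stopifnot(inherits(groups, "risk_groups"))
  risk_rank <- match(groups$labels, c("good", "intermediate", "poor"))
  vapply(pi, function(x) {
    i <- findInterval(x, groups$cutpoints) + 1L  # boundary -> left interval
    j <- which(groups$cutpoints == x)
    if (length(j)) {
      lower <- j[1L]; upper <- j[1L] + 1L
      i <- if (risk_rank[lower] <= risk_rank[upper]) lower else upper
    }
    groups$labels[i]
  }, character(1))
}

#' Kaplan-Meier curves, log-rank test, and per-group hazard ratios
#'
#' @param groups group label per sample (factor or character).
#' @param survival a [survival_records()] table.
#' @param reference reference group for the hazard ratios (default: first
#'   factor level).
#' @return list with `km` (a `survfit` object), `logrank` (list with
#'   `statistic`, `df`, `p_value`; NULL with a warning if only one group),
#'   and `hazard_ratio` (named, reference = 1).
#' @export
km_logrank <- function(groups, survival, reference = NULL) {
  stopifnot(inherits(survival, "survival_records"))
  g <- factor(groups)
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  if (length(g) != nrow(survival)) stop("groups and survival differ in length")
  y <- survival::Surv(survival$time, survival$event)
  km <- survival::survfit(y ~ g)
  if (nlevels(droplevels(g)) < 2L) {
    warning("log-rank test needs >= 2 non-empty groups; returning curves only")
    return(list(km = km, logrank = NULL,
                hazard_ratio = stats::setNames(1, levels(droplevels(g)))))
  }
  sd <- survival::survdiff(y ~ g)
  df <- length(sd$n) - 1L
  lr <- list(statistic = sd$chisq, df = df,
             p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  cx <- survival::coxph(y ~ g, ties = "efron")
  hr <- stats::setNames(c(1, exp(unname(stats::coef(cx)))), levels(g))
  list(km = km, logrank = lr, hazard_ratio = hr)
}

#' Holm step-down multiple-testing correction
#'
#' @param p numeric P-values in `[0, 1]`.
#' @return adjusted P-values (same order as input).
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
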