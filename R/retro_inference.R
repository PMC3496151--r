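## Maximum-likelihood inference under the retrospective likelihood.

#' Retrospective log-likelihood of the observed genotypes
#'
#' Evaluates `sum_i log[ L_i(g_i) p_{g_i} / sum_g L_i(g) p_g ]`, the
#' log-probability of the observed genotypes conditional on the disease
#' phenotypes, with the phenotype likelihood `L_i` built on
#' stratum-specific incidence-constrained baselines.  Because it
#' conditions on phenotype, this likelihood is unaffected by
#' phenotype-dependent (clinic-based) ascertainment.
#'
#' @param records carrier records (single gene).
#' @param snp SNP column name; records with missing dose are dropped
#'   (logged).
#' @param beta effect parameters on the log-HR scale.
#' @param q minor-allele frequency: scalar, or named vector per country
#'   stratum.
#' @param spec an [effect_spec()].
#' @param curves incidence table (default [default_incidence()] for the
#'   records' gene).
#' @param mode `"breast_only"`, `"competing"` or `"subtype"`.
#' @param props subtype proportions (subtype mode).
#' @return scalar log-likelihood.
#' @export
retro_loglik <- function(records, snp, beta = 0, q = 0.25,
                         spec = effect_spec(), curves = NULL,
                         mode = c("breast_only", "competing", "subtype"),
                         props = NULL) {
  mode <- match.arg(mode)
  model <- build_model(records, snp, spec, curves, mode, props,
                       q_fixed = q)
  if (length(beta) != model$nbeta)
    stop("beta must have length ", model$nbeta)
  model_loglik(model, beta)
}

#' Fit the carrier modifier model for one SNP
#'
#' Joint maximum-likelihood estimation of the genotype log-hazard
#' ratio(s) and the per-stratum minor-allele frequencies under the
#' retrospective likelihood, with model-based (inverse observed
#' information) and family-cluster-robust covariance.  Analyses are
#' stratified by country; incidence curves may be birth-cohort-specific.
#'
#' Reported tests: for the trend model the 1-df likelihood-ratio
#' P-trend; for the genotype-specific model the 2-df LRT; per-parameter
#' robust Wald tests throughout.  In competing mode cause-specific
#' log-HRs for breast and ovarian cancer are estimated simultaneously
#' (with per-disease LRTs when `lr_tests = TRUE`); in subtype mode
#' ER-positive and ER-negative log-HRs are estimated simultaneously and
#' the robust Wald test of their difference is reported.
#'
#' @inheritParams retro_loglik
#' @param q_fixed optionally fix allele frequencies instead of
#'   estimating them (scalar or named per-stratum vector).  Default
#'   `NULL`: frequencies estimated jointly.
#' @param beta_init starting values for the effect parameters.
#' @param lr_tests compute likelihood-ratio tests that need auxiliary
#'   constrained refits (competing/subtype per-component tests).
#' @param df_correction finite-cluster `G/(G-1)` factor for the robust
#'   covariance.
#' @param max_iter optimizer iteration cap; non-convergence is flagged,
#'   never silent.
#' @param beta_by_stratum fit stratum-specific effect parameters
#'   (used by [test_heterogeneity()]).
#' @param subtype_shared in subtype mode, constrain both subtypes to a
#'   common effect (used by [fit_subtype()]'s `constrain_equal`).
#' @return an object of class `carrier_fit`.
#' @export
fit_snp <- function(records, snp, spec = effect_spec(), curves = NULL,
                    mode = c("breast_only", "competing", "subtype"),
                    props = NULL, q_fixed = NULL, beta_init = NULL,
                    lr_tests = TRUE, df_correction = FALSE,
                    max_iter = 500, beta_by_stratum = FALSE,
                    subtype_shared = FALSE) {
  mode <- match.arg(mode)
  model <- build_model(records, snp, spec, curves, mode, props,
                       q_fixed = q_fixed,
                       beta_by_stratum = beta_by_stratum,
                       subtype_shared = subtype_shared)
  n_aff <- sum(model$status != "unaffected")
  if (n_aff == 0 || n_aff == model$n_records)
    stop("fit requires at least one affected and one unaffected carrier")

  fixed_idx <- integer()
  if (mode == "subtype" && !subtype_shared) {
    ne <- model$ne
    if (!model$active_subtypes[1]) fixed_idx <- seq_len(ne)
    if (!model$active_subtypes[2]) fixed_idx <- ne + seq_len(ne)
  }
  if (mode == "competing") {
    ## a disease with identically-zero incidence carries no information
    ## about its effect: fix that block at zero (reported as NA)
    ne <- model$ne
    zero_curve <- vapply(c("breast", "ovarian"), function(d)
      all(vapply(model$lam_star, function(l) all(l[[d]] == 0),
                 logical(1))), logical(1))
    if (zero_curve["breast"]) fixed_idx <- c(fixed_idx, seq_len(ne))
    if (zero_curve["ovarian"]) fixed_idx <- c(fixed_idx, ne + seq_len(ne))
  }
  ft <- fit_model(model, beta_init = beta_init, fixed_idx = fixed_idx,
                  fixed_val = rep(0, length(fixed_idx)),
                  max_iter = max_iter)
  inf <- fit_inference(model, ft, df_correction = df_correction)

  npar <- ft$npar
  expand <- function(m) {
    full <- matrix(NA_real_, npar, npar,
                   dimnames = list(model$par_names, model$par_names))
    full[ft$free, ft$free] <- m
    full
  }
  cov_model <- expand(inf$cov_model)
  cov_robust <- expand(inf$cov_robust)
  theta <- stats::setNames(ft$theta, model$par_names)
  beta <- theta[seq_len(model$nbeta)]
  beta[intersect(fixed_idx, seq_len(model$nbeta))] <- NA_real_
  K <- length(model$strata_levels)
  q <- stats::setNames(unpack_theta(model, ft$theta)$q,
                       model$strata_levels)

  se_m <- sqrt(diag(cov_model))[seq_len(model$nbeta)]
  se_r <- sqrt(diag(cov_robust))[seq_len(model$nbeta)]
  zcrit <- stats::qnorm(0.975)
  hr <- data.frame(
    parameter = names(beta),
    estimate = unname(beta),
    hr = exp(unname(beta)),
    lcl = exp(unname(beta) - zcrit * se_r),
    ucl = exp(unname(beta) + zcrit * se_r),
    se_robust = se_r, se_model = se_m,
    p_wald = 2 * stats::pnorm(-abs(unname(beta) / se_r)),
    stringsAsFactors = FALSE)

  nul <- null_fit(model)
  tests <- list()
  lrt <- function(ll1, ll0, df) {
    stat <- 2 * (ll1 - ll0)
    list(statistic = stat, df = df,
         p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
  }
  nb_free <- length(setdiff(seq_len(model$nbeta), fixed_idx))
  if (!beta_by_stratum && nb_free > 0) {
    overall <- lrt(ft$loglik, nul$loglik, nb_free)
    tests[[if (nb_free == 1 && model$spec$parametrization == "trend")
      "p_trend" else "lrt_overall"]] <- overall
  }
  if (mode == "breast_only" && spec$parametrization == "genotype2df")
    tests$p_2df <- lrt(ft$loglik, nul$loglik, 2)
  if (mode %in% c("competing", "subtype") && !beta_by_stratum &&
      !subtype_shared) {
    comp <- if (mode == "competing") c("breast", "ovarian")
            else c("pos", "neg")
    ne <- model$ne
    blocks <- list(seq_len(ne), ne + seq_len(ne))
    if (lr_tests) for (k in 1:2) {
      if (mode == "subtype" && !model$active_subtypes[k]) next
      if (all(blocks[[k]] %in% fixed_idx)) next
      ft0 <- fit_model(model,
                       fixed_idx = union(blocks[[k]], fixed_idx),
                       fixed_val = rep(0, length(union(blocks[[k]],
                                                       fixed_idx))),
                       max_iter = max_iter)
      tests[[paste0("p_trend_", comp[k])]] <-
        lrt(ft$loglik, ft0$loglik, length(setdiff(blocks[[k]],
                                                  fixed_idx)))
    }
    if (mode == "subtype" && all(model$active_subtypes)) {
      ## robust Wald test of beta_pos - beta_neg (per-allele component)
      i1 <- 1L; i2 <- ne + 1L
      d <- beta[i1] - beta[i2]
      v <- cov_robust[i1, i1] + cov_robust[i2, i2] -
        2 * cov_robust[i1, i2]
      z <- d / sqrt(v)
      tests$p_difference <- list(statistic = unname(z), df = 1,
                                 p = 2 * stats::pnorm(-abs(unname(z))))
    }
  }

  counts <- genotype_status_counts(model)
  structure(list(
    snp = snp, gene = model$gene, mode = mode, spec = spec,
    beta = beta, q = q, se_model = se_m, se_robust = se_r, hr = hr,
    loglik = ft$loglik, loglik_null = nul$loglik,
    cov_model = cov_model, cov_robust = cov_robust, tests = tests,
    converged = ft$converged, iterations = ft$iterations,
    counts = counts,
    n = list(records = model$n_records, affected = n_aff,
             unaffected = model$n_records - n_aff,
             dropped_missing_genotype = model$n_dropped),
    model = model, theta = theta, free = ft$free
  ), class = "carrier_fit")
}

## Genotype count table by case status, mirroring a results-table row.
genotype_status_counts <- function(model) {
  cl <- model$cells
  lab <- if (model$mode == "competing")
    c("unaffected", "breast", "ovarian") else c("unaffected", "breast")
  out <- matrix(0L, 3, length(lab),
                dimnames = list(paste0("g", 0:2), lab))
  for (r in seq_len(nrow(cl))) {
    s <- if (cl$status[r] == "unaffected") "unaffected" else cl$status[r]
    out[cl$g[r] + 1, s] <- out[cl$g[r] + 1, s] + cl$n[r]
  }
  out
}

#' @export
print.carrier_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Retrospective-likelihood fit: %s (%s, %s model%s)\n",
              x$snp, x$gene, x$spec$parametrization,
              if (x$mode != "breast_only") paste0(", ", x$mode) else ""))
  cat(sprintf("  %d carriers (%d affected / %d unaffected), %d dropped for missing genotype\n",
              x$n$records, x$n$affected, x$n$unaffected,
              x$n$dropped_missing_genotype))
  hr <- x$hr
  for (i in seq_len(nrow(hr)))
    cat(sprintf("  %-16s HR %.*f (95%% CI %.*f to %.*f)  robust SE %.*f\n",
                hr$parameter[i], digits, hr$hr[i], digits, hr$lcl[i],
                digits, hr$ucl[i], digits, hr$se_robust[i]))
  cat(sprintf("  allele frequency: %s\n",
              paste(sprintf("%s=%.4f", names(x$q), x$q), collapse = " ")))
  for (nm in names(x$tests))
    cat(sprintf("  %s: statistic %.4g (df %d), p = %.3g\n", nm,
                x$tests[[nm]]$statistic, x$tests[[nm]]$df,
                x$tests[[nm]]$p))
  cat(sprintf("  loglik %.4f (null %.4f), converged: %s\n", x$loglik,
              x$loglik_null, x$converged))
  invisible(x)
}

#' Competing-risks fit (breast and ovarian cancer simultaneously)
#'
#' Convenience wrapper around [fit_snp()] with `mode = "competing"`:
#' cause-specific hazard ratios for both cancers are estimated jointly,
#' each disease's baseline constrained to its own incidence curve, with
#' per-disease censoring at the corresponding prophylactic surgery.
#'
#' @inheritParams fit_snp
#' @export
fit_competing <- function(records, snp, spec = effect_spec(),
                          curves = NULL, ...) {
  if (!is.null(curves) &&
      !any(curves$disease == "ovarian" &
             curves$gene %in% unique(records$gene)))
    stop("configuration error: competing fit needs an ovarian incidence curve")
  fit_snp(records, snp, spec = spec, curves = curves,
          mode = "competing", ...)
}

#' ER-subtype-specific fit with missing-at-random subtype labels
#'
#' Estimates simultaneous hazard ratios for ER-positive and ER-negative
#' breast cancer.  The cause-specific hazard for subtype `s` is
#' `lambda0(t) pi_s(t) exp(beta_s z_g)`; carriers with unknown tumour ER
#' status contribute the sum over subtypes (missing at random).  The
#' overall genotype relative risk `sum_s pi_s(t) exp(beta_s z_g)` feeds
#' the baseline incidence constraint.  Reports the robust Wald test of
#' `beta_pos - beta_neg` (`p_difference`).
#'
#' @inheritParams fit_snp
#' @param props age-indexed subtype proportions (`age`, `pi_pos`,
#'   `pi_neg`); defaults to the packaged illustrative
#'   [default_subtype_props()].
#' @param constrain_equal force a common effect for both subtypes
#'   (then the fit coincides with the single-disease model).
#' @export
fit_subtype <- function(records, snp, props = NULL,
                        spec = effect_spec(), constrain_equal = FALSE,
                        ...) {
  fit_snp(records, snp, spec = spec, mode = "subtype", props = props,
          subtype_shared = constrain_equal, ...)
}

#' Likelihood-ratio test of a genotype-by-age interaction
#'
#' Tests proportional hazards by comparing the trend model against one
#' in which the per-allele log-HR varies linearly with age
#' (per decade, centred at age 40).
#'
#' @inheritParams fit_snp
#' @return list with `statistic`, `df` (1), `p`, and both fits.
#' @export
test_age_interaction <- function(records, snp, curves = NULL, ...) {
  ev_ages <- followup_table(records, "breast_only")
  ev <- ev_ages$end_age[ev_ages$status == "breast"]
  if (length(unique(ev)) < 2)
    stop("degenerate data: no variation in event ages; ",
         "age interaction is not estimable")
  f0 <- fit_snp(records, snp, spec = effect_spec("trend"),
                curves = curves, ...)
  f1 <- fit_snp(records, snp,
                spec = effect_spec("trend", age_interaction = TRUE),
                curves = curves, ...)
  stat <- 2 * (f1$loglik - f0$loglik)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(max(stat, 0), 1, lower.tail = FALSE),
       fit_null = f0, fit_interaction = f1)
}

#' Likelihood-ratio test of between-stratum heterogeneity
#'
#' Compares a model with stratum-specific log-hazard ratios against the
#' common-effect model.  Strata with fewer than `min_stratum` carriers
#' are grouped into a single pooled stratum before fitting.
#'
#' @inheritParams fit_snp
#' @param stratum_var column defining the strata (default `country`).
#' @param min_stratum minimum carriers per stratum before pooling.
#' @return list with `statistic`, `df` (K-1), `p`, and both fits.
#' @export
test_heterogeneity <- function(records, snp, curves = NULL,
                               stratum_var = "country",
                               min_stratum = 10, ...) {
  rec <- records
  sizes <- table(rec[[stratum_var]])
  small <- names(sizes)[sizes < min_stratum]
  if (length(small)) {
    log_msg("STRATA_GROUPED",
            sprintf("%d small strata pooled: %s", length(small),
                    paste(small, collapse = ",")))
    rec[[stratum_var]][rec[[stratum_var]] %in% small] <- "pooled_small"
  }
  K <- length(unique(rec[[stratum_var]]))
  if (K < 2) stop("heterogeneity test needs >= 2 strata")
  f0 <- fit_snp(rec, snp, curves = curves, ...)
  f1 <- fit_snp(rec, snp, curves = curves, beta_by_stratum = TRUE, ...)
  stat <- 2 * (f1$loglik - f0$loglik)
  df <- (K - 1L) * f0$model$nbeta_block
  list(statistic = stat, df = df,
       p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       fit_common = f0, fit_by_stratum = f1)
}

#' Wald test of an effect difference between two carrier groups
#'
#' Fits the model separately in two groups (e.g. mutation classes, with
#' the class labels taken as input) and compares the leading effect
#' parameters with a two-sided Wald z-test using robust standard
#' errors: `z = (b1 - b2) / sqrt(se1^2 + se2^2)`.
#'
#' @inheritParams fit_snp
#' @param group grouping column name in `records`, or a vector with one
#'   value per record; must have exactly two non-empty levels.
#' @return list with `statistic` (z), `p`, the group labels and fits.
#' @export
test_group_difference <- function(records, snp, group, curves = NULL,
                                  ...) {
  gvec <- if (length(group) == 1 && is.character(group) &&
                group %in% names(records)) records[[group]] else group
  stopifnot(length(gvec) == nrow(records))
  lev <- unique(stats::na.omit(gvec))
  if (length(lev) != 2)
    stop("group must have exactly two levels, got ",
         length(lev))
  fits <- lapply(lev, function(l) {
    sub <- records[!is.na(gvec) & gvec == l, , drop = FALSE]
    if (!nrow(sub)) stop("empty group: ", l)
    fit_snp(sub, snp, curves = curves, ...)
  })
  b <- vapply(fits, function(f) f$beta[1], numeric(1))
  se <- vapply(fits, function(f) f$se_robust[1], numeric(1))
  z <- (b[1] - b[2]) / sqrt(sum(se^2))
  list(statistic = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
       groups = as.character(lev),
       estimates = stats::setNames(b, lev), se = stats::setNames(se, lev),
       fits = stats::setNames(fits, lev))
}

#' Exclude prevalent cases (survival-bias sensitivity analysis)
#'
#' Removes carriers whose breast cancer was diagnosed more than
#' `window_years` before recruitment (strictly more; a diagnosis exactly
#' `window_years` before recruitment is retained).  Unaffected carriers
#' are always retained; affected carriers without a recruitment age are
#' retained with a warning.
#'
#' @param records carrier records.
#' @param window_years the window (default 5 years).
#' @return filtered records with an `"excluded"` attribute.
#' @export
exclude_prevalent <- function(records, window_years = 5) {
  aff <- !is.na(records$bc_age)
  no_rec <- aff & is.na(records$recruitment_age)
  if (any(no_rec))
    warning(sum(no_rec),
            " affected record(s) without recruitment_age retained")
  drop <- aff & !is.na(records$recruitment_age) &
    (records$recruitment_age - records$bc_age > window_years)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("snp_names")) attr(out, a) <- attr(records, a)
  attr(out, "excluded") <- data.frame(
    individual_id = records$individual_id[drop],
    reason = rep("prevalent_case", sum(drop)), stringsAsFactors = FALSE)
  log_msg("PREVALENT_EXCLUDED",
          sprintf("%d prevalent case(s) removed (window %g years)",
                  sum(drop), window_years))
  out
}
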