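## The genotype model, the incidence-constrained baseline hazard, and
## per-genotype phenotype log-likelihoods.
##
## The modifier model is a proportional-hazards model on the carrier's
## cancer hazard: lambda_g(t) = lambda0(t) * r_g(t), with genotype
## relative risk r_g(t) and a baseline lambda0 chosen so that the
## genotype-AVERAGED hazard among survivors reproduces the externally
## supplied carrier incidence curve lambda*(t) at every age:
##
##   lambda0(t) = lambda*(t) * sum_g p_g S_g(t) / sum_g p_g S_g(t) r_g(t)
##
## computed forward in age with S_g(t) = exp(-sum_{u<t} lambda0(u) r_g(u)).
## Hazards are piecewise constant on yearly intervals [t, t+1); the
## event contribution is the density form S_g(t) * lambda_g(t).

#' Genotype prior probabilities under Hardy-Weinberg equilibrium
#'
#' @param q minor-allele frequency in (0,1) (0 and 1 allowed, giving a
#'   degenerate single-genotype prior).
#' @return numeric length-3 vector `(p0, p1, p2)` summing to 1.
#' @export
genotype_probs <- function(q) {
  stopifnot(q >= 0, q <= 1)
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Specify the genotype effect parametrization
#'
#' `trend` is the per-allele (multiplicative) model, log-hazard linear
#' in minor-allele dose; `genotype2df` fits free heterozygote and
#' homozygote log-hazard ratios.  With `age_interaction = TRUE` (trend
#' only) the per-allele log-HR varies linearly with age,
#' `beta(t) = beta0 + beta1 (t - center_age)/age_scale`.
#'
#' @param parametrization `"trend"` or `"genotype2df"`.
#' @param age_interaction add a genotype-by-age interaction term.
#' @param center_age,age_scale centering/scaling of the interaction
#'   covariate (default: age 40, per decade).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(parametrization = c("trend", "genotype2df"),
                        age_interaction = FALSE, center_age = 40,
                        age_scale = 10) {
  parametrization <- match.arg(parametrization)
  if (age_interaction && parametrization != "trend")
    stop("age interaction is supported for the trend parametrization only")
  structure(list(parametrization = parametrization,
                 age_interaction = age_interaction,
                 center_age = center_age, age_scale = age_scale),
            class = "effect_spec")
}

## Number of effect parameters for one disease/subtype component.
n_effect_par <- function(spec) {
  switch(spec$parametrization,
         trend = if (spec$age_interaction) 2L else 1L,
         genotype2df = 2L)
}

effect_par_names <- function(spec, prefix = "") {
  nm <- switch(spec$parametrization,
               trend = if (spec$age_interaction) c("trend", "age_slope")
                       else "trend",
               genotype2df = c("het", "hom"))
  paste0(prefix, nm)
}

## 3 x nT matrix of genotype relative risks r_g(t) on the age grid.
rr_matrix <- function(spec, beta, ages) {
  nT <- length(ages)
  if (spec$parametrization == "trend") {
    b <- rep(beta[1], nT)
    if (spec$age_interaction)
      b <- b + beta[2] * (ages - spec$center_age) / spec$age_scale
    rbind(rep(1, nT), exp(b), exp(2 * b))
  } else {
    rbind(rep(1, nT), rep(exp(beta[1]), nT), rep(exp(beta[2]), nT))
  }
}

#' Genotype relative risk
#'
#' Evaluates the hazard ratio `r_g(t)` for dose `g` at age `t` under an
#' effect specification.
#'
#' @param spec an [effect_spec()].
#' @param beta numeric parameter vector (log hazard ratios).
#' @param g genotype dose, 0/1/2 (vectorised).
#' @param t age in years (vectorised with `g`).
#' @return positive numeric vector of hazard ratios.
#' @export
relative_risk <- function(spec, beta, g, t = spec$center_age) {
  stopifnot(all(g %in% 0:2))
  n <- max(length(g), length(t))
  g <- rep_len(g, n); t <- rep_len(t, n)
  if (spec$parametrization == "trend") {
    b <- beta[1] + if (spec$age_interaction)
      beta[2] * (t - spec$center_age) / spec$age_scale else 0
    exp(b * g)
  } else {
    exp(beta[1] * (g == 1) + beta[2] * (g == 2))
  }
}

## Forward recursion for one stratum.  lam_star and R are lists over
## diseases (length 1 single-disease, 2 competing); the survival used in
## the weighting is joint across diseases.  Returns per-disease baseline
## hazards and (exclusive) cumulative genotype-specific hazards.
baseline_recursion <- function(lam_star, R, p) {
  nd <- length(lam_star)
  nT <- length(lam_star[[1]])
  lam0 <- lapply(seq_len(nd), function(d) numeric(nT))
  ## CUM[[d]][g, j] = sum_{u < j} lam0_d(u) r_{d,g}(u);  j in 1..nT+1
  CUM <- lapply(seq_len(nd), function(d) matrix(0, 3, nT + 1))
  logS <- rep(0, 3)
  for (j in seq_len(nT)) {
    S <- exp(logS)
    num <- sum(p * S)
    if (!is.finite(num) || num <= 0)
      stop("degenerate hazard: survival mass extinguished at interval ", j)
    tot <- rep(0, 3)
    for (d in seq_len(nd)) {
      den <- sum(p * S * R[[d]][, j])
      if (den <= 0) {
        if (lam_star[[d]][j] > 0)
          stop("degenerate hazard: zero at-risk weight at interval ", j)
        l0 <- 0
      } else l0 <- lam_star[[d]][j] * num / den
      lam0[[d]][j] <- l0
      h <- l0 * R[[d]][, j]
      CUM[[d]][, j + 1] <- CUM[[d]][, j] + h
      tot <- tot + h
    }
    logS <- logS - tot
  }
  list(lam0 = lam0, CUM = CUM)
}

## Extract one curve's hazard vector on an age grid from an
## incidence_table; errors if any grid age is not covered.
curve_vector <- function(curves, gene, disease, band, ages) {
  sub <- curves[curves$gene == gene & curves$disease == disease &
                  curves$cohort_band == band, , drop = FALSE]
  if (!nrow(sub) && band != "all")
    sub <- curves[curves$gene == gene & curves$disease == disease &
                    curves$cohort_band == "all", , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no incidence curve for gene=%s disease=%s band=%s",
                 gene, disease, band))
  idx <- match(ages, sub$age)
  if (anyNA(idx))
    stop(sprintf("incidence curve (%s, %s, %s) does not cover ages %s",
                 gene, disease, band,
                 paste(ages[is.na(idx)], collapse = ",")))
  sub$hazard[idx]
}

#' Incidence-constrained baseline hazard
#'
#' Computes the genotype-0 baseline hazard such that the
#' genotype-averaged hazard among carriers still at risk equals the
#' supplied population incidence curve at every age (see the module
#' notes above for the forward recursion).
#'
#' @param curve an `incidence_table` (from [read_incidence()] or
#'   [default_incidence()]) or a numeric vector of yearly hazards.
#' @param q minor-allele frequency.
#' @param spec an [effect_spec()].
#' @param beta effect parameters (log hazard ratios).
#' @param gene,disease,cohort_band curve selectors when `curve` is a
#'   table.
#' @param ages integer age grid (defaults to the curve's own ages).
#' @return data.frame of class `baseline_hazard` with columns `age`,
#'   `hazard`; genotype relative risks and cumulative hazards are kept
#'   in attributes for [phenotype_loglik()].
#' @export
constrained_baseline <- function(curve, q, spec = effect_spec(), beta = 0,
                                 gene = "BRCA1", disease = "breast",
                                 cohort_band = "all", ages = NULL) {
  if (is.numeric(curve)) {
    lam <- unname(curve)
    if (is.null(ages)) ages <- seq_along(lam) + 17L
  } else {
    if (is.null(ages))
      ages <- sort(unique(curve$age[curve$gene == gene &
                                      curve$disease == disease]))
    lam <- curve_vector(curve, gene, disease, cohort_band, ages)
  }
  R <- rr_matrix(spec, beta, ages)
  p <- genotype_probs(q)
  br <- baseline_recursion(list(lam), list(R), p)
  out <- data.frame(age = ages, hazard = br$lam0[[1]])
  attr(out, "rr") <- R
  attr(out, "cum") <- br$CUM[[1]]
  attr(out, "q") <- q
  class(out) <- c("baseline_hazard", "data.frame")
  out
}

#' Per-genotype phenotype log-likelihood
#'
#' Log-likelihood of one carrier's observed phenotype (follow-up and
#' affection status) under each of the three genotypes.  An unaffected
#' carrier followed to age `T` contributes `log S_g(T)`; a carrier
#' affected at age `t` contributes `log S_g(t) + log(lambda0(t) r_g(t))`.
#' With a second (competing) baseline, the survival term uses both
#' diseases' cumulative hazards at their disease-specific end ages and
#' the event factor is the cause-specific hazard of the observed
#' disease.
#'
#' @param fu a `followup` from [derive_followup()].
#' @param baseline a `baseline_hazard` for breast cancer.
#' @param baseline_ov optional ovarian `baseline_hazard` (competing
#'   mode).
#' @return numeric length-3 vector of log-likelihood values (g = 0,1,2).
#' @export
phenotype_loglik <- function(fu, baseline, baseline_ov = NULL) {
  ages <- baseline$age
  a_min <- ages[1]; nT <- length(ages)
  idx <- function(a) {
    i <- a - a_min + 1
    if (i > nT + 1) stop("end_age outside the age grid")
    max(1, i)
  }
  cumB <- attr(baseline, "cum"); RB <- attr(baseline, "rr")
  if (is.null(baseline_ov)) {
    j <- idx(fu$end_age)
    ll <- -cumB[, j]
    if (fu$status == "breast") {
      if (j > nT) stop("event age outside the age grid")
      ll <- ll + log(baseline$hazard[j] * RB[, j])
    }
    return(unname(ll))
  }
  cumO <- attr(baseline_ov, "cum"); RO <- attr(baseline_ov, "rr")
  jb <- idx(fu$bc_end); jo <- idx(fu$oc_end)
  ll <- -cumB[, jb] - cumO[, jo]
  if (fu$status == "breast")
    ll <- ll + log(baseline$hazard[jb] * RB[, jb])
  if (fu$status == "ovarian")
    ll <- ll + log(baseline_ov$hazard[jo] * RO[, jo])
  unname(ll)
}
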