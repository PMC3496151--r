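## Synthetic clinic-ascertained carrier cohorts.
##
## The generator mirrors the statistical structure the analysis
## assumes: HWE founder genotypes with family (sibship) correlation,
## genotype- and subtype-specific piecewise-constant yearly hazards for
## breast and ovarian cancer whose genotype-average reproduces the
## configured incidence curves, prophylactic-surgery censoring, and
## outcome-dependent (affected-oversampled) recruitment at age >= 18.
## Simulation is discrete-yearly on the same grid as the analysis.

#' Configuration for the synthetic cohort generator
#'
#' All generative parameters, with a mandatory seed.  The first SNP in
#' `snp_names` carries the configured effects; any further SNPs are
#' null modifiers.  Subtype-specific effects (`beta_pos`, `beta_neg`),
#' when supplied, replace `beta_breast`.
#'
#' @param n_families number of simulated families.
#' @param sibship_sizes integer vector sampled uniformly for the number
#'   of sisters per family.
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param strata country labels; families are assigned uniformly.
#' @param maf minor-allele frequency of the effect SNP, recycled over
#'   strata.
#' @param snp_names SNP column names; extra SNPs beyond the first get
#'   frequency `maf` too unless `extra_maf` is given.
#' @param extra_maf optional frequencies for `snp_names[-1]`.
#' @param beta_breast per-allele log-HR for breast cancer (length 1,
#'   trend) or heterozygote/homozygote log-HRs (length 2).
#' @param beta_ovarian per-allele log-HR for ovarian cancer.
#' @param beta_pos,beta_neg ER-subtype-specific per-allele log-HRs.
#' @param age_slope genotype-by-age interaction slope (per decade,
#'   centred at 40) on the breast log-HR.
#' @param curves incidence table (default [default_incidence()]).
#' @param props subtype proportions (default
#'   [default_subtype_props()]).
#' @param er_missing_rate probability that a breast tumour's ER status
#'   is missing (missing at random).
#' @param p_mastectomy,p_oophorectomy yearly probabilities of bilateral
#'   prophylactic surgery from `surgery_from_age` on.
#' @param surgery_from_age youngest age at which surgery can occur.
#' @param w_affected,w_unaffected recruitment weights: a carrier is
#'   recruited as a proband with probability
#'   `base_recruit * w_status / max(w_affected, w_unaffected)`.
#' @param base_recruit overall recruitment scale in (0, 1].
#' @param relative_inclusion probability that each relative of a
#'   recruited proband is also included.
#' @param birth_year_range,interview_age_range uniform ranges for birth
#'   year and age at interview (recruitment).
#' @param mutation_class_probs sampling probabilities for the mutation
#'   class label.
#' @param seed integer seed; mandatory for reproducibility.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_families = 500, sibship_sizes = 1:4,
                       gene = c("BRCA1", "BRCA2"), strata = "ALL",
                       maf = 0.25, snp_names = "rs0001",
                       extra_maf = NULL,
                       beta_breast = 0, beta_ovarian = 0,
                       beta_pos = NULL, beta_neg = NULL, age_slope = 0,
                       curves = NULL, props = NULL,
                       er_missing_rate = 0.3,
                       p_mastectomy = 0.005, p_oophorectomy = 0.01,
                       surgery_from_age = 30,
                       w_affected = 5, w_unaffected = 1,
                       base_recruit = 1, relative_inclusion = 0.5,
                       birth_year_range = c(1930, 1985),
                       interview_age_range = c(22, 70),
                       mutation_class_probs = c(class1 = 0.65,
                                                class2 = 0.28,
                                                other = 0.07),
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  gene <- match.arg(gene)
  if (is.null(curves)) curves <- default_incidence(gene)
  if (is.null(props)) props <- default_subtype_props(gene)
  stopifnot(all(c(er_missing_rate, p_mastectomy, p_oophorectomy,
                  base_recruit, relative_inclusion) >= 0),
            all(c(er_missing_rate, p_mastectomy, p_oophorectomy,
                  base_recruit, relative_inclusion) <= 1),
            w_affected >= 0, w_unaffected >= 0,
            max(w_affected, w_unaffected) > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate a clinic-ascertained carrier cohort
#'
#' Draws families, genotypes and life histories under the configured
#' model (see [sim_config()]) and applies outcome-dependent
#' recruitment.  Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return carrier records (a data.frame as from
#'   [read_carrier_table()]) for the recruited carriers, with the
#'   `snp_names` attribute set.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  resample0 <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  nf <- cfg$n_families
  sib <- resample0(cfg$sibship_sizes, nf)
  N <- sum(sib)
  fam <- rep(seq_len(nf), sib)
  strata <- as.character(cfg$strata)
  maf <- rep_len(cfg$maf, length(strata))
  fam_stratum <- sample(seq_along(strata), nf, replace = TRUE)
  stratum <- fam_stratum[fam]

  ## genotypes: founder alleles at the stratum frequency; sibs draw
  ## from shared parental genotypes (family correlation)
  draw_snp <- function(q_by_stratum) {
    qf <- q_by_stratum[fam_stratum]
    m1 <- stats::rbinom(nf, 1, qf); m2 <- stats::rbinom(nf, 1, qf)
    f1 <- stats::rbinom(nf, 1, qf); f2 <- stats::rbinom(nf, 1, qf)
    pm <- stats::rbinom(N, 1, 0.5); pf <- stats::rbinom(N, 1, 0.5)
    mm <- ifelse(pm == 1, m2[fam], m1[fam])
    ff <- ifelse(pf == 1, f2[fam], f1[fam])
    as.integer(mm + ff)
  }
  geno <- matrix(NA_integer_, N, length(cfg$snp_names),
                 dimnames = list(NULL, cfg$snp_names))
  geno[, 1] <- draw_snp(maf)
  if (length(cfg$snp_names) > 1) {
    em <- cfg$extra_maf %||% rep(cfg$maf[1], length(cfg$snp_names) - 1)
    for (k in seq_along(cfg$snp_names[-1]))
      geno[, k + 1] <- draw_snp(rep_len(em[k], length(strata)))
  }
  z <- geno[, 1]

  ## genotype-specific yearly hazards per stratum (3 x nT), with the
  ## population (genotype-averaged) hazard equal to the configured curve
  ages <- sort(unique(cfg$curves$age[cfg$curves$gene == cfg$gene &
                                       cfg$curves$disease == "breast"]))
  nT <- length(ages)
  subtype_mode <- !is.null(cfg$beta_pos) || !is.null(cfg$beta_neg)
  bb <- cfg$beta_breast
  spec_b <- if (length(bb) == 2 && cfg$age_slope == 0)
    effect_spec("genotype2df")
  else effect_spec("trend", age_interaction = cfg$age_slope != 0)
  pi_pos <- cfg$props$pi_pos[match(ages, cfg$props$age)]
  haz <- lapply(seq_along(strata), function(c) {
    p <- genotype_probs(maf[c])
    lamB <- curve_vector(cfg$curves, cfg$gene, "breast", "all", ages)
    lamO <- curve_vector(cfg$curves, cfg$gene, "ovarian", "all", ages)
    RO <- rr_matrix(effect_spec("trend"), cfg$beta_ovarian, ages)
    if (subtype_mode) {
      Ep <- rr_matrix(effect_spec("trend"), cfg$beta_pos %||% 0, ages)
      En <- rr_matrix(effect_spec("trend"), cfg$beta_neg %||% 0, ages)
      pp <- matrix(pi_pos, 3, nT, byrow = TRUE)
      RB <- pp * Ep + (1 - pp) * En
    } else {
      RB <- rr_matrix(spec_b, if (cfg$age_slope != 0)
        c(bb[1], cfg$age_slope) else bb, ages)
      Ep <- En <- NULL
    }
    br <- baseline_recursion(list(lamB, lamO), list(RB, RO), p)
    ## 3 x nT genotype-specific yearly hazards
    HB <- sweep(RB, 2, br$lam0[[1]], `*`)
    HO <- sweep(RO, 2, br$lam0[[2]], `*`)
    if (any(HB + HO > 1))
      stop("configured hazards imply yearly event probability > 1")
    list(HB = HB, HO = HO, Ep = Ep, En = En, RB = RB)
  })

  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  interview <- resample(seq(cfg$interview_age_range[1],
                            cfg$interview_age_range[2]), N)
  birth_year <- resample(seq(cfg$birth_year_range[1],
                             cfg$birth_year_range[2]), N)

  bc_age <- oc_age <- mast_age <- ooph_age <- rep(NA_integer_, N)
  er <- rep(NA_character_, N)
  active <- rep(TRUE, N)       # still cancer-free
  has_mast <- rep(FALSE, N); has_ooph <- rep(FALSE, N)
  row3 <- z + 1L

  for (j in seq_len(nT)) {
    t_age <- ages[j]
    obs <- active & (t_age < interview)
    if (!any(obs)) next
    hb <- ho <- numeric(N)
    for (c in seq_along(strata)) {
      inc <- obs & stratum == c
      hb[inc] <- haz[[c]]$HB[cbind(row3[inc], j)]
      ho[inc] <- haz[[c]]$HO[cbind(row3[inc], j)]
    }
    hb[has_mast] <- 0; ho[has_ooph] <- 0
    htot <- hb + ho
    ev <- obs & (stats::runif(N) < 1 - exp(-htot))
    if (any(ev)) {
      is_bc <- stats::runif(N) < ifelse(htot > 0, hb / pmax(htot, 1e-300), 0)
      bc <- ev & is_bc; oc <- ev & !is_bc
      bc_age[bc] <- t_age; oc_age[oc] <- t_age
      active[ev] <- FALSE
      if (any(bc)) {
        ppos <- numeric(N)
        for (c in seq_along(strata)) {
          inc <- bc & stratum == c
          if (!any(inc)) next
          if (subtype_mode) {
            ppos[inc] <- pi_pos[j] *
              haz[[c]]$Ep[cbind(row3[inc], j)] /
              haz[[c]]$RB[cbind(row3[inc], j)]
          } else ppos[inc] <- pi_pos[j]
        }
        er[bc] <- ifelse(stats::runif(N)[bc] < ppos[bc], "pos", "neg")
      }
    }
    ## prophylactic surgeries among carriers still cancer-free
    can_surg <- active & !ev & obs & t_age >= cfg$surgery_from_age
    new_mast <- can_surg & !has_mast &
      (stats::runif(N) < cfg$p_mastectomy)
    new_ooph <- can_surg & !has_ooph &
      (stats::runif(N) < cfg$p_oophorectomy)
    mast_age[new_mast] <- t_age; has_mast[new_mast] <- TRUE
    ooph_age[new_ooph] <- t_age; has_ooph[new_ooph] <- TRUE
  }

  affected <- !is.na(bc_age) | !is.na(oc_age)
  w <- ifelse(affected, cfg$w_affected, cfg$w_unaffected)
  p_rec <- cfg$base_recruit * w / max(cfg$w_affected, cfg$w_unaffected)
  proband <- stats::runif(N) < p_rec
  fam_has <- as.logical(tapply(proband, fam, any))[fam]
  included <- proband |
    (fam_has & stats::runif(N) < cfg$relative_inclusion)
  included <- included & interview >= 18

  er[!is.na(er) & stats::runif(N) < cfg$er_missing_rate] <- NA

  rec <- data.frame(
    individual_id = sprintf("F%05d_%d", fam, stats::ave(
      rep(1, N), fam, FUN = seq_along)),
    family_id = sprintf("F%05d", fam),
    study_id = paste0("S_", strata[stratum]),
    country = strata[stratum],
    gene = cfg$gene,
    birth_year = birth_year,
    mutation_class = sample(names(cfg$mutation_class_probs), N,
                            replace = TRUE,
                            prob = cfg$mutation_class_probs),
    age_last_obs = interview,
    bc_age = bc_age, oc_age = oc_age,
    mastectomy_age = mast_age, oophorectomy_age = ooph_age,
    recruitment_age = interview,
    er_status = ifelse(is.na(er), "missing", er),
    stringsAsFactors = FALSE)
  for (s in cfg$snp_names) rec[[s]] <- geno[, s]
  out <- rec[included, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "snp_names") <- cfg$snp_names
  out
}

#' Summarise a carrier cohort
#'
#' Counts by affection status (single-disease censoring rules),
#' person-years of follow-up from birth to censure, median and
#' interquartile range of the censoring age, decade-of-birth histogram
#' and mutation-class counts.
#'
#' @param records carrier records.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records))
    return(structure(list(n = c(unaffected = 0, breast = 0),
                          person_years = 0,
                          median_censure = NA_real_, iqr_censure = NA_real_,
                          birth_decades = table(integer()),
                          mutation_class = table(character())),
                     class = "cohort_summary"))
  fu <- followup_table(records, "breast_only")
  n <- c(unaffected = sum(fu$status == "unaffected"),
         breast = sum(fu$status == "breast"))
  q <- stats::quantile(fu$end_age, c(0.25, 0.5, 0.75))
  structure(list(
    n = n,
    person_years = sum(fu$end_age),
    median_censure = unname(q[2]),
    iqr_censure = unname(c(q[1], q[3])),
    birth_decades = table(10 * (records$birth_year %/% 10)),
    mutation_class = table(records$mutation_class)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Carrier cohort summary\n")
  cat(sprintf("  carriers: %d unaffected, %d breast cancer\n",
              x$n["unaffected"], x$n["breast"]))
  cat(sprintf("  person-years follow-up: %d\n", round(x$person_years)))
  if (!is.na(x$median_censure))
    cat(sprintf("  median age at censure: %g (IQR %g to %g)\n",
                x$median_censure, x$iqr_censure[1], x$iqr_censure[2]))
  invisible(x)
}
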