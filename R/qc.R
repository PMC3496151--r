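## Genotyping quality control.
##
## Mirrors the QC pipeline used for iPLEX carrier genotyping: per-sample
## missingness, per-study call rate, duplicate concordance, a
## cross-centre test plate, and per-study Hardy-Weinberg tests on
## unrelated subjects.  All operations act on a sample x SNP matrix of
## minor-allele doses (0/1/2, NA = failed call) and are idempotent.

#' Exclude samples that failed too many SNPs
#'
#' A sample is excluded when its number of missing calls reaches the
#' failure count implied by the fail fraction: with the default 20% and
#' 26 SNPs typed, five or more missing calls exclude the sample.  The
#' count is `max(1, round(fail_fraction * n_snps_typed))`.
#'
#' @param genotypes sample x SNP matrix of doses (rownames = sample ids).
#' @param n_snps_typed number of SNPs attempted (defaults to
#'   `ncol(genotypes)`).
#' @param fail_fraction fraction of failed SNPs that triggers exclusion.
#' @return data.frame with `sample_id`, `n_missing`, `excluded`, `reason`.
#' @export
sample_missingness_filter <- function(genotypes,
                                      n_snps_typed = ncol(genotypes),
                                      fail_fraction = 0.20) {
  if (is.null(n_snps_typed) || n_snps_typed == 0)
    stop("n_snps_typed must be positive")
  fail_count <- max(1, round(fail_fraction * n_snps_typed))
  n_missing <- rowSums(is.na(genotypes))
  excluded <- n_missing >= fail_count
  data.frame(
    sample_id = rownames(genotypes) %||% as.character(seq_len(nrow(genotypes))),
    n_missing = as.integer(n_missing),
    excluded = excluded,
    reason = ifelse(excluded, "sample_missingness", ""),
    stringsAsFactors = FALSE
  )
}

#' Per-study, per-SNP call-rate check
#'
#' A (study, SNP) stratum passes only if its call rate is strictly
#' greater than `min_rate` (default "over 95%"), evaluated after
#' failing samples have been removed.  Failing pairs are removed from
#' that SNP's analysis.
#'
#' @param genotypes sample x SNP dose matrix after sample exclusions.
#' @param study study identifier per sample (length `nrow(genotypes)`).
#' @param min_rate call-rate threshold (strict inequality).
#' @return data.frame with `study`, `snp`, `n`, `call_rate`, `pass`,
#'   `reason`.
#' @export
study_call_rate_check <- function(genotypes, study, min_rate = 0.95) {
  stopifnot(length(study) == nrow(genotypes))
  snps <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  out <- do.call(rbind, lapply(unique(study), function(s) {
    sub <- genotypes[study == s, , drop = FALSE]
    n <- nrow(sub)
    rate <- if (n == 0) rep(NA_real_, ncol(sub)) else colMeans(!is.na(sub))
    data.frame(study = s, snp = snps, n = n, call_rate = rate,
               pass = !is.na(rate) & rate > min_rate,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(study = character(), snp = character(),
                      n = integer(), call_rate = numeric(),
                      pass = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  out$reason <- ifelse(out$pass, "",
                       ifelse(out$n == 0, "no data", "low_call_rate"))
  rownames(out) <- NULL
  out
}

#' Duplicate-sample concordance check
#'
#' Each duplicate pair is concordant when every SNP called in both
#' members agrees.  A study passes when the fraction of concordant
#' pairs is at least `min_concord`; a study with no duplicate pairs
#' passes with a warning.
#'
#' @param genotypes sample x SNP dose matrix.
#' @param pairs data.frame with columns `sample1`, `sample2`, `study`.
#' @param min_concord minimum concordant fraction (default 0.98).
#' @param studies studies to report on (default: those present in
#'   `pairs`); a listed study with no duplicate pairs passes with a
#'   warning.
#' @return data.frame with per-study `n_pairs`, `n_concordant`,
#'   `concordance`, `pass`.
#' @export
duplicate_concordance_check <- function(genotypes, pairs,
                                        min_concord = 0.98,
                                        studies = unique(pairs$study)) {
  out <- do.call(rbind, lapply(studies, function(s) {
    ps <- pairs[pairs$study == s, , drop = FALSE]
    conc <- vapply(seq_len(nrow(ps)), function(i) {
      g1 <- genotypes[ps$sample1[i], ]
      g2 <- genotypes[ps$sample2[i], ]
      ok <- !is.na(g1) & !is.na(g2)
      all(g1[ok] == g2[ok])
    }, logical(1))
    data.frame(study = s, n_pairs = nrow(ps),
               n_concordant = sum(conc),
               concordance = if (nrow(ps)) mean(conc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(study = character(), n_pairs = integer(),
                      n_concordant = integer(), concordance = numeric())
  out$pass <- is.na(out$concordance) | out$concordance >= min_concord
  if (any(is.na(out$concordance)))
    warning("study with zero duplicate pairs passes by convention: ",
            paste(out$study[is.na(out$concordance)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Cross-centre test-plate consistency check
#'
#' The genotyping centres type a shared plate of reference samples; for
#' each SNP and each pair of centres, the number of samples with
#' discordant non-missing calls is counted.  A centre pair fails a SNP
#' when more than `max_inconsistent` samples disagree, in which case all
#' studies genotyped at those centres are excluded from that SNP.
#'
#' @param plate named list (one element per centre) of sample x SNP
#'   dose matrices over the same reference samples and SNPs.
#' @param max_inconsistent maximum tolerated discordant samples.
#' @return data.frame with `snp`, `centre1`, `centre2`,
#'   `n_discordant`, `pass`.
#' @export
cross_centre_plate_check <- function(plate, max_inconsistent = 1) {
  centres <- names(plate)
  stopifnot(length(centres) >= 2)
  snps <- colnames(plate[[1]])
  cp <- utils::combn(centres, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(cp)), function(k) {
    a <- plate[[cp[1, k]]]; b <- plate[[cp[2, k]]]
    disc <- vapply(snps, function(s) {
      ok <- !is.na(a[, s]) & !is.na(b[, s])
      sum(a[ok, s] != b[ok, s])
    }, numeric(1))
    data.frame(snp = snps, centre1 = cp[1, k], centre2 = cp[2, k],
               n_discordant = as.integer(disc),
               pass = disc <= max_inconsistent,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square test comparing observed genotype
#' counts `(n0, n1, n2)` (doses 0/1/2) with the counts expected under
#' HWE at the maximum-likelihood allele frequency
#' `q = (n1 + 2 n2) / (2 n)`.  Monomorphic input returns statistic 0 and
#' p = 1.  An exact test (conditional on the allele count, summing
#' heterozygote configurations no more probable than the observed one)
#' is available for small counts.
#'
#' @param n0,n1,n2 genotype counts.
#' @param exact use the exact conditional test instead of chi-square.
#' @return list with `statistic`, `p_value`, `q` (minor-allele
#'   frequency), `method`.
#' @export
hwe_test <- function(n0, n1, n2, exact = FALSE) {
  if (any(c(n0, n1, n2) < 0)) stop("genotype counts must be non-negative")
  n <- n0 + n1 + n2
  if (n == 0) stop("total genotype count must be positive")
  q <- (n1 + 2 * n2) / (2 * n)
  if (q == 0 || q == 1)
    return(list(statistic = 0, p_value = 1, q = q, method = "monomorphic"))
  if (exact) {
    p <- .hwe_exact_p(n0, n1, n2)
    return(list(statistic = NA_real_, p_value = p, q = q, method = "exact"))
  }
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       q = q, method = "chi-square")
}

## Exact HWE p-value: distribution of the heterozygote count given the
## minor-allele count, summing configurations with probability <= observed.
.hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nm <- n1 + 2 * min(n2, n0)          # minor-allele copies
  nA <- n1 + 2 * max(n2, n0)
  hets <- seq(nm %% 2, nm, by = 2)
  logp <- vapply(hets, function(h) {
    hom_m <- (nm - h) / 2; hom_M <- (nA - h) / 2
    lfactorial(n) - lfactorial(hom_m) - lfactorial(h) - lfactorial(hom_M) +
      h * log(2) + lfactorial(nm) + lfactorial(nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - logsumexp(logp))
  sum(p[p <= p[hets == n1] * (1 + 1e-12)])
}

#' Per-study HWE screen on unrelated subjects
#'
#' Selects one member per family (the lowest `individual_id`,
#' deterministically), tests HWE per (study, SNP), and classifies each
#' stratum: `exclude` for p < `p_exclude`, `review` for p in
#' \[`p_exclude`, `p_review`\] (logged in place of a cluster-plot
#' inspection), `pass` otherwise.
#'
#' @param records carrier records (for `family_id`, `individual_id`,
#'   `study_id`).
#' @param genotypes sample x SNP dose matrix, rownames = individual ids.
#' @param p_exclude,p_review decision thresholds.
#' @param exact passed to [hwe_test()].
#' @return data.frame with one row per (study, SNP).
#' @export
hwe_screen <- function(records, genotypes, p_exclude = 0.005,
                       p_review = 0.05, exact = FALSE) {
  ord <- order(records$family_id, records$individual_id)
  rec <- records[ord, ]
  unrel <- rec$individual_id[!duplicated(rec$family_id)]
  g <- genotypes[rownames(genotypes) %in% unrel, , drop = FALSE]
  study <- rec$study_id[match(rownames(g), rec$individual_id)]
  snps <- colnames(g)
  out <- do.call(rbind, lapply(unique(study), function(s) {
    sub <- g[study == s, , drop = FALSE]
    do.call(rbind, lapply(snps, function(snp) {
      x <- sub[, snp]
      cnt <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
               sum(x == 2, na.rm = TRUE))
      if (sum(cnt) == 0)
        return(data.frame(study = s, snp = snp, n = 0,
                          statistic = NA_real_, p_value = NA_real_,
                          decision = "no data", stringsAsFactors = FALSE))
      h <- hwe_test(cnt[1], cnt[2], cnt[3], exact = exact)
      decision <- if (h$p_value < p_exclude) "exclude"
                  else if (h$p_value <= p_review) "review" else "pass"
      data.frame(study = s, snp = snp, n = sum(cnt),
                 statistic = h$statistic, p_value = h$p_value,
                 decision = decision, stringsAsFactors = FALSE)
    }))
  }))
  for (i in which(out$decision == "review"))
    log_msg("HWE_REVIEW", sprintf(
      "study %s SNP %s HWE p=%.4g in review band; retained after review",
      out$study[i], out$snp[i], out$p_value[i]))
  rownames(out) <- NULL
  out
}

#' Flag potential duplicate subjects across studies
#'
#' A pair is flagged when either (a) the phenotype rule matches: equal
#' birth year, gene, exact mutation description and all event/censoring
#' ages; or (b) the genotype rule matches: identity of non-missing calls
#' at least `min_identity` over at least `min_shared_snps` SNPs called
#' in both.
#'
#' @param records carrier records.
#' @param genotypes sample x SNP dose matrix, rownames = individual ids.
#' @param min_shared_snps minimum jointly called SNPs for the genotype
#'   rule (default 26).
#' @param min_identity minimum fraction of identical calls.
#' @return data.frame of flagged pairs with the matching rule.
#' @export
find_potential_duplicates <- function(records, genotypes,
                                      min_shared_snps = 26,
                                      min_identity = 0.95) {
  ids <- records$individual_id
  pheno_key <- paste(records$birth_year, records$gene,
                     records$mutation_class, records$bc_age,
                     records$oc_age, records$age_last_obs, sep = "|")
  out <- list()
  n <- length(ids)
  for (i in seq_len(max(0, n - 1))) for (j in seq(i + 1, n)) {
    by_pheno <- pheno_key[i] == pheno_key[j]
    by_geno <- FALSE
    gi <- if (ids[i] %in% rownames(genotypes)) genotypes[ids[i], ] else NULL
    gj <- if (ids[j] %in% rownames(genotypes)) genotypes[ids[j], ] else NULL
    if (!is.null(gi) && !is.null(gj)) {
      ok <- !is.na(gi) & !is.na(gj)
      if (sum(ok) >= min_shared_snps)
        by_geno <- mean(gi[ok] == gj[ok]) >= min_identity
    }
    if (by_pheno || by_geno)
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[j],
        rule = if (by_pheno && by_geno) "phenotype+genotype"
               else if (by_pheno) "phenotype" else "genotype",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id1 = character(), id2 = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full genotyping QC pipeline
#'
#' Applies, in order: per-sample missingness exclusion, per-study
#' call-rate check, optional duplicate-pair concordance check, and the
#' per-study HWE screen on unrelated subjects.  Returns a `qc_report`
#' aggregating all component tables and the exclusion lists.
#'
#' @param records carrier records.
#' @param genotypes sample x SNP dose matrix (rownames = individual ids).
#' @param duplicate_pairs optional data.frame for
#'   [duplicate_concordance_check()].
#' @param n_snps_typed SNPs attempted per sample (missingness rule).
#' @param ... thresholds forwarded to the component checks.
#' @return an object of class `qc_report`.
#' @export
run_qc <- function(records, genotypes, duplicate_pairs = NULL,
                   n_snps_typed = ncol(genotypes), ...) {
  samp <- sample_missingness_filter(genotypes, n_snps_typed = n_snps_typed)
  keep <- samp$sample_id[!samp$excluded]
  g2 <- genotypes[rownames(genotypes) %in% keep, , drop = FALSE]
  rec2 <- records[records$individual_id %in% keep, , drop = FALSE]
  study <- rec2$study_id[match(rownames(g2), rec2$individual_id)]
  call_rate <- study_call_rate_check(g2, study)
  dup <- if (!is.null(duplicate_pairs))
    duplicate_concordance_check(genotypes, duplicate_pairs) else NULL
  hwe <- hwe_screen(rec2, g2)
  structure(list(
    sample_missingness = samp,
    call_rate = call_rate,
    duplicate_concordance = dup,
    hwe = hwe,
    excluded_samples = samp[samp$excluded, c("sample_id", "reason")],
    excluded_study_snp = {
      cr_ex <- call_rate[!call_rate$pass, c("study", "snp", "reason")]
      hw_ex <- hwe[hwe$decision == "exclude", c("study", "snp")]
      hw_ex$reason <- rep("hwe_deviation", nrow(hw_ex))
      rbind(cr_ex, hw_ex)
    }
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotyping QC report\n")
  cat(sprintf("  samples excluded (missingness): %d\n",
              nrow(x$excluded_samples)))
  cat(sprintf("  (study, SNP) strata failing call rate: %d\n",
              sum(!x$call_rate$pass)))
  if (!is.null(x$duplicate_concordance))
    cat(sprintf("  studies failing duplicate concordance: %d\n",
                sum(!x$duplicate_concordance$pass)))
  cat(sprintf("  (study, SNP) HWE exclusions: %d, review-band: %d\n",
              sum(x$hwe$decision == "exclude"),
              sum(x$hwe$decision == "review")))
  invisible(x)
}
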