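# Retrospective-likelihood inference: likelihood values, MLE, tests.

test_that("retrospective loglik collapses to the genotype prior when the
           phenotype is uninformative", {
  tc <- random_toy_case(n = 10, n_int = 3, seed = 4)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)
  q <- 0.3
  p <- genotype_probs(q)
  expected <- sum(log(p[tc$df$g + 1]))
  ## beta = 0: L_i(g) is constant in g, the phenotype cancels
  expect_equal(retro_loglik(rec, "g", beta = 0, q = q, curves = curves),
               expected, tolerance = 1e-12)
  ## no follow-up at all: same collapse for any beta
  rec0 <- rec; rec0$bc_age <- NA; rec0$oc_age <- NA
  rec0$age_last_obs <- 18; rec0$er_status <- "missing"
  rec0$recruitment_age <- 18
  expect_equal(retro_loglik(rec0, "g", beta = 0.7, q = q,
                            curves = curves),
               expected, tolerance = 1e-12)
})

test_that("retrospective loglik equals the enumeration oracle", {
  for (seed in 1:5) {
    tc <- random_toy_case(n = 10, n_int = sample(2:3, 1), seed = seed)
    rec <- toy_records(tc$df)
    curves <- toy_curves(tc$lam, tc$ages)
    for (beta in c(-0.8, 0, 0.4)) {
      q <- runif(1, 0.1, 0.45)
      expect_equal(
        retro_loglik(rec, "g", beta = beta, q = q, curves = curves),
        oracle_retro_single(tc$df, tc$lam, tc$a_min, q, beta),
        tolerance = 1e-10)
    }
  }
})

test_that("the MLE matches a fine grid search on a toy cohort", {
  tc <- random_toy_case(n = 12, n_int = 3, seed = 42)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)
  q <- 0.3
  fit <- suppressWarnings(fit_snp(rec, "g", curves = curves,
                                  q_fixed = q, lr_tests = FALSE))
  grid <- seq(-2, 2, by = 1e-3)
  lls <- vapply(grid, function(b)
    oracle_retro_single(tc$df, tc$lam, tc$a_min, q, b), numeric(1))
  b_grid <- grid[which.max(lls)]
  expect_lt(abs(fit$beta[1] - b_grid), 2e-3)
})

test_that("permuted genotypes give a null estimate within 3 SE", {
  cfg <- sim_config(n_families = 600, maf = 0.3,
                    beta_breast = log(0.8), seed = 77)
  rec <- simulate_cohort(cfg)
  set.seed(78)
  rec$rs0001 <- sample(rec$rs0001)      # break genotype-phenotype link
  f <- suppressMessages(fit_snp(rec, "rs0001", lr_tests = FALSE))
  expect_lt(abs(f$beta[1] / f$se_robust[1]), 3)
})

test_that("joint allele-frequency estimation recovers the truth", {
  cfg <- sim_config(n_families = 1200, maf = 0.3, beta_breast = 0,
                    seed = 5)
  rec <- simulate_cohort(cfg)
  f <- suppressMessages(fit_snp(rec, "rs0001", lr_tests = FALSE))
  expect_lt(abs(f$q - 0.3), 0.02)
  expect_true(f$converged)
})

test_that("records with missing genotype are dropped per SNP", {
  tc <- random_toy_case(n = 15, n_int = 3, seed = 9)
  rec <- toy_records(tc$df)
  rec$g[c(2, 5)] <- NA
  curves <- toy_curves(tc$lam, tc$ages)
  f <- suppressMessages(
    suppressWarnings(fit_snp(rec, "g", curves = curves, q_fixed = 0.3,
                             lr_tests = FALSE)))
  expect_equal(f$n$dropped_missing_genotype, 2)
  expect_equal(f$n$records, 13)
})

test_that("age-interaction test is valid on degenerate and normal data", {
  rec <- toy_records(data.frame(status = rep(c("breast", "unaffected"), 5),
                                end = rep(c(40, 50), 5),
                                g = rep(0:1, 5)))
  expect_error(test_age_interaction(rec, "g"), "degenerate|variation")
  cfg <- sim_config(n_families = 400, maf = 0.3, beta_breast = 0,
                    seed = 10)
  sim <- simulate_cohort(cfg)
  res <- suppressMessages(test_age_interaction(sim, "rs0001",
                                               lr_tests = FALSE))
  expect_equal(res$df, 1)
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
})

test_that("heterogeneity test: identical strata give statistic 0 and
           one stratum errors", {
  tc <- random_toy_case(n = 16, n_int = 3, seed = 12)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)
  rec2 <- rec
  rec2$country <- "B"
  rec2$individual_id <- paste0(rec2$individual_id, "b")
  rec2$family_id <- paste0(rec2$family_id, "b")
  both <- rbind(rec, rec2)
  res <- suppressWarnings(suppressMessages(
    test_heterogeneity(both, "g", curves = curves, lr_tests = FALSE)))
  expect_lt(abs(res$statistic), 1e-4)
  expect_equal(res$p, 1, tolerance = 1e-4)
  expect_error(suppressMessages(
    test_heterogeneity(rec, "g", curves = curves)), ">= 2 strata")
})

test_that("group-difference Wald test: identical groups give z = 0,
           empty group errors", {
  tc <- random_toy_case(n = 20, n_int = 3, seed = 13)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)
  rec2 <- rec
  rec2$individual_id <- paste0(rec2$individual_id, "b")
  rec2$family_id <- paste0(rec2$family_id, "b")
  both <- rbind(rec, rec2)
  grp <- rep(c("class1", "class2"), each = nrow(rec))
  res <- suppressWarnings(suppressMessages(
    test_group_difference(both, "g", grp, curves = curves,
                          lr_tests = FALSE)))
  expect_equal(res$statistic, 0, tolerance = 1e-6)
  expect_equal(res$p, 1, tolerance = 1e-5)
  expect_error(test_group_difference(rec, "g", rep("class1", nrow(rec)),
                                     curves = curves),
               "two levels")
})

test_that("prevalent-case exclusion uses a strict five-year window", {
  rec <- toy_records(data.frame(status = rep("breast", 3),
                                end = c(40, 40, 40), g = c(0, 1, 2)))
  rec$age_last_obs <- c(46, 45, 50)
  rec$recruitment_age <- c(46, 45, NA)
  un <- toy_records(data.frame(status = "unaffected", end = 60, g = 0))
  un$individual_id <- "U1"
  un$recruitment_age <- 20     # recruited long before censure
  all_rec <- rbind(rec, un)
  expect_warning(out <- suppressMessages(exclude_prevalent(all_rec, 5)),
                 "recruitment_age")
  ## diagnosed 6y before recruitment: out; exactly 5y: retained;
  ## missing recruitment: retained; unaffected: retained
  expect_setequal(out$individual_id, c("I002", "I003", "U1"))
  expect_equal(attr(out, "excluded")$individual_id, "I001")
})

test_that("estimates are invariant to stratum relabelling", {
  cfg <- sim_config(n_families = 500, maf = 0.25, strata = c("UK", "US"),
                    beta_breast = log(0.85), seed = 21)
  rec <- simulate_cohort(cfg)
  f1 <- suppressMessages(fit_snp(rec, "rs0001", lr_tests = FALSE))
  rec2 <- rec
  rec2$country <- c(UK = "ZZ_UK", US = "AA_US")[rec2$country]
  f2 <- suppressMessages(fit_snp(rec2, "rs0001", lr_tests = FALSE))
  expect_equal(unname(f1$beta[1]), unname(f2$beta[1]), tolerance = 1e-6)
  expect_equal(unname(f1$se_robust[1]), unname(f2$se_robust[1]),
               tolerance = 1e-5)
})
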