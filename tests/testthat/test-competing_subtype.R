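# Competing-risks and ER-subtype model extensions.

test_that("competing loglik equals the two-disease enumeration oracle", {
  set.seed(31)
  a_min <- 18L; ages <- 18:20
  lamB <- c(0.04, 0.06, 0.05); lamO <- c(0.02, 0.01, 0.03)
  n <- 14
  df <- data.frame(
    status = sample(c("breast", "ovarian", "unaffected"), n, TRUE),
    g = sample(0:2, n, TRUE, prob = c(0.5, 0.38, 0.12)))
  df$end <- ifelse(df$status == "unaffected",
                   sample(c(ages, 21L), n, TRUE),
                   sample(ages, n, TRUE))
  df$bc_end <- df$end; df$oc_end <- df$end
  rec <- toy_records(df)
  curves <- toy_curves(lamB, ages, lamO = lamO)
  for (b in list(c(0, 0), c(0.3, -0.4), c(-0.6, 0.5))) {
    q <- runif(1, 0.15, 0.4)
    expect_equal(
      retro_loglik(rec, "g", beta = b, q = q, curves = curves,
                   mode = "competing"),
      oracle_retro_competing(df, lamB, lamO, a_min, q, b[1], b[2]),
      tolerance = 1e-10)
  }
  ## null effects collapse to the genotype prior
  q <- 0.3
  expect_equal(retro_loglik(rec, "g", beta = c(0, 0), q = q,
                            curves = curves, mode = "competing"),
               sum(log(genotype_probs(q)[df$g + 1])), tolerance = 1e-12)
})

test_that("competing MLE matches a two-parameter grid search", {
  set.seed(32)
  a_min <- 18L; ages <- 18:20
  lamB <- c(0.05, 0.07, 0.06); lamO <- c(0.03, 0.02, 0.04)
  n <- 15
  df <- data.frame(
    status = sample(c("breast", "ovarian", "unaffected"), n, TRUE),
    g = sample(0:2, n, TRUE, prob = c(0.45, 0.4, 0.15)))
  df$end <- ifelse(df$status == "unaffected",
                   sample(c(ages, 21L), n, TRUE),
                   sample(ages, n, TRUE))
  df$bc_end <- df$end; df$oc_end <- df$end
  rec <- toy_records(df)
  curves <- toy_curves(lamB, ages, lamO = lamO)
  q <- 0.3
  fit <- suppressWarnings(
    fit_snp(rec, "g", curves = curves, mode = "competing",
            q_fixed = q, lr_tests = FALSE))
  ## stage 1: coarse grid; stage 2: 1e-3 grid around the coarse optimum
  ll_fun <- function(bB, bO)
    oracle_retro_competing(df, lamB, lamO, a_min, q, bB, bO)
  coarse <- seq(-2, 2, by = 0.05)
  cg <- expand.grid(bB = coarse, bO = coarse)
  cg$ll <- mapply(ll_fun, cg$bB, cg$bO)
  top <- cg[which.max(cg$ll), ]
  fine_b <- seq(top$bB - 0.06, top$bB + 0.06, by = 1e-3)
  fine_o <- seq(top$bO - 0.06, top$bO + 0.06, by = 1e-3)
  fg <- expand.grid(bB = fine_b, bO = fine_o)
  fg$ll <- mapply(ll_fun, fg$bB, fg$bO)
  best <- fg[which.max(fg$ll), ]
  expect_lt(abs(fit$beta[1] - best$bB), 2e-3)
  expect_lt(abs(fit$beta[2] - best$bO), 2e-3)
})

test_that("zero ovarian incidence reduces the competing fit to the
           single-disease fit", {
  curves <- default_incidence("BRCA1")
  curves$hazard[curves$disease == "ovarian"] <- 0
  cfg <- sim_config(n_families = 500, maf = 0.25,
                    beta_breast = log(0.8), curves = curves, seed = 33)
  rec <- simulate_cohort(cfg)
  f1 <- suppressMessages(fit_snp(rec, "rs0001", curves = curves,
                                 lr_tests = FALSE))
  f2 <- suppressMessages(fit_competing(rec, "rs0001", curves = curves,
                                       lr_tests = FALSE))
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]), tolerance = 1e-6)
  expect_true(is.na(f2$beta[2]))        # no information: reported absent
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("swapping which disease comes first leaves competing estimates
           unchanged", {
  cfg <- sim_config(n_families = 600, maf = 0.25,
                    beta_breast = log(0.85), beta_ovarian = log(1.2),
                    seed = 34)
  rec <- simulate_cohort(cfg)
  curves <- default_incidence("BRCA1")
  f <- suppressMessages(fit_competing(rec, "rs0001", curves = curves,
                                      lr_tests = FALSE))
  curves_swapped <- curves[order(curves$disease, decreasing = TRUE), ]
  f2 <- suppressMessages(fit_competing(rec, "rs0001",
                                       curves = curves_swapped,
                                       lr_tests = FALSE))
  expect_equal(f$beta, f2$beta, tolerance = 1e-8)
})

test_that("missing ovarian curve raises a configuration error", {
  tc <- random_toy_case(n = 12, n_int = 3, seed = 35)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)     # breast only
  expect_error(fit_competing(rec, "g", curves = curves),
               "ovarian incidence")
})

test_that("subtype model with pi_pos = 1 reduces to the single-disease
           fit with beta_neg absent", {
  cfg <- sim_config(n_families = 500, maf = 0.25,
                    beta_breast = log(0.8), seed = 36)
  rec <- simulate_cohort(cfg)
  rec$er_status[!is.na(rec$bc_age)] <- "pos"
  props <- data.frame(age = 18:79, pi_pos = 1, pi_neg = 0)
  f1 <- suppressMessages(fit_snp(rec, "rs0001", lr_tests = FALSE))
  f2 <- suppressMessages(fit_subtype(rec, "rs0001", props = props,
                                     lr_tests = FALSE))
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]), tolerance = 1e-6)
  expect_true(is.na(f2$beta[2]))
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("constraining equal subtype effects recovers the single-disease
           fit (collapsibility)", {
  cfg <- sim_config(n_families = 500, maf = 0.25,
                    beta_breast = log(0.8), er_missing_rate = 0.3,
                    seed = 37)
  rec <- simulate_cohort(cfg)
  f1 <- suppressMessages(fit_snp(rec, "rs0001", lr_tests = FALSE))
  f2 <- suppressMessages(fit_subtype(rec, "rs0001",
                                     constrain_equal = TRUE,
                                     lr_tests = FALSE))
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]), tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("invalid subtype proportions are rejected", {
  tc <- random_toy_case(n = 12, n_int = 3, seed = 38)
  rec <- toy_records(tc$df)
  curves <- toy_curves(tc$lam, tc$ages)
  props <- data.frame(age = tc$ages, pi_pos = 0.7, pi_neg = 0.5)
  expect_error(fit_subtype(rec, "g", props = props, curves = curves),
               "sum to 1")
})

test_that("subtype estimates separate differential effects", {
  ## ER-negative-specific protective effect, none for ER-positive
  cfg <- sim_config(n_families = 2500, maf = 0.25,
                    beta_pos = 0, beta_neg = log(0.7),
                    er_missing_rate = 0.3, seed = 39)
  rec <- simulate_cohort(cfg)
  f <- suppressMessages(fit_subtype(rec, "rs0001", lr_tests = FALSE))
  expect_lt(abs(f$beta[2] - log(0.7)), 0.12)
  expect_lt(abs(f$beta[1]), 0.15)
  expect_true(!is.null(f$tests$p_difference))
})
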