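# Genotyping QC rules and the Hardy-Weinberg test.

make_plate <- function(n_samples, n_snps = 26, missing_per_sample = 0) {
  g <- matrix(0L, n_samples, n_snps,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("rs%02d", seq_len(n_snps))))
  for (i in seq_along(missing_per_sample))
    if (missing_per_sample[i] > 0)
      g[i, seq_len(missing_per_sample[i])] <- NA
  g
}

test_that("sample missingness rule excludes at 5+ of 26 SNPs", {
  g <- make_plate(4, 26, missing_per_sample = c(0, 4, 5, 26))
  res <- sample_missingness_filter(g)
  expect_equal(res$excluded, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$reason[3], "sample_missingness")
  expect_error(sample_missingness_filter(g[, 0, drop = FALSE]),
               "positive")
  ## idempotent: re-filtering the survivors excludes nobody
  res2 <- sample_missingness_filter(g[!res$excluded, , drop = FALSE])
  expect_false(any(res2$excluded))
})

test_that("study call rate uses the strict >95% rule", {
  rates <- c(100, 96, 95) / 100
  g <- do.call(rbind, lapply(seq_along(rates), function(k) {
    m <- matrix(0L, 100, 1)
    n_miss <- round((1 - rates[k]) * 100)
    if (n_miss > 0) m[seq_len(n_miss), 1] <- NA
    m
  }))
  colnames(g) <- "rs1"
  study <- rep(c("A", "B", "C"), each = 100)
  res <- study_call_rate_check(g, study)
  expect_equal(res$pass[res$study == "A"], TRUE)   # 100%
  expect_equal(res$pass[res$study == "B"], TRUE)   # 96% > 95%
  expect_equal(res$pass[res$study == "C"], FALSE)  # 95% is not over 95%
  ## empty study fails with "no data"
  res2 <- study_call_rate_check(g[0, , drop = FALSE], character(0))
  expect_equal(nrow(res2), 0)
})

test_that("duplicate concordance threshold is 98% of pairs", {
  g <- make_plate(200, 4)
  g[2, ] <- c(1L, 0L, 0L, 0L)     # one discordant duplicate pair
  pairs <- data.frame(sample1 = rownames(g)[seq(1, 199, 2)],
                      sample2 = rownames(g)[seq(2, 200, 2)],
                      study = "A", stringsAsFactors = FALSE)
  res <- duplicate_concordance_check(g, pairs)     # 99/100 concordant
  expect_true(res$pass)
  g[4, ] <- c(1L, 1L, 0L, 0L); g[6, ] <- c(0L, 1L, 0L, 0L)
  res2 <- duplicate_concordance_check(g, pairs)    # 97/100
  expect_equal(res2$n_concordant, 97)
  expect_false(res2$pass)
  ## a study with zero duplicate pairs passes with a warning
  expect_warning(res3 <- duplicate_concordance_check(
    g, pairs, studies = c("A", "B")))
  expect_true(res3$pass[res3$study == "B"])
  expect_equal(res3$n_pairs[res3$study == "B"], 0)
})

test_that("cross-centre plate tolerates one discordant sample, not two", {
  a <- make_plate(95, 2)
  b <- a
  expect_true(all(cross_centre_plate_check(list(c1 = a, c2 = b))$pass))
  b[1, 1] <- 1L
  r1 <- cross_centre_plate_check(list(c1 = a, c2 = b))
  expect_true(r1$pass[r1$snp == "rs01"])           # exactly one tolerated
  b[2, 1] <- 2L
  r2 <- cross_centre_plate_check(list(c1 = a, c2 = b))
  expect_false(r2$pass[r2$snp == "rs01"])
  expect_true(r2$pass[r2$snp == "rs02"])
})

test_that("HWE chi-square matches hand-computed expected counts", {
  ## exact HWE proportions and monomorphic input give statistic 0
  expect_equal(hwe_test(25, 50, 25)$statistic, 0)
  expect_equal(hwe_test(25, 50, 25)$p_value, 1)
  expect_equal(hwe_test(100, 0, 0)$statistic, 0)
  expect_equal(hwe_test(100, 0, 0)$p_value, 1)
  expect_error(hwe_test(-1, 2, 3), "non-negative")

  ## observed genotype distribution of a real-scale stratum, checked
  ## against a from-scratch expected-count computation
  n0 <- 2279; n1 <- 943; n2 <- 94; n <- n0 + n1 + n2
  q <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat_hand <- sum((c(n0, n1, n2) - e)^2 / e)
  h <- hwe_test(n0, n1, n2)
  expect_equal(h$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(h$p_value, pchisq(stat_hand, 1, lower.tail = FALSE))

  ## allele relabelling leaves the statistic unchanged
  h_rev <- hwe_test(n2, n1, n0)
  expect_equal(h$statistic, h_rev$statistic, tolerance = 1e-12)

  ## exact test agrees with chi-square in a well-behaved case
  he <- hwe_test(60, 35, 5, exact = TRUE)
  expect_true(he$p_value > 0.05)
})

test_that("HWE test is calibrated on simulated equilibrium genotypes", {
  set.seed(2024)
  n <- 1000; maf <- 0.2; reps <- 1000
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  rej <- vapply(seq_len(reps), function(i) {
    cnt <- as.vector(rmultinom(1, n, p))
    hwe_test(cnt[1], cnt[2], cnt[3])$p_value < 0.05
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(sum(rej), bounds[1])
  expect_lte(sum(rej), bounds[2])
})

test_that("duplicate subject detection uses phenotype and genotype rules", {
  rec <- toy_records(data.frame(status = c("breast", "breast", "unaffected"),
                                end = c(40, 40, 50), g = c(1, 1, 0)))
  g <- matrix(rep(c(0L, 1L, 0L), each = 30), 3, 30, byrow = TRUE)
  g[3, ] <- rep(0L, 30)
  g[2, ] <- g[1, ]                               # genotype clones
  rownames(g) <- rec$individual_id
  ## rows 1 and 2 share phenotype AND genotype
  found <- find_potential_duplicates(rec, g)
  expect_true(any(found$id1 == "I001" & found$id2 == "I002"))
  ## same year of birth and ages but different mutation class:
  ## phenotype rule must not fire
  rec2 <- rec; rec2$mutation_class[2] <- "class2"
  g2 <- g; g2[2, 1:20] <- 1L                     # 33% identity
  found2 <- find_potential_duplicates(rec2, g2)
  expect_false(any(found2$id1 == "I001" & found2$id2 == "I002"))
})

test_that("full QC run aggregates exclusions", {
  set.seed(11)
  rec <- toy_records(data.frame(
    status = rep(c("breast", "unaffected"), 25),
    end = rep(c(40, 50), 25), g = rbinom(50, 2, 0.3)))
  rec$family_id <- sprintf("FAM%03d", seq_len(50))
  g <- matrix(rbinom(50 * 26, 2, 0.3), 50, 26,
              dimnames = list(rec$individual_id,
                              sprintf("rs%02d", 1:26)))
  g[1, 1:10] <- NA
  rep_ <- suppressMessages(run_qc(rec, g))
  expect_s3_class(rep_, "qc_report")
  expect_equal(rep_$excluded_samples$sample_id, rec$individual_id[1])
  expect_true(all(rep_$call_rate$pass))
})
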