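# Independent brute-force oracles: explicit per-individual, per-year
# products, written without any of the package's internal machinery.
# Used to pin the likelihood engine and the MLE.

oracle_rr <- function(beta, g, parametrization = "trend") {
  if (parametrization == "trend") exp(beta[1] * g)
  else exp(if (g == 1) beta[1] else if (g == 2) beta[2] else 0)
}

# Naive forward recursion for the constrained baseline (single disease).
oracle_baseline <- function(lam_star, q, beta,
                            parametrization = "trend") {
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  nT <- length(lam_star)
  S <- c(1, 1, 1)
  lam0 <- numeric(nT)
  for (j in seq_len(nT)) {
    num <- 0; den <- 0
    for (g in 0:2) {
      r <- oracle_rr(beta, g, parametrization)
      num <- num + p[g + 1] * S[g + 1]
      den <- den + p[g + 1] * S[g + 1] * r
    }
    lam0[j] <- lam_star[j] * num / den
    for (g in 0:2)
      S[g + 1] <- S[g + 1] * exp(-lam0[j] * oracle_rr(beta, g,
                                                      parametrization))
  }
  lam0
}

# Retrospective log-likelihood by direct genotype enumeration,
# single-disease model.  df: columns status ("breast"/"unaffected"),
# end (integer age), g (dose).  Ages start at a_min.
oracle_retro_single <- function(df, lam_star, a_min, q, beta,
                                parametrization = "trend") {
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  lam0 <- oracle_baseline(lam_star, q, beta, parametrization)
  ll <- 0
  for (i in seq_len(nrow(df))) {
    Lg <- numeric(3)
    jend <- df$end[i] - a_min + 1
    for (g in 0:2) {
      r <- oracle_rr(beta, g, parametrization)
      S <- 1
      if (jend > 1) for (j in seq_len(jend - 1))
        S <- S * exp(-lam0[j] * r)
      Lg[g + 1] <- if (df$status[i] == "breast")
        S * lam0[jend] * r else S
    }
    num <- Lg[df$g[i] + 1] * p[df$g[i] + 1]
    ll <- ll + log(num / sum(Lg * p))
  }
  ll
}

# Competing-risks oracle: joint survival over both diseases with
# disease-specific end ages.  df: status in unaffected/breast/ovarian,
# bc_end, oc_end, g.
oracle_retro_competing <- function(df, lamB, lamO, a_min, q,
                                   betaB, betaO) {
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  nT <- length(lamB)
  S <- c(1, 1, 1)
  l0B <- numeric(nT); l0O <- numeric(nT)
  for (j in seq_len(nT)) {
    num <- sum(p * S)
    denB <- 0; denO <- 0
    for (g in 0:2) {
      denB <- denB + p[g + 1] * S[g + 1] * exp(betaB * g)
      denO <- denO + p[g + 1] * S[g + 1] * exp(betaO * g)
    }
    l0B[j] <- lamB[j] * num / denB
    l0O[j] <- lamO[j] * num / denO
    for (g in 0:2)
      S[g + 1] <- S[g + 1] *
        exp(-(l0B[j] * exp(betaB * g) + l0O[j] * exp(betaO * g)))
  }
  ll <- 0
  for (i in seq_len(nrow(df))) {
    Lg <- numeric(3)
    jb <- df$bc_end[i] - a_min + 1
    jo <- df$oc_end[i] - a_min + 1
    for (g in 0:2) {
      rB <- exp(betaB * g); rO <- exp(betaO * g)
      S <- 1
      if (jb > 1) for (j in seq_len(jb - 1)) S <- S * exp(-l0B[j] * rB)
      if (jo > 1) for (j in seq_len(jo - 1)) S <- S * exp(-l0O[j] * rO)
      Lg[g + 1] <- S * switch(df$status[i],
                              breast = l0B[jb] * rB,
                              ovarian = l0O[jo] * rO,
                              1)
    }
    num <- Lg[df$g[i] + 1] * p[df$g[i] + 1]
    ll <- ll + log(num / sum(Lg * p))
  }
  ll
}

# Build full carrier records from a minimal (status, end, g) table on a
# toy age grid; unaffected rows are censored at `end`.
toy_records <- function(df, gene = "BRCA1", country = "ALL") {
  n <- nrow(df)
  er <- if (is.null(df$er)) rep("missing", n) else df$er
  data.frame(
    individual_id = sprintf("I%03d", seq_len(n)),
    family_id = sprintf("FAM%03d", seq_len(n)),
    study_id = rep("S1", n), country = rep(country, n),
    gene = rep(gene, n),
    birth_year = rep(1960L, n), mutation_class = rep("class1", n),
    age_last_obs = df$end,
    bc_age = ifelse(df$status == "breast", df$end, NA),
    oc_age = ifelse(df$status == "ovarian", df$end, NA),
    mastectomy_age = rep(NA_real_, n),
    oophorectomy_age = rep(NA_real_, n),
    recruitment_age = pmax(df$end, 18),
    er_status = ifelse(df$status == "breast", er, "missing"),
    g = df$g, stringsAsFactors = FALSE)
}

toy_curves <- function(lamB, ages, lamO = NULL, gene = "BRCA1") {
  out <- data.frame(disease = "breast", gene = gene, cohort_band = "all",
                    age = ages, hazard = lamB)
  if (!is.null(lamO))
    out <- rbind(out, data.frame(disease = "ovarian", gene = gene,
                                 cohort_band = "all", age = ages,
                                 hazard = lamO))
  class(out) <- c("incidence_table", "data.frame")
  out
}

# Random small single-disease test case on a 2-3 interval grid.
random_toy_case <- function(n = 12, n_int = 3, seed = 1) {
  set.seed(seed)
  a_min <- 18L
  ages <- a_min + seq_len(n_int) - 1L
  lam <- round(runif(n_int, 0.02, 0.08), 3)
  g <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.38, 0.12))
  status <- sample(c("breast", "unaffected"), n, replace = TRUE)
  end <- ifelse(status == "breast",
                sample(ages, n, replace = TRUE),
                sample(c(ages, a_min + n_int), n, replace = TRUE))
  list(df = data.frame(status = status, end = end, g = g,
                       stringsAsFactors = FALSE),
       lam = lam, ages = ages, a_min = a_min)
}
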