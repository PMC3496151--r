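## Internal likelihood engine shared by all fitting functions.
##
## Under the retrospective likelihood, a carrier's contribution depends
## on her data only through (country stratum, birth-cohort band,
## affection status, disease-specific end ages, ER subtype, genotype).
## Carriers are therefore aggregated into cells keyed by that tuple;
## every likelihood, gradient and score evaluation is O(#cells),
## independent of cohort size.  Per-individual scores for the family
## sandwich are recovered by mapping individuals to their cell.

build_model <- function(records, snp, spec = effect_spec(),
                        curves = NULL,
                        mode = c("breast_only", "competing", "subtype"),
                        props = NULL, q_fixed = NULL,
                        beta_by_stratum = FALSE, stratum_var = "country",
                        subtype_shared = FALSE) {
  mode <- match.arg(mode)
  gene <- unique(records$gene)
  if (length(gene) != 1)
    stop("records span multiple genes; analyse each gene separately")
  if (is.null(curves)) curves <- default_incidence(gene)
  if (mode == "subtype" && is.null(props))
    props <- default_subtype_props(gene)
  if (mode == "subtype" && spec$age_interaction)
    stop("age interaction is not supported in the subtype model")

  g <- records[[snp]]
  if (is.null(g)) stop("no genotype column named ", snp)
  keep <- !is.na(g)
  n_dropped <- sum(!keep)
  if (n_dropped)
    log_msg("MISSING_GENOTYPE",
            sprintf("%d record(s) without %s genotype dropped", n_dropped,
                    snp))
  rec <- records[keep, , drop = FALSE]
  g <- as.integer(g[keep])
  if (!nrow(rec)) stop("no records with observed genotype for ", snp)

  fu <- followup_table(rec, if (mode == "competing") "competing"
                            else "breast_only")

  ## age grid from the breast curve
  ages <- sort(unique(curves$age[curves$gene == gene &
                                   curves$disease == "breast"]))
  if (!length(ages)) stop("no breast incidence curve for gene ", gene)
  a_min <- ages[1]; nT <- length(ages)
  if (any(ages != a_min + seq_len(nT) - 1))
    stop("incidence curve ages must form a contiguous yearly grid")

  to_idx <- function(a, event) {
    i <- pmin(pmax(floor(a) - a_min + 1, 1), nT + 1)
    if (any(event & (floor(a) - a_min + 1 > nT)))
      stop("event age outside the age grid")
    if (any(a - a_min + 1 > nT + 1))
      stop("end_age outside the age grid")
    as.integer(i)
  }

  ## cohort bands from the curve table
  band_levels <- unique(curves$cohort_band[curves$gene == gene])
  if (length(band_levels) > 1) {
    rng <- regmatches(band_levels,
                      regexec("^(\\d+)-(\\d+)$", band_levels))
    if (any(lengths(rng) != 3))
      stop("cohort_band labels must be 'all' or 'YYYY-YYYY'")
    lo <- as.numeric(vapply(rng, `[`, "", 2))
    hi <- as.numeric(vapply(rng, `[`, "", 3))
    band <- vapply(rec$birth_year, function(by) {
      if (is.na(by)) stop("birth_year required with cohort-specific curves")
      w <- which(by >= lo & by <= hi)
      if (!length(w)) stop("no cohort band covers birth year ", by)
      band_levels[w[1]]
    }, "")
  } else band <- rep(band_levels, nrow(rec))

  strata <- rec[[stratum_var]] %||% rep("ALL", nrow(rec))
  strata_levels <- sort(unique(strata))
  si <- match(strata, strata_levels)
  bi <- match(band, band_levels)

  status <- fu$status
  is_bc <- status == "breast"
  jb <- to_idx(fu$bc_end, is_bc)
  jo <- to_idx(fu$oc_end, status == "ovarian")

  sub <- rep("", nrow(rec))
  if (mode == "subtype") {
    sub[is_bc] <- rec$er_status[is_bc]
    sub[is_bc & !(sub %in% c("pos", "neg"))] <- "missing"
  }

  key <- paste(si, bi, status, jb,
               if (mode == "competing") jo else 0L, sub, g, sep = "_")
  uk <- !duplicated(key)
  ind_cell <- match(key, key[uk])
  cells <- data.frame(stratum = si[uk], band = bi[uk],
                      status = status[uk], jb = jb[uk], jo = jo[uk],
                      sub = sub[uk], g = g[uk],
                      n = tabulate(ind_cell, nbins = sum(uk)),
                      stringsAsFactors = FALSE)

  ## incidence vectors per band
  lam_star <- lapply(band_levels, function(b) {
    lb <- list(breast = curve_vector(curves, gene, "breast", b, ages))
    if (mode == "competing")
      lb$ovarian <- curve_vector(curves, gene, "ovarian", b, ages)
    lb
  })

  pi_mat <- NULL
  active_subtypes <- c(TRUE, TRUE)
  if (mode == "subtype") {
    idxp <- match(ages, props$age)
    if (anyNA(idxp)) stop("subtype proportions must cover the age grid")
    pp <- props$pi_pos[idxp]; pn <- props$pi_neg[idxp]
    if (any(abs(pp + pn - 1) > 1e-8) || any(pp < 0) || any(pn < 0))
      stop("subtype proportions must be in [0,1] and sum to 1")
    pi_mat <- rbind(pos = pp, neg = pn)
    active_subtypes <- c(any(pp > 0), any(pn > 0))
    if (!active_subtypes[1] && any(cells$sub == "pos") ||
        !active_subtypes[2] && any(cells$sub == "neg"))
      stop("observed subtype has zero proportion at all ages")
  }

  ne <- n_effect_par(spec)
  n_components <- switch(mode, breast_only = 1L, competing = 2L,
                         subtype = if (subtype_shared) 1L else 2L)
  K <- length(strata_levels)
  nbeta_block <- ne * n_components
  nbeta <- nbeta_block * (if (beta_by_stratum) K else 1L)

  comp_names <- switch(mode,
                       breast_only = "",
                       competing = c("breast_", "ovarian_"),
                       subtype = if (subtype_shared) ""
                                 else c("pos_", "neg_"))
  bnames <- unlist(lapply(comp_names, function(p)
    effect_par_names(spec, p)))
  if (beta_by_stratum)
    bnames <- unlist(lapply(strata_levels, function(s)
      paste0(s, ":", bnames)))
  par_names <- c(bnames,
                 if (is.null(q_fixed)) paste0("q_", strata_levels))

  ## per-stratum genotype counts (for q init and the null likelihood)
  gcount <- matrix(0, K, 3)
  for (r in seq_len(nrow(cells)))
    gcount[cells$stratum[r], cells$g[r] + 1] <-
      gcount[cells$stratum[r], cells$g[r] + 1] + cells$n[r]

  list(mode = mode, spec = spec, gene = gene, ages = ages, a_min = a_min,
       nT = nT, strata_levels = strata_levels, band_levels = band_levels,
       lam_star = lam_star, pi_mat = pi_mat,
       active_subtypes = active_subtypes, cells = cells,
       ind_cell = ind_cell, family = rec$family_id,
       individual_id = rec$individual_id,
       q_fixed = q_fixed, beta_by_stratum = beta_by_stratum,
       subtype_shared = subtype_shared,
       ne = ne, n_components = n_components, nbeta_block = nbeta_block,
       nbeta = nbeta, par_names = par_names, gcount = gcount,
       n_dropped = n_dropped, n_records = nrow(rec),
       status = status)
}

## Split theta into per-stratum beta blocks and q vector.
unpack_theta <- function(model, theta) {
  K <- length(model$strata_levels)
  beta <- theta[seq_len(model$nbeta)]
  if (is.null(model$q_fixed)) {
    q <- expit(theta[model$nbeta + seq_len(K)])
  } else {
    q <- rep_len(unname(model$q_fixed), K)
    if (!is.null(names(model$q_fixed)) &&
        all(model$strata_levels %in% names(model$q_fixed)))
      q <- unname(model$q_fixed[model$strata_levels])
  }
  beta_of <- function(c) {
    if (model$beta_by_stratum)
      beta[(c - 1) * model$nbeta_block + seq_len(model$nbeta_block)]
    else beta
  }
  list(beta_of = beta_of, q = q)
}

## Relative-risk structures for one beta block.
## Returns list(lam_R = per-disease R for the constraint,
##              ev = per-event-type 3 x nT log event-factor matrices
##                   EXCLUDING log lambda0).
rr_structures <- function(model, beta) {
  spec <- model$spec; ages <- model$ages; ne <- model$ne
  if (model$mode == "breast_only") {
    R <- rr_matrix(spec, beta, ages)
    list(R = list(breast = R), ev = list(breast = log(R)))
  } else if (model$mode == "competing") {
    RB <- rr_matrix(spec, beta[seq_len(ne)], ages)
    RO <- rr_matrix(spec, beta[ne + seq_len(ne)], ages)
    list(R = list(breast = RB, ovarian = RO),
         ev = list(breast = log(RB), ovarian = log(RO)))
  } else {
    Ep <- rr_matrix(spec, beta[seq_len(ne)], ages)
    En <- if (isTRUE(model$subtype_shared)) Ep
          else rr_matrix(spec, beta[ne + seq_len(ne)], ages)
    pp <- matrix(model$pi_mat["pos", ], 3, model$nT, byrow = TRUE)
    pn <- matrix(model$pi_mat["neg", ], 3, model$nT, byrow = TRUE)
    Rtot <- pp * Ep + pn * En
    list(R = list(breast = Rtot),
         ev = list(pos = log(pp * Ep), neg = log(pn * En),
                   missing = log(Rtot)))
  }
}

## Vector of per-cell retrospective log-likelihood values.
cell_loglik <- function(model, theta) {
  up <- unpack_theta(model, theta)
  cl <- model$cells
  out <- numeric(nrow(cl))
  for (c in seq_along(model$strata_levels)) {
    p <- genotype_probs(up$q[c])
    lp <- log(p)
    rs <- rr_structures(model, up$beta_of(c))
    for (b in seq_along(model$band_levels)) {
      sel <- which(cl$stratum == c & cl$band == b)
      if (!length(sel)) next
      lam <- model$lam_star[[b]]
      br <- baseline_recursion(lam[names(rs$R)], rs$R, p)
      sub <- cl[sel, , drop = FALSE]
      ## survival term, (cells x 3)
      TB <- t(br$CUM[[1]])
      llm <- -TB[sub$jb, , drop = FALSE]
      if (model$mode == "competing") {
        TO <- t(br$CUM[[2]])
        llm <- llm - TO[sub$jo, , drop = FALSE]
      }
      ## event factors
      ev_rows <- which(sub$status != "unaffected")
      for (i in ev_rows) {
        if (model$mode == "breast_only") {
          j <- sub$jb[i]
          llm[i, ] <- llm[i, ] + log(br$lam0[[1]][j]) + rs$ev$breast[, j]
        } else if (model$mode == "competing") {
          if (sub$status[i] == "breast") {
            j <- sub$jb[i]
            llm[i, ] <- llm[i, ] + log(br$lam0[[1]][j]) + rs$ev$breast[, j]
          } else {
            j <- sub$jo[i]
            llm[i, ] <- llm[i, ] + log(br$lam0[[2]][j]) + rs$ev$ovarian[, j]
          }
        } else {
          j <- sub$jb[i]
          llm[i, ] <- llm[i, ] + log(br$lam0[[1]][j]) +
            rs$ev[[sub$sub[i]]][, j]
        }
      }
      w <- llm + matrix(lp, nrow(llm), 3, byrow = TRUE)
      out[sel] <- w[cbind(seq_len(nrow(w)), sub$g + 1)] - row_logsumexp(w)
    }
  }
  out
}

model_loglik <- function(model, theta)
  sum(model$cells$n * cell_loglik(model, theta))

## Closed-form null: with all effect parameters 0 the phenotype factor
## cancels and the retrospective likelihood is the HWE multinomial, so
## qhat is the per-stratum sample allele frequency.
null_fit <- function(model) {
  gc <- model$gcount
  n <- rowSums(gc)
  q <- (gc[, 2] + 2 * gc[, 3]) / (2 * n)
  if (!is.null(model$q_fixed))
    q <- unpack_theta(model, rep(0, model$nbeta))$q
  ll <- 0
  for (c in seq_len(nrow(gc))) {
    p <- genotype_probs(q[c])
    nz <- gc[c, ] > 0
    ll <- ll + sum(gc[c, nz] * log(p[nz]))
  }
  list(loglik = ll, q = stats::setNames(q, model$strata_levels))
}

## Maximize the retrospective likelihood.  `fixed` is an optional
## named list: indices into theta held at the supplied values.
fit_model <- function(model, beta_init = NULL, fixed_idx = integer(),
                      fixed_val = numeric(), max_iter = 500,
                      reltol = 1e-9) {
  K <- length(model$strata_levels)
  q0 <- (model$gcount[, 2] + 2 * model$gcount[, 3]) /
    (2 * rowSums(model$gcount))
  q0 <- pmin(pmax(q0, 1e-4), 1 - 1e-4)
  theta0 <- c(beta_init %||% rep(0, model$nbeta),
              if (is.null(model$q_fixed)) logit(q0))
  npar <- length(theta0)
  free <- setdiff(seq_len(npar), fixed_idx)
  full <- function(th_free) {
    th <- numeric(npar)
    th[free] <- th_free
    th[fixed_idx] <- fixed_val
    th
  }
  negll <- function(th_free) -model_loglik(model, full(th_free))
  if (!length(free)) {
    th <- full(numeric(0))
    return(list(theta = th, loglik = model_loglik(model, th),
                converged = TRUE, iterations = 0L, free = free,
                npar = npar))
  }
  opt <- stats::optim(theta0[free], negll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = reltol,
                                     ndeps = rep(1e-5, length(free))))
  if (opt$convergence != 0)
    warning("optimizer did not converge (code ", opt$convergence, ")")
  list(theta = full(opt$par), loglik = -opt$value,
       converged = opt$convergence == 0,
       iterations = unname(opt$counts["function"]), free = free,
       npar = npar)
}

## Observed information, per-family scores, model-based and
## cluster-robust covariance of the FREE parameters at the MLE.
fit_inference <- function(model, fitted, score_step = 1e-5,
                          hess_step = 1e-4, df_correction = FALSE) {
  free <- fitted$free
  th <- fitted$theta
  f_free <- function(x) {
    t2 <- th; t2[free] <- x
    model_loglik(model, t2)
  }
  H <- num_hessian(f_free, th[free], h = hess_step)
  ## per-cell scores by central differences
  p <- length(free)
  C <- matrix(0, nrow(model$cells), p)
  for (j in seq_len(p)) {
    e <- th; e[free[j]] <- e[free[j]] + score_step
    f <- th; f[free[j]] <- f[free[j]] - score_step
    C[, j] <- (cell_loglik(model, e) - cell_loglik(model, f)) /
      (2 * score_step)
  }
  scores <- C[model$ind_cell, , drop = FALSE]
  A <- -H
  cov_model <- tryCatch(solve(A), error = function(e) {
    warning("information matrix is singular; covariance unavailable")
    matrix(NA_real_, p, p)
  })
  cov_robust <- tryCatch(
    sandwich_cov(scores, H, cluster = model$family,
                 df_correction = df_correction),
    error = function(e) {
      warning("robust covariance unavailable: ", conditionMessage(e))
      matrix(NA_real_, p, p)
    })
  list(hessian = H, scores = scores, cov_model = cov_model,
       cov_robust = cov_robust)
}
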