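## End-to-end pipeline: simulate (or read) -> eligibility -> QC ->
## fit(s) -> report bundle with a run manifest.

#' Run the carrier-modifier analysis pipeline
#'
#' Executes the configured stages in order and returns (and optionally
#' writes) a report bundle.  The configuration is a named list or the
#' path to a YAML file with entries:
#'
#' * `seed` (required integer) — drives every stochastic stage;
#' * `simulate` — arguments for [sim_config()] (synthetic input), or
#'   `input` with `carrier_table` and optionally `incidence` paths;
#' * `qc` — logical or list; runs genotyping QC and masks failing
#'   (study, SNP) strata;
#' * `fit` — list with `snps` (default: all genotype columns),
#'   `parametrization`, and `analyses`, any of `"overall"`,
#'   `"genotype2df"`, `"competing"`, `"subtype"`, `"heterogeneity"`,
#'   `"age_interaction"`; optional `exclude_prevalent` (window in
#'   years) and `group_diff` (grouping column, e.g. `mutation_class`);
#' * `out_dir` — where to write `manifest.json`, `report.json` and
#'   `report.tsv` (omit to keep everything in memory).
#'
#' Every reported number is traceable to the returned manifest (config
#' snapshot, seed, input hashes, stage timings, exclusion counts).
#'
#' @param config named list or YAML path.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with `manifest`, `records`, `qc`, `fits`
#'   and `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed))
    stop("config schema violation at 'seed': required integer")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config schema violation at 'simulate'/'input': one required")
  out_dir <- out_dir %||% config$out_dir
  manifest <- list(
    package_version = as.character(utils::packageVersion("carrierhr")),
    seed = config$seed, config = config, input_hashes = list(),
    timings = list(), exclusions = list())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## -- input ---------------------------------------------------------
  curves <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config,
                   c(config$simulate, list(seed = config$seed)))
    records <- simulate_cohort(cfg)
    curves <- cfg$curves
  } else {
    path <- config$input$carrier_table
    if (is.null(path))
      stop("config schema violation at 'input.carrier_table'")
    records <- read_carrier_table(path)
    manifest$input_hashes$carrier_table <- unname(tools::md5sum(path))
    if (!is.null(config$input$incidence)) {
      curves <- read_incidence(config$input$incidence)
      manifest$input_hashes$incidence <-
        unname(tools::md5sum(config$input$incidence))
    }
  }
  snp_names <- attr(records, "snp_names")
  manifest$timings$input <- tic() - t0

  ## -- eligibility ---------------------------------------------------
  records <- apply_eligibility(records)
  manifest$exclusions$eligibility <- nrow(attr(records, "excluded"))
  if (!is.null(config$fit$exclude_prevalent)) {
    records <- exclude_prevalent(records,
                                 config$fit$exclude_prevalent)
    manifest$exclusions$prevalent <- nrow(attr(records, "excluded"))
  }

  ## -- qc ------------------------------------------------------------
  qc <- NULL
  if (isTRUE(config$qc) || is.list(config$qc)) {
    t1 <- tic()
    geno <- as.matrix(records[, snp_names, drop = FALSE])
    rownames(geno) <- records$individual_id
    qc <- run_qc(records, geno)
    drop_samp <- qc$excluded_samples$sample_id
    records <- records[!(records$individual_id %in% drop_samp), ,
                       drop = FALSE]
    ex <- qc$excluded_study_snp
    for (i in seq_len(nrow(ex)))
      records[[ex$snp[i]]][records$study_id == ex$study[i]] <- NA
    attr(records, "snp_names") <- snp_names
    manifest$exclusions$qc_samples <- length(drop_samp)
    manifest$exclusions$qc_study_snp <- nrow(ex)
    manifest$timings$qc <- tic() - t1
  }

  ## -- fits ----------------------------------------------------------
  fits <- list(); report <- list()
  if (!identical(config$fit, FALSE)) {
    t1 <- tic()
    fit_cfg <- config$fit %||% list()
    snps <- fit_cfg$snps %||% snp_names
    analyses <- fit_cfg$analyses %||% "overall"
    for (snp in snps) {
      fs <- list()
      if ("overall" %in% analyses)
        fs$overall <- fit_snp(records, snp, effect_spec("trend"),
                              curves = curves)
      if ("genotype2df" %in% analyses)
        fs$genotype2df <- fit_snp(records, snp,
                                  effect_spec("genotype2df"),
                                  curves = curves)
      if ("competing" %in% analyses)
        fs$competing <- fit_competing(records, snp, curves = curves)
      if ("subtype" %in% analyses)
        fs$subtype <- fit_subtype(records, snp, curves = curves)
      if ("heterogeneity" %in% analyses)
        fs$heterogeneity <- test_heterogeneity(records, snp,
                                               curves = curves)
      if ("age_interaction" %in% analyses)
        fs$age_interaction <- test_age_interaction(records, snp,
                                                   curves = curves)
      if (!is.null(fit_cfg$group_diff))
        fs$group_diff <- test_group_difference(records, snp,
                                               fit_cfg$group_diff,
                                               curves = curves)
      fits[[snp]] <- fs
      report[[snp]] <- report_row(snp, fs)
    }
    manifest$timings$fit <- tic() - t1
  }
  manifest$timings$total <- tic() - t0

  bundle <- list(manifest = manifest, records = records, qc = qc,
                 fits = fits, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    tsv <- do.call(rbind, lapply(names(fits), function(snp) {
      do.call(rbind, lapply(names(fits[[snp]]), function(a) {
        f <- fits[[snp]][[a]]
        if (!inherits(f, "carrier_fit")) return(NULL)
        cbind(snp = snp, analysis = a, f$hr)
      }))
    }))
    if (!is.null(tsv))
      utils::write.table(tsv, file.path(out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bundle)
}

## One report entry per SNP: genotype counts by status plus the
## headline statistics of each requested analysis.
report_row <- function(snp, fs) {
  row <- list(snp = snp)
  get_test <- function(f, nm)
    if (!is.null(f$tests[[nm]])) f$tests[[nm]]$p else NULL
  if (!is.null(fs$overall)) {
    f <- fs$overall
    cnt <- f$counts
    row$gene <- f$gene
    row$n_unaffected <- sum(cnt[, "unaffected"])
    row$n_affected <- sum(cnt[, colnames(cnt) != "unaffected"])
    row$genotype_counts <- as.data.frame(cnt)
    row$per_allele <- list(hr = f$hr$hr[1], lcl = f$hr$lcl[1],
                           ucl = f$hr$ucl[1],
                           p_trend = get_test(f, "p_trend"))
    row$q_hat <- as.list(f$q)
  }
  if (!is.null(fs$genotype2df)) {
    f <- fs$genotype2df
    row$genotype_specific <- list(
      hr_het = f$hr$hr[1], hr_hom = f$hr$hr[2],
      p_2df = get_test(f, "p_2df"))
  }
  if (!is.null(fs$competing)) {
    f <- fs$competing
    row$competing <- list(
      hr_breast = f$hr$hr[1], hr_ovarian = f$hr$hr[2],
      p_trend_breast = get_test(f, "p_trend_breast"),
      p_trend_ovarian = get_test(f, "p_trend_ovarian"))
  }
  if (!is.null(fs$subtype)) {
    f <- fs$subtype
    row$subtype <- list(
      hr_er_pos = f$hr$hr[1], hr_er_neg = f$hr$hr[2],
      p_difference = get_test(f, "p_difference"))
  }
  if (!is.null(fs$heterogeneity))
    row$p_heterogeneity <- fs$heterogeneity$p
  if (!is.null(fs$age_interaction))
    row$p_age_interaction <- fs$age_interaction$p
  if (!is.null(fs$group_diff))
    row$p_group_difference <- fs$group_diff$p
  row
}
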