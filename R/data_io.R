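## Carrier tables, incidence curves, eligibility and censoring rules.
##
## Conventions (fixed across the package):
##  * ages are integer years; an event "at age t" occurs in [t, t+1)
##    (half-open yearly intervals);
##  * missing values are empty fields in the delimited files;
##  * ties among candidate censoring ages resolve in the fixed priority
##    breast > ovarian > mastectomy > last observation.

CARRIER_TABLE_VERSION <- 1L

.carrier_cols <- c(
  "individual_id", "family_id", "study_id", "country", "gene",
  "birth_year", "mutation_class", "age_last_obs", "bc_age", "oc_age",
  "mastectomy_age", "oophorectomy_age", "recruitment_age", "er_status"
)
.age_cols <- c("age_last_obs", "bc_age", "oc_age", "mastectomy_age",
               "oophorectomy_age", "recruitment_age")

#' Read a carrier phenotype/genotype table
#'
#' Reads a tab-separated carrier table (one row per mutation carrier) with
#' a versioned `#carrier_table_version=` header line, validates every row
#' against the domain invariants, and returns the valid records.  Rows
#' that violate an invariant are dropped and reported in the
#' `"rejected"` attribute with the offending line number and a
#' machine-readable reason code.
#'
#' Mandatory columns: `individual_id`, `family_id`, `study_id`,
#' `country`, `gene` (`BRCA1`/`BRCA2`), `birth_year`, `mutation_class`
#' (`class1`/`class2`/`other`/`unknown`), `age_last_obs`, `bc_age`,
#' `oc_age`, `mastectomy_age`, `oophorectomy_age`, `recruitment_age`,
#' `er_status` (`pos`/`neg`/empty), plus one column of minor-allele
#' doses (0/1/2, empty = missing) per SNP.  Unknown columns are ignored.
#'
#' @param path path to a TSV file.
#' @param snp_names character vector of SNP column names; if `NULL`,
#'   every column not in the documented phenotype set is treated as a SNP.
#' @return a `data.frame` of validated carrier records with attributes
#'   `snp_names` and `rejected`.
#' @export
read_carrier_table <- function(path, snp_names = NULL) {
  if (!file.exists(path)) stop("carrier table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"),
                          colClasses = "character")
  missing_cols <- setdiff(.carrier_cols, names(df))
  if (length(missing_cols))
    stop("carrier table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(snp_names))
    snp_names <- setdiff(names(df), c(.carrier_cols, "double_carrier"))
  missing_snp <- setdiff(snp_names, names(df))
  if (length(missing_snp))
    stop("carrier table format error: missing SNP column(s): ",
         paste(missing_snp, collapse = ", "))
  validate_carriers(df, snp_names)
}

## Validate and type a raw character data.frame of carrier rows.
## Returns typed records; invalid rows go to attr(, "rejected").
validate_carriers <- function(df, snp_names = character()) {
  n <- nrow(df)
  out <- df
  for (col in c("birth_year", .age_cols)) {
    suppressWarnings(out[[col]] <- as.numeric(df[[col]]))
  }
  for (s in snp_names) suppressWarnings(out[[s]] <- as.numeric(df[[s]]))
  reason <- character(n)
  bad_num <- function(col)
    !is.na(df[[col]]) & df[[col]] != "" & is.na(out[[col]])

  for (col in c("birth_year", .age_cols))
    reason[reason == "" & bad_num(col)] <-
      paste0("unparsable value in ", col)
  reason[reason == "" & is.na(out$age_last_obs)] <- "missing age_last_obs"
  reason[reason == "" & !(df$gene %in% c("BRCA1", "BRCA2"))] <-
    "invalid gene"
  reason[reason == "" &
           !(is.na(df$mutation_class) |
               df$mutation_class %in% c("class1", "class2", "other",
                                        "unknown"))] <-
    "invalid mutation_class"
  for (col in .age_cols)
    reason[reason == "" & !is.na(out[[col]]) & out[[col]] < 0] <-
      paste0("negative ", col)
  for (col in c("bc_age", "oc_age", "mastectomy_age", "oophorectomy_age"))
    reason[reason == "" & !is.na(out[[col]]) &
             out[[col]] > out$age_last_obs] <- "event after censoring"
  reason[reason == "" & !is.na(out$recruitment_age) &
           out$recruitment_age < 18] <- "recruited before age 18"
  reason[reason == "" &
           !(is.na(df$er_status) | df$er_status %in% c("pos", "neg"))] <-
    "invalid er_status"
  reason[reason == "" & !is.na(df$er_status) & is.na(out$bc_age)] <-
    "er_status without breast cancer"
  for (s in snp_names)
    reason[reason == "" & !is.na(out[[s]]) & !(out[[s]] %in% 0:2)] <-
      paste0("invalid genotype dose in ", s)

  keep <- reason == ""
  rejected <- data.frame(line = which(!keep),
                         individual_id = df$individual_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  for (r in seq_len(nrow(rejected)))
    log_msg("ROW_REJECTED", sprintf("line %d (%s): %s", rejected$line[r],
                                    rejected$individual_id[r],
                                    rejected$reason[r]))
  out <- out[keep, , drop = FALSE]
  out$mutation_class[is.na(out$mutation_class)] <- "unknown"
  out$er_status[is.na(out$er_status)] <- "missing"
  rownames(out) <- NULL
  attr(out, "snp_names") <- snp_names
  attr(out, "rejected") <- rejected
  out
}

#' Write a carrier table
#'
#' Inverse of [read_carrier_table()]: writes TSV with the versioned
#' header comment; missing values become empty fields.
#'
#' @param records carrier records as returned by [read_carrier_table()]
#'   or [simulate_cohort()].
#' @param path output path.
#' @export
write_carrier_table <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("#carrier_table_version=%d\n", CARRIER_TABLE_VERSION),
      file = con)
  df <- as.data.frame(records)
  df$er_status[df$er_status == "missing"] <- NA
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Apply cohort eligibility rules
#'
#' Excludes carriers of pathogenic mutations in both genes (rows flagged
#' in an optional logical `double_carrier` column) and keeps only the
#' first occurrence of any duplicated `individual_id`.  Exclusions are
#' logged with reason codes and returned alongside the kept records.
#'
#' @param records carrier records.
#' @return the kept records, with an `"excluded"` attribute listing
#'   `individual_id` and `reason` for every removed row.
#' @export
apply_eligibility <- function(records) {
  reason <- character(nrow(records))
  if (!is.null(records$double_carrier)) {
    dc <- records$double_carrier %in% c(TRUE, "TRUE", "1", 1)
    reason[dc] <- "double_carrier"
  }
  dup <- duplicated(records$individual_id)
  reason[reason == "" & dup] <- "duplicate_individual"
  keep <- reason == ""
  excluded <- data.frame(individual_id = records$individual_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  for (r in seq_len(nrow(excluded)))
    log_msg("ELIGIBILITY_EXCLUDED",
            sprintf("%s: %s", excluded$individual_id[r],
                    excluded$reason[r]))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("snp_names", "rejected"))
    attr(out, a) <- attr(records, a)
  attr(out, "excluded") <- excluded
  out
}

#' Derive follow-up (censoring) information for one carrier
#'
#' Applies the study's censoring rules.  In `breast_only` mode a carrier
#' is followed to the first of breast cancer diagnosis, ovarian cancer
#' diagnosis, bilateral prophylactic mastectomy, or last observation;
#' only a first breast cancer counts as affected, and carriers censored
#' at ovarian cancer are treated as unaffected.  In `competing` mode
#' follow-up ends at the first cancer diagnosis of either type, with the
#' per-disease risk sets additionally censored at the corresponding
#' prophylactic surgery (`bc_end` at mastectomy, `oc_end` at
#' oophorectomy); no follow-up is counted after a first cancer.
#'
#' @param record a single carrier record (one-row data.frame or list).
#' @param mode `"breast_only"` or `"competing"`.
#' @return an object of class `followup`: a list with `end_age`,
#'   `status` (`unaffected`/`breast`/`ovarian`), `bc_end`, `oc_end`.
#' @export
derive_followup <- function(record, mode = c("breast_only", "competing")) {
  mode <- match.arg(mode)
  fu <- followup_table(as.data.frame(record, stringsAsFactors = FALSE),
                       mode)
  structure(list(end_age = fu$end_age[1], status = fu$status[1],
                 bc_end = fu$bc_end[1], oc_end = fu$oc_end[1]),
            class = "followup")
}

## Vectorised follow-up derivation; the single-record exported wrapper
## and all fits go through this one code path.
followup_table <- function(records, mode = c("breast_only", "competing")) {
  mode <- match.arg(mode)
  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  last <- records$age_last_obs
  if (any(is.na(last))) stop("invalid record: age_last_obs missing")
  bc <- inf_na(records$bc_age)
  oc <- inf_na(records$oc_age)
  mast <- inf_na(records$mastectomy_age)
  ooph <- inf_na(records$oophorectomy_age)

  if (mode == "breast_only") {
    end <- pmin(bc, oc, mast, last)
    ## tie priority: breast > ovarian > mastectomy > last observation
    status <- ifelse(bc <= end, "breast", "unaffected")
    data.frame(end_age = end, status = status, bc_end = end,
               oc_end = end, stringsAsFactors = FALSE)
  } else {
    ebc <- ifelse(bc <= mast, bc, Inf)  # breast events after mastectomy
    eoc <- ifelse(oc <= ooph, oc, Inf)  # are censored, not counted
    t1 <- pmin(ebc, eoc, last)
    status <- ifelse(ebc <= t1, "breast",
                     ifelse(eoc <= t1, "ovarian", "unaffected"))
    data.frame(end_age = t1, status = status,
               bc_end = pmin(t1, mast), oc_end = pmin(t1, ooph),
               stringsAsFactors = FALSE)
  }
}

#' Read incidence (penetrance) curves
#'
#' Reads yearly population (carrier-average) cancer hazards from a CSV
#' with columns `disease` (`breast`/`ovarian`), `gene`, `cohort_band`
#' (optional; `"all"` when absent), `age` (integer year) and `hazard`.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `incidence_table`.
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("disease", "gene", "age", "hazard")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("incidence format error: missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$cohort_band)) df$cohort_band <- "all"
  df$cohort_band[is.na(df$cohort_band) | df$cohort_band == ""] <- "all"
  if (any(!is.finite(df$hazard)) || any(df$hazard < 0))
    stop("incidence format error: hazards must be finite and non-negative")
  class(df) <- c("incidence_table", "data.frame")
  df[c("disease", "gene", "cohort_band", "age", "hazard")]
}

#' Write incidence curves
#' @param curves an `incidence_table`.
#' @param path CSV path.
#' @export
write_incidence <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Illustrative carrier incidence curves
#'
#' Piecewise-constant yearly breast and ovarian cancer hazards for
#' mutation carriers on ages 18-79.  These are synthetic illustrative
#' constants in the high-penetrance range (cumulative breast cancer risk
#' to age 70 of roughly 55\% for BRCA1), packaged so that every stage of
#' the pipeline is runnable without external data.  They are *not*
#' external cohort estimates; real analyses should supply their own
#' curves via [read_incidence()].
#'
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param ages integer ages covered by the curve.
#' @return an `incidence_table` with breast and ovarian curves.
#' @export
default_incidence <- function(gene = c("BRCA1", "BRCA2"), ages = 18:79) {
  gene <- match.arg(gene)
  step <- function(cuts, vals) vals[findInterval(ages, cuts)]
  if (gene == "BRCA1") {
    breast  <- step(c(0, 30, 40, 50, 60), c(0.001, 0.010, 0.030, 0.025, 0.020))
    ovarian <- step(c(0, 40, 50),          c(0.0005, 0.010, 0.012))
  } else {
    breast  <- step(c(0, 30, 40, 50, 60), c(0.0005, 0.006, 0.020, 0.022, 0.020))
    ovarian <- step(c(0, 45, 55),          c(0.0002, 0.004, 0.008))
  }
  df <- rbind(
    data.frame(disease = "breast", gene = gene, cohort_band = "all",
               age = ages, hazard = breast),
    data.frame(disease = "ovarian", gene = gene, cohort_band = "all",
               age = ages, hazard = ovarian)
  )
  class(df) <- c("incidence_table", "data.frame")
  df
}

#' Illustrative ER-subtype proportions among carrier breast cancers
#'
#' Age-indexed fractions of carrier breast tumours that are estrogen
#' receptor positive, as a step function in age.  Illustrative defaults
#' (BRCA1 tumours predominantly ER-negative, BRCA2 predominantly
#' ER-positive); user-replaceable in every fitting function.
#'
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param ages integer ages.
#' @return data.frame with columns `age`, `pi_pos`, `pi_neg`.
#' @export
default_subtype_props <- function(gene = c("BRCA1", "BRCA2"), ages = 18:79) {
  gene <- match.arg(gene)
  pi_pos <- if (gene == "BRCA1") ifelse(ages < 50, 0.20, 0.35)
            else ifelse(ages < 50, 0.75, 0.80)
  data.frame(age = ages, pi_pos = pi_pos, pi_neg = 1 - pi_pos)
}
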