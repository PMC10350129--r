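# Reading, harmonizing, filtering and meta-analysing GWAS summary statistics.
#
# Two dialects are supported:
#   * "ldsc_munged": SNP, A1, A2, Z, N  (tab-delimited, optionally gzipped)
#   * "full": CHR, POS, SNP, A1, A2, BETA, SE, P, FREQ, INFO, N_EFF
# A1 is always the effect allele; Z/BETA signs follow A1; positions 1-based.

SUMSTAT_MUNGED_COLS <- c("SNP", "A1", "A2", "Z", "N")
SUMSTAT_FULL_COLS <- c("CHR", "POS", "SNP", "A1", "A2", "BETA", "SE", "P",
                       "FREQ", "N_EFF")

new_sumstat <- function(dt, cohort = NA_character_, symptom = NA_character_,
                        dialect = "full") {
  data.table::setDT(dt)
  data.table::setattr(dt, "cohort", cohort)
  data.table::setattr(dt, "symptom", symptom)
  data.table::setattr(dt, "dialect", dialect)
  data.table::setattr(dt, "class", c("sumstat", class(dt)))
  dt
}

#' @export
print.sumstat <- function(x, ...) {
  cat(sprintf("<sumstat> %d variants  cohort=%s symptom=%s dialect=%s\n",
              nrow(x), attr(x, "cohort"), attr(x, "symptom"),
              attr(x, "dialect")))
  NextMethod()
}

#' Validate a summary-statistic table
#'
#' Checks the invariants of the format: positive standard errors, p in
#' (0, 1], z = beta/se (within 1e-6) where all three are present, and unique
#' variant ids. Offending rows are reported with their (1-based) row numbers.
#'
#' @param dt a `sumstat` or data.frame with sumstat columns.
#' @return list with `ok` (logical) and `problems` (data.table of row, rule).
#' @export
validate_sumstats <- function(dt) {
  probs <- list()
  flag <- function(rows, rule) {
    if (length(rows)) probs[[length(probs) + 1L]] <<-
        data.table::data.table(row = rows, rule = rule)
  }
  if ("SE" %in% names(dt)) flag(which(!is.na(dt$SE) & dt$SE <= 0), "se_nonpositive")
  if ("P" %in% names(dt)) flag(which(!is.na(dt$P) & (dt$P <= 0 | dt$P > 1)), "p_out_of_range")
  if (all(c("BETA", "SE", "Z") %in% names(dt))) {
    i <- which(!is.na(dt$BETA) & !is.na(dt$SE) & !is.na(dt$Z) & dt$SE > 0)
    bad <- i[abs(dt$Z[i] - dt$BETA[i] / dt$SE[i]) > 1e-6]
    flag(bad, "z_beta_se_inconsistent")
  }
  dup <- which(duplicated(dt$SNP))
  flag(dup, "duplicate_variant_id")
  probs <- if (length(probs)) data.table::rbindlist(probs) else
    data.table::data.table(row = integer(), rule = character())
  list(ok = nrow(probs) == 0L, problems = probs)
}

#' Read GWAS summary statistics
#'
#' @param path tab-delimited file (gzip accepted by extension).
#' @param dialect "auto" (sniff the header), "ldsc_munged", or "full".
#' @param cohort,symptom provenance tags attached to the table.
#' @param drop_invalid drop invalid rows (with a warning listing their row
#'   numbers) rather than failing (default TRUE).
#' @return a `sumstat` data.table.
#' @export
read_sumstats <- function(path, dialect = c("auto", "ldsc_munged", "full"),
                          cohort = NA_character_, symptom = NA_character_,
                          drop_invalid = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", ""))
  if (dialect == "auto")
    dialect <- if (all(SUMSTAT_MUNGED_COLS %in% names(dt)) &&
                   !"BETA" %in% names(dt)) "ldsc_munged" else "full"
  need <- if (dialect == "ldsc_munged") SUMSTAT_MUNGED_COLS else
    c("SNP", "A1", "A2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  for (col in intersect(c("Z", "N", "BETA", "SE", "P", "FREQ", "INFO",
                          "N_EFF", "POS"), names(dt))) {
    if (!is.numeric(dt[[col]])) {
      v <- suppressWarnings(as.numeric(dt[[col]]))
      bad <- which(is.na(v) & !is.na(dt[[col]]))
      if (length(bad))
        warning(sprintf("column %s: non-numeric values at data row(s) %s",
                        col, paste(utils::head(bad, 10L), collapse = ", ")))
      data.table::set(dt, j = col, value = v)
    }
  }
  if (!"Z" %in% names(dt) && all(c("BETA", "SE") %in% names(dt)))
    dt[, "Z" := dt$BETA / dt$SE]
  chk <- validate_sumstats(dt)
  if (!chk$ok) {
    if (!drop_invalid) stop("invalid rows: ",
                            paste(utils::head(chk$problems$row, 10), collapse = ", "))
    warning(sprintf("dropping %d invalid row(s) [%s]", nrow(chk$problems),
                    paste(unique(chk$problems$rule), collapse = ", ")))
    dt <- dt[setdiff(seq_len(nrow(dt)), chk$problems$row)]
  }
  new_sumstat(dt, cohort, symptom, dialect)
}

#' Write summary statistics to disk
#'
#' @param dt `sumstat` table.
#' @param path output path; ".gz" suffix gzips.
#' @param dialect column subset to write.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dt, path,
                           dialect = c("full", "ldsc_munged")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "ldsc_munged") SUMSTAT_MUNGED_COLS else
    intersect(c(SUMSTAT_FULL_COLS, "Z", "INFO", "N"), names(dt))
  miss <- setdiff(cols, names(dt))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  data.table::fwrite(as.data.frame(dt)[, cols, drop = FALSE], path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize a summary-statistic table to a reference allele map
#'
#' For each variant the observed A1/A2 pair is reconciled with the reference:
#' direct match is kept; swapped alleles flip the sign of Z/BETA; strand
#' flips are resolved by complementing; strand-plus-swap flips the sign.
#' Palindromic (A/T, C/G) variants are strand-ambiguous and dropped when
#' `drop_ambiguous`. Irreconcilable variants are dropped and counted.
#' Output alleles are rewritten to the reference orientation, so the
#' operation is involutive.
#'
#' @param dt `sumstat` table.
#' @param reference data.frame with SNP, A1, A2.
#' @param drop_ambiguous drop palindromic variants (default TRUE).
#' @return harmonized `sumstat`; attribute `"harmonize_report"` counts
#'   kept / sign-flipped / strand-flipped / ambiguous / unmatched / mismatched.
#' @export
harmonize_sumstats <- function(dt, reference, drop_ambiguous = TRUE) {
  ref <- data.table::as.data.table(reference)[, c("SNP", "A1", "A2")]
  data.table::setnames(ref, c("SNP", "REF_A1", "REF_A2"))
  x <- data.table::as.data.table(dt)
  m <- merge(x, ref, by = "SNP", sort = FALSE)
  n_unmatched <- nrow(x) - nrow(m)
  comp1 <- ALLELE_COMPLEMENT[m$A1]
  comp2 <- ALLELE_COMPLEMENT[m$A2]
  ambiguous <- !is.na(comp2) & m$A1 == comp2
  same <- m$A1 == m$REF_A1 & m$A2 == m$REF_A2
  swap <- m$A1 == m$REF_A2 & m$A2 == m$REF_A1
  strand <- !is.na(comp1) & comp1 == m$REF_A1 & comp2 == m$REF_A2
  strand_swap <- !is.na(comp1) & comp1 == m$REF_A2 & comp2 == m$REF_A1
  if (drop_ambiguous) {
    same[ambiguous] <- swap[ambiguous] <- FALSE
    strand[ambiguous] <- strand_swap[ambiguous] <- FALSE
  }
  keep <- same | swap | strand | strand_swap
  flip <- (swap | strand_swap) & !same & !strand
  n_mismatch <- sum(!keep & !ambiguous)
  out <- m[keep]
  fl <- flip[keep]
  for (col in intersect(c("Z", "BETA"), names(out)))
    data.table::set(out, which(fl), col, -out[[col]][fl])
  if ("FREQ" %in% names(out))
    data.table::set(out, which(fl), "FREQ", 1 - out$FREQ[fl])
  out[, "A1" := out$REF_A1]
  out[, "A2" := out$REF_A2]
  out[, c("REF_A1", "REF_A2") := NULL]
  out <- new_sumstat(out, attr(dt, "cohort"), attr(dt, "symptom"),
                     attr(dt, "dialect") %||% "full")
  data.table::setattr(out, "harmonize_report", list(
    kept = nrow(out), sign_flipped = sum(fl),
    strand_flipped = sum((strand | strand_swap)[keep]),
    ambiguous_dropped = if (drop_ambiguous) sum(ambiguous) else 0L,
    unmatched = n_unmatched, mismatched = n_mismatch))
  out
}

#' Effective sample size of a case-control GWAS
#'
#' N_eff = 4 / (1/N_case + 1/N_control); equals the total N for a balanced
#' design and discounts unbalanced designs to the equivalent balanced power.
#' A meta-analysis's effective sample size is the sum over cohorts.
#'
#' @param n_case,n_control positive counts (vectorized).
#' @return effective sample size(s).
#' @export
effective_n <- function(n_case, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0))
    stop("case and control counts must be positive")
  4 / (1 / n_case + 1 / n_control)
}

#' QC thresholds for summary statistics
#'
#' @param min_info minimum imputation INFO (default 0.9).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param min_n_eff minimum effective sample size (default 5000, the
#'   LD-score-estimation inclusion threshold).
#' @param drop_ambiguous drop palindromic variants during harmonization.
#' @return `qc_config` list.
#' @export
qc_config <- function(min_info = 0.9, min_maf = 0.01, min_n_eff = 5000,
                      drop_ambiguous = TRUE) {
  stopifnot(min_info >= 0, min_info <= 1, min_maf >= 0, min_maf < 0.5,
            min_n_eff >= 0)
  structure(list(min_info = min_info, min_maf = min_maf,
                 min_n_eff = min_n_eff, drop_ambiguous = drop_ambiguous),
            class = "qc_config")
}

#' Filter a summary-statistic table
#'
#' Applies the QC thresholds; every dropped variant is attributed to exactly
#' one rule (the first failing, in the order INFO, MAF, N_eff) in the report.
#'
#' @param dt `sumstat` table.
#' @param config a [qc_config()].
#' @return filtered `sumstat` with attribute `"qc_report"` (data.table of
#'   rule, dropped).
#' @export
qc_sumstats <- function(dt, config = qc_config()) {
  x <- data.table::as.data.table(dt)
  reason <- rep(NA_character_, nrow(x))
  if ("INFO" %in% names(x))
    reason[is.na(reason) & !is.na(x$INFO) & x$INFO < config$min_info] <- "info"
  if ("FREQ" %in% names(x)) {
    maf <- pmin(x$FREQ, 1 - x$FREQ)
    reason[is.na(reason) & !is.na(maf) & maf < config$min_maf] <- "maf"
  }
  ncol_ <- if ("N_EFF" %in% names(x)) "N_EFF" else if ("N" %in% names(x)) "N"
  if (!is.null(ncol_))
    reason[is.na(reason) & x[[ncol_]] < config$min_n_eff] <- "n_eff"
  rep_dt <- data.table::data.table(rule = c("info", "maf", "n_eff"))
  rep_dt[, "dropped" := vapply(rep_dt$rule, function(r)
    sum(reason == r, na.rm = TRUE), integer(1))]
  out <- new_sumstat(x[is.na(reason)], attr(dt, "cohort"),
                     attr(dt, "symptom"), attr(dt, "dialect") %||% "full")
  data.table::setattr(out, "qc_report", rep_dt)
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Per variant, weights w_i = 1/se_i^2 give pooled beta = sum(w b)/sum(w) and
#' pooled se = sum(w)^(-1/2). Variants present in any cohort are retained
#' (union semantics) with a per-variant count of contributing cohorts;
#' N/N_EFF are summed over contributors. Tables must already be harmonized
#' to a common allele reference.
#'
#' @param tables list of `sumstat` tables with BETA and SE.
#' @return meta-analysed `sumstat` with columns BETA, SE, Z, P, N_EFF,
#'   N_COHORTS.
#' @export
ivw_meta <- function(tables) {
  stopifnot(length(tables) >= 1L)
  for (t in tables)
    if (!all(c("BETA", "SE") %in% names(t)))
      stop("ivw_meta requires BETA and SE in every table")
  all_dt <- data.table::rbindlist(lapply(tables, function(t) {
    data.table::as.data.table(t)[, intersect(
      c("SNP", "A1", "A2", "BETA", "SE", "FREQ", "N", "N_EFF", "CHR", "POS"),
      names(t)), with = FALSE]
  }), fill = TRUE)
  al <- unique(all_dt[, c("SNP", "A1", "A2")])
  if (anyDuplicated(al$SNP))
    stop("tables are not harmonized: conflicting alleles for some variants")
  if (length(tables) > 1L) {
    shared <- Reduce(intersect, lapply(tables, function(t) t$SNP))
    if (length(shared) == 0L)
      warning("no variant shared by all cohorts; union semantics apply")
  }
  for (col in c("N", "N_EFF", "FREQ"))
    if (!col %in% names(all_dt)) all_dt[, (col) := NA_real_]
  w <- 1 / all_dt$SE^2
  all_dt[, "w" := w]
  all_dt[, "wb" := w * all_dt$BETA]
  agg <- all_dt[, list(
    A1 = A1[1L], A2 = A2[1L],
    BETA = sum(wb) / sum(w), SE = 1 / sqrt(sum(w)),
    N_EFF = {
      ne <- if (all(is.na(N_EFF))) N else N_EFF
      if (all(is.na(ne))) NA_real_ else sum(ne, na.rm = TRUE)
    },
    FREQ = if (all(is.na(FREQ))) NA_real_ else mean(FREQ, na.rm = TRUE),
    N_COHORTS = .N), by = "SNP"]
  agg[, "Z" := agg$BETA / agg$SE]
  agg[, "P" := 2 * stats::pnorm(-abs(agg$Z))]
  new_sumstat(agg, cohort = "meta",
              symptom = attr(tables[[1L]], "symptom"))
}
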