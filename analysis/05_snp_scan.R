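#!/usr/bin/env Rscript
# Stage 5: genomic factor meta-analysis of the community symptoms - per-SNP
# common-pathway effects on the general factor and the Q_SNP heterogeneity
# statistic, after the well-powered-symptom filter.

suppressPackageStartupMessages(library(symfactor))
out <- "results/scan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
src <- "results/demo"
if (!file.exists(file.path(src, "ld_scores.tsv")))
  stop("run analysis/01_simulate_cohorts.R first")

files <- list.files(file.path(src, "sumstats"), pattern = "^comm",
                    full.names = TRUE)
tabs <- lapply(files, read_sumstats)
names(tabs) <- sub("\\.sumstats$", "", basename(files))
poly <- Reduce(intersect, lapply(tabs, function(t) t$SNP))
tabs <- lapply(tabs, function(t) t[match(poly, t$SNP)])
ldt <- read.delim(file.path(src, "ld_scores.tsv"))
ld <- ld_scores(poly, ldt$L2[match(poly, ldt$SNP)], M = nrow(ldt))
k <- length(tabs)
scv <- build_S_V(tabs, ld, n_blocks = max(200, k * (k + 1) / 2 + 30))

wp <- well_powered_filter(scv, min_n_eff = 500)
cat("Well-powered symptoms (h2 > 0, mean chi2 > 1.02, N_eff > 500):\n")
print(wp$table[, c("label", "h2_obs", "mean_chi2", "included")],
      digits = 3)
stopifnot(length(wp$included) >= 2)

scan <- factor_meta_scan(tabs[wp$included], scv, seed = 42)
cat(sprintf("\nScanned %d variants (%d skipped).\n", nrow(scan),
            length(attr(scan, "skipped"))))
cat("Top five factor associations:\n")
print(as.data.frame(scan[1:5, c("SNP", "beta_f", "se", "p", "q_snp", "p_q",
                                "tier")]), digits = 3, row.names = FALSE)
cat(sprintf("\nQ_SNP heterogeneity: %d of %d variants at p_Q < 0.05 (%.1f%%)\n",
            sum(scan$p_q < 0.05), nrow(scan),
            100 * mean(scan$p_q < 0.05)))
cat("About half of each symptom's genetic variance is symptom-specific in\n",
    "this study (loadings 0.7), so widespread heterogeneity is the expected\n",
    "signature; the nominal-rate calibration under a pure common pathway\n",
    "(no specific genetic variance) is exercised in the test suite.\n",
    sep = "")

data.table::fwrite(scan, file.path(out, "factor_scan.tsv"), sep = "\t")
cat("Wrote", file.path(out, "factor_scan.tsv"), "\n")
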