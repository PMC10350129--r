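#!/usr/bin/env Rscript
# Stage 6: genetic regression of external traits on the symptom factors.
#
# Two synthetic external traits are generated alongside the community
# symptoms: one sharing the symptom factor's genetics (a depression
# correlate) and one genetically unrelated. Single regressions give the
# marginal genetic relationship; the multiple regression adjusts each
# factor for the others. Benjamini-Yekutieli FDR is applied across tests.

suppressPackageStartupMessages(library(symfactor))
out <- "results/regression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# simulate symptoms plus external traits from an extended truth: factor 1
# carries the symptoms, factor 2 an unrelated trait axis
labs <- c("Dep", "Anh", "Fatig", "Guilt", "Sui", "Correlate", "Unrelated")
L <- cbind(c(rep(0.7, 5), 0.5, 0), c(rep(0, 5), 0, 0.6))
truth <- true_structure(labs, L, h2_liab = c(rep(0.2, 5), 0.3, 0.3),
                        prevalence_pop = c(rep(0.25, 5), 0.5, 0.5))
co <- cohort_design("c", "community", 20000)
l <- synthetic_ld_profile(4000, seed = 42)
cfg <- simulation_config(truth, list(co), m_snps = 4000, seed = 42,
                         mode = "sumstat_direct", ld = l)
sim <- simulate_sumstats_direct(cfg)
tabs <- sim$tables$c
ld <- ld_scores(tabs[[1]]$SNP, l, M = 4000)
k <- length(tabs)
scv <- build_S_V(tabs, ld, n_blocks = max(200, k * (k + 1) / 2 + 30))

meas <- build_factor_spec(list(MDD = labs[1:5]), labs[1:5])
rows <- list()
for (trait in c("Correlate", "Unrelated")) {
  for (mode in c("single", "multiple")) {
    r <- genetic_regression(scv, meas, trait = trait, mode = mode,
                            seed = 42)
    rows[[paste(trait, mode)]] <- r
  }
}
res <- data.table::rbindlist(rows)
res$q_by <- fdr_by(res$p)

cat("Genetic regression of external traits on the symptom factor:\n")
print(as.data.frame(res[, c("trait", "factor", "mode", "beta", "se", "p",
                            "q_by")]), digits = 3, row.names = FALSE)
cat("\nThe shared-genetics trait should show a clear positive coefficient",
    "\n(truth: 0.5 on the factor scale) and the unrelated trait a null.\n")

data.table::fwrite(res, file.path(out, "genetic_regressions.tsv"),
                   sep = "\t")
cat("Wrote", file.path(out, "genetic_regressions.tsv"), "\n")
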