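#!/usr/bin/env Rscript
# Simulates the longitudinal photoaging study with known ground truth:
# 25 photoaging + 10 control animals, 12 weekly five-site measurements of
# eta_collagen and eta_porphyrins, biopsy withdrawals after weeks 5/10/12
# and per-week anesthetic mortality.

library(uvskin)
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = 20260925L)
co <- simulate_cohort(cfg)
write_cohort_csv(co, "results/cohort.csv")

obs <- observed_rows(co)
counts <- table(obs$group, obs$week)
cat("Animals contributing a measurement, by group and week:\n")
print(counts)
cat(sprintf("\nRemaining at week 10: photoaging %d, control %d\n",
            counts["photoaging", "10"], counts["control", "10"]))
cat("wrote results/cohort.csv\n")
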