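#!/usr/bin/env Rscript
# Step 0 -- generate the synthetic two-cohort longitudinal dataset.
#
# Emulates the study frame the models assume: cohort A measured near
# birth, 6 and 10 years, cohort B near birth, 7.5 and 17 years, with
# partial attendance, plate batches of 96, child-level random intercepts
# and slopes and a small plate effect.  The CpG panel mixes the eight
# trajectory archetypes (known labels, used later by 04_classify) with
# null and linear-change CpGs.
#
# Writes: results/betas.tsv, results/sample_sheet.tsv,
#         results/truth.tsv, results/simulation_log.txt

suppressMessages(library(methtraj))
seed <- 20260915L
dir.create("results", showWarnings = FALSE)

set.seed(seed)
arch <- trajectory_archetypes()
panel <- archetype_table(n_cpgs = nrow(arch), beta0 = 0.5,
                         beta1 = arch$beta1, beta2 = arch$beta2,
                         beta3 = arch$beta3, sigma2_age = 0,
                         sigma2_age6p = 0, sigma2_age9p = 0,
                         sigma2_plate = 1e-5)
# heterogeneous between-child intercept variance across CpGs gives the
# per-CpG concordance estimates something real to agree on across cohorts
extra <- archetype_table(n_cpgs = 52,
                         beta1 = c(rep(0, 26), rnorm(26, -9e-4, 1e-3)),
                         sigma2_intercept = rlnorm(52, log(1e-3), 1),
                         sigma2_age = c(rep(0, 26), rep(2e-6, 26)))
tab <- rbind(panel, extra)
tab$cpg_id <- sprintf("cg%07d", seq_len(nrow(tab)))

cfg <- sim_config(n_children = c(A = 300, B = 250),
                  archetypes = tab, seed = seed)
sim <- simulate_cohort(cfg)

write_beta_matrix(sim$betas, "results/betas.tsv")
write_sample_sheet(sim$meta, "results/sample_sheet.tsv")
truth <- data.frame(cpg_id = tab$cpg_id,
                    label = c(arch$label, rep(NA, nrow(extra))),
                    beta1 = tab$beta1)
write.table(truth, "results/truth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cs <- cohort_summary(sim$meta)
log <- c(sprintf("seed: %d", seed),
         sprintf("CpGs: %d (8 archetypes, 26 null, 26 linear-change)",
                 nrow(sim$betas)),
         capture.output(print(cs)),
         sprintf("truncation events: %d (fraction %.2e)",
                 sim$truncation$count, sim$truncation$fraction))
writeLines(log, "results/simulation_log.txt")
cat(paste(log, collapse = "\n"), "\n")
cat("Found: a", nrow(sim$betas), "CpG x", ncol(sim$betas),
    "sample beta matrix with the intended two-cohort age coverage.\n")
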