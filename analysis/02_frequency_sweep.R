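#!/usr/bin/env Rscript
# Frequency sweep of the fiber-free viscoelastic cell (1, 20, 45 Hz),
# run in both solver modes, with peaks compared against the published
# values.
#
# Finding: peak stress and strain are nearly identical across 1-45 Hz in
# both quasi-static and implicit-dynamic mode. The 1 Hz strain peaks agree
# with the published 1 Hz values; the published 3-5x amplification at
# 45 Hz is not recovered by the stated model (see the methods vignette).

library(cellstrain)
dir.create("results", showWarnings = FALSE)

cfg_q <- suite_config(scenarios = paste0("baseline_", c(1, 20, 45), "Hz"),
                      target_edge = 0.8, mode = "quasi_static",
                      steps_per_cycle = 24, seed = 1)
res_q <- run_suite(cfg_q, keep_series = FALSE)
res_q$table$solver_mode <- "quasi_static"

cfg_d <- cfg_q
cfg_d$mode <- "dynamic_newmark"
res_d <- run_suite(cfg_d)
res_d$table$solver_mode <- "dynamic_newmark"

tab <- rbind(res_q$table, res_d$table)
write.csv(tab, "results/frequency_sweep.csv", row.names = FALSE)
print(tab[, c("scenario", "solver_mode", "region", "quantity", "peak",
              "ratio_vs_1hz")], digits = 4)

cmp <- compare_to_reference(res_q$table)
write.csv(cmp, "results/frequency_sweep_vs_published.csv", row.names = FALSE)
print(cmp, digits = 3)
message("note: 45 Hz rows miss the published amplification in both modes; ",
        "1 Hz strain rows agree (see results/frequency_sweep_vs_published.csv)")
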