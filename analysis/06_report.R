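#!/usr/bin/env Rscript
# Aggregated comparison against the published peak values. Reads the
# summary tables written by scripts 02-05 (run those first) and emits one
# report with ratio and pass/fail at the +/-30% band used throughout.

library(cellstrain)

paths <- c("results/frequency_sweep.csv", "results/nucleus_stiffness.csv",
           "results/cytoskeleton.csv")
have <- file.exists(paths)
if (!any(have)) stop("run analysis scripts 02-05 first", call. = FALSE)
tabs <- lapply(paths[have], read.csv)
tab <- do.call(rbind, lapply(tabs, function(t)
  t[, c("scenario", "frequency_hz", "region", "quantity", "peak",
        "frame_time_s", "excluded_policy", "ratio_vs_1hz")]))
tab <- tab[!duplicated(tab[, c("scenario", "region", "quantity")]), ]

rep <- compare_to_reference(tab)
write.csv(rep, "results/published_comparison.csv", row.names = FALSE)
print(rep[, c("scenario", "region", "quantity", "paper_value", "computed",
              "ratio", "pass")], digits = 3)

message(sprintf("\n%d of %d published values within +/-30%%", sum(rep$pass),
                nrow(rep)))
message("misses concentrate in the 45 Hz rows: with the stated parameters ",
        "the model response is frequency-flat over 1-45 Hz in both solver ",
        "modes (storage modulus varies < 0.01%, inertia negligible), so ",
        "the published high-frequency amplification is not reproduced.")
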