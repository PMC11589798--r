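#!/usr/bin/env Rscript
# Sensitivity analysis: how much of the disparity-elimination benefit
# depends on what agents do on non-PA days (0, 30, 45 minutes)?
# Writes results/nonpa_sensitivity.csv.

suppressMessages(library(paequity))

scale <- 0.0012
n_rep <- 10
seed <- 20240904

params <- load_params()
ref <- load_growth_reference()

rows <- list()
for (npa in c(0, 30, 45)) {
  message("non-PA-day minutes = ", npa, " ...")
  grid <- run_experiment_grid(params, "pa_days", fractions = 1,
                              scale = scale, n_replicates = n_rep,
                              base_seed = seed, non_pa_minutes = npa,
                              horizon = "childhood", ref = ref)
  s <- grid$summary
  s$non_pa_minutes <- npa
  rows[[length(rows) + 1L]] <- s
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/nonpa_sensitivity.csv", row.names = FALSE)

tot <- out[out$group == "total" & out$outcome == "cases_averted", ]
message("overweight/obesity cases averted by full elimination:")
for (i in seq_len(nrow(tot))) {
  message(sprintf("  %2d min on non-PA days: %10.0f  [%.0f, %.0f]",
                  tot$non_pa_minutes[i], tot$mean[i], tot$lo[i],
                  tot$hi[i]))
}
message("less activity on non-PA days widens the effective disparity, ",
        "so the benefit of eliminating it grows.")
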