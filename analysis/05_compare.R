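#!/usr/bin/env Rscript
# Stage 5: between-method comparison statistics, for (a) the synthetic run
# of stages 1-4 and (b) the published net-estimate tables, whose
# recomputed comparison statistics should reproduce the published
# comparison table.

library(phasecost)
library(data.table)

est <- readRDS("scratch/analysis/04_estimates.rds")
cmp_syn <- method_comparison(est$matched, est$fe, round_report = TRUE)
fwrite(cmp_syn, "results/05_comparison_synthetic.csv")

ref <- reference_net_estimates()
cmp_pub <- method_comparison(
  ref[, .(treatment_type, phase, net_usd_pppm = matched_usd_pppm)],
  ref[, .(treatment_type, phase, net_usd_pppm = fe_usd_pppm)],
  round_report = TRUE)
fwrite(cmp_pub, "results/05_comparison_published_inputs.csv")

tot_syn <- cmp_syn[treatment_type == "Total"]
tot_pub <- cmp_pub[treatment_type == "Total"]
message("synthetic Total proportional differences (%): ",
        paste(sprintf("%s=%.1f", tot_syn$phase,
                      tot_syn$proportional_difference_pct), collapse = " "))
message("published-input Total proportional differences (%): ",
        paste(sprintf("%s=%.1f", tot_pub$phase,
                      tot_pub$proportional_difference_pct), collapse = " "))
message("terminal-phase absolute divergence, synthetic run: $",
        tot_syn[phase == "terminal", absolute_difference_usd])
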