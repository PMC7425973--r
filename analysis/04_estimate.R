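#!/usr/bin/env Rscript
# Stage 4: net expenditure PPPM by treatment type and phase, with both
# methods (price-revision deflated to 2018, converted at $1 = 102.5 yen).

library(phasecost)
library(data.table)

pop <- readRDS("scratch/analysis/01_population.rds")$pop
coh <- readRDS("scratch/analysis/02_cohorts.rds")
mts <- readRDS("scratch/analysis/03_matches.rds")
adj <- price_adjustment()

matched_tbl <- rbind(
  suppressWarnings(matched_net_estimates(mts$incident$pairs, coh$phase_maps,
                                         pop$claims, coh$register, adj)),
  suppressWarnings(matched_net_estimates(mts$death$pairs, coh$phase_maps,
                                         pop$claims, coh$register, adj)))

reg <- coh$register
fe_tbl <- rbind(
  fixed_effects_estimates(reg[patient_id %in% mts$incident$pairs$case_id],
                          coh$phase_maps, pop$claims, pop$demographics,
                          "incident", adj),
  fixed_effects_estimates(reg[patient_id %in% mts$death$pairs$case_id],
                          coh$phase_maps, pop$claims, pop$demographics,
                          "death", adj))

saveRDS(list(matched = matched_tbl, fe = fe_tbl),
        "scratch/analysis/04_estimates.rds")
num <- function(x) round(x)
fwrite(matched_tbl[, .(cohort, treatment_type, phase, n,
                       reference_usd_pppm = num(reference_usd_pppm),
                       net_usd_pppm = num(net_usd_pppm),
                       ci_low = num(ci_low), ci_high = num(ci_high))],
       "results/04_matched_estimates.csv")
fwrite(fe_tbl[, .(cohort, treatment_type, phase, n,
                  reference_usd_pppm = num(reference_usd_pppm),
                  net_usd_pppm = num(net_usd_pppm),
                  ci_low = num(ci_low), ci_high = num(ci_high))],
       "results/04_fe_estimates.csv")

tot_m <- matched_tbl[treatment_type == "Total"]
tot_f <- fe_tbl[treatment_type == "Total"]
message("Total net USD PPPM, matched:   ",
        paste(sprintf("%s=%0.f", tot_m$phase, tot_m$net_usd_pppm),
              collapse = " "))
message("Total net USD PPPM, fixed-eff: ",
        paste(sprintf("%s=%0.f", tot_f$phase, tot_f$net_usd_pppm),
              collapse = " "))
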