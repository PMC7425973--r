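#!/usr/bin/env Rscript
# Stage 3: exact matching. Incident cohort: same stratum (sex, 5-year age
# band, 15 conditions) and utilization in the index month, expanding up to
# 12 months; death cohort: same stratum and same death month, no expansion.

library(phasecost)
library(data.table)

pop <- readRDS("scratch/analysis/01_population.rds")$pop
coh <- readRDS("scratch/analysis/02_cohorts.rds")

keys <- phasecost:::patient_month_keys(pop$claims, pop$demographics)
inc <- match_incident(coh$register, pop$claims, pop$demographics,
                      seed = 101L, keys = keys)
dth <- match_death(coh$register, pop$claims, pop$demographics,
                   seed = 102L, keys = keys)
saveRDS(list(incident = inc, death = dth), "scratch/analysis/03_matches.rds")

n_elig <- sum(coh$register$eligible)
n_dth_elig <- sum(coh$register$eligible & !is.na(coh$register$death_month))
match_summary <- data.table(
  cohort = c("incident", "death"),
  eligible = c(n_elig, n_dth_elig),
  matched = c(nrow(inc$pairs), nrow(dth$pairs)),
  unmatched = c(nrow(inc$unmatched), nrow(dth$unmatched)),
  offset_zero = c(sum(inc$pairs$anchor_offset == 0L),
                  nrow(dth$pairs)))
match_summary[, match_rate_pct := round(100 * matched / eligible, 1)]
fwrite(match_summary, "results/03_match_summary.csv")

offsets <- inc$pairs[, .N, by = anchor_offset][order(anchor_offset)]
fwrite(offsets, "results/03_incident_offsets.csv")

message("incident: ", nrow(inc$pairs), "/", n_elig, " matched; death: ",
        nrow(dth$pairs), "/", n_dth_elig, " matched")
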