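#!/usr/bin/env Rscript
# Stage 2: screen cases (12-month cancer-free lookback, age >= 20, treated,
# non-recurrent), assign phases of care, and tabulate the cohort.

library(phasecost)
library(data.table)

inp <- readRDS("scratch/analysis/01_population.rds")
pop <- inp$pop

register <- build_case_register(pop$claims, pop$demographics)
phase_maps <- build_phase_maps(register, pop$claims)
saveRDS(list(register = register, phase_maps = phase_maps),
        "scratch/analysis/02_cohorts.rds")

excl <- register[, .N, by = exclusion_reason][order(-N)]
fwrite(excl, "results/02_exclusions.csv")

phase_counts <- phase_maps[, .(patient_months = .N,
                               patients = data.table::uniqueN(patient_id)),
                           by = phase]
fwrite(phase_counts, "results/02_phase_counts.csv")

tt <- register[eligible == TRUE, .N, by = treatment_type][order(-N)]
fwrite(tt, "results/02_treatment_types.csv")

message(sum(register$eligible), " eligible cases of ", nrow(register),
        " flagged; exclusions: ",
        paste(sprintf("%s=%d", excl$exclusion_reason[excl$exclusion_reason != ""],
                      excl$N[excl$exclusion_reason != ""]), collapse = ", "))
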