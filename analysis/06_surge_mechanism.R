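#!/usr/bin/env Rscript
# Stage 6: isolate the terminal-phase divergence mechanism. A baseline
# expenditure surge common to ALL decedents in their last 6 months is
# invisible to the matched comparison (the matched control dies the same
# month and surges too) but loads fully onto the fixed-effects terminal
# coefficient (the patient's own pre-disease months have no surge). The
# gap between the estimators should therefore grow with the surge
# multiplier.

library(phasecost)
library(data.table)

flat <- price_adjustment(rates = c("2010" = 1, "2012" = 1, "2014" = 1,
                                   "2016" = 1))
one_run <- function(mult, seed) {
  cfg <- simulation_config(
    n_patients = 4000, study_start = "2011-04", study_end = "2016-03",
    seed = seed, hcc_monthly_hazard = 1.8e-3, post_hcc_death_hazard = 0.05,
    background_death_hazard = 0.005, eol_surge_multiplier = mult,
    phase_increment_yen = uniform_phase_increments(
      3684 * 102.5, 285 * 102.5, 208 * 102.5))
  pop <- generate_population(cfg)
  reg <- build_case_register(pop$claims, pop$demographics)
  pm <- build_phase_maps(reg, pop$claims)
  dth <- match_death(reg, pop$claims, pop$demographics, seed = seed + 1L)
  m <- suppressWarnings(matched_net_estimates(dth$pairs, pm, pop$claims,
                                              reg, flat))
  fe <- fixed_effects_estimates(reg[patient_id %in% dth$pairs$case_id], pm,
                                pop$claims, pop$demographics, "death", flat,
                                by_treatment = FALSE)
  data.table(surge_multiplier = mult, n_pairs = nrow(dth$pairs),
             matched_terminal_usd = round(m[treatment_type == "Total",
                                            net_usd_pppm]),
             fe_terminal_usd = round(fe$net_usd_pppm))
}

grid <- rbindlist(lapply(c(1, 2, 3), function(mult) {
  reps <- rbindlist(lapply(1:5, function(r) one_run(mult, 700L + 10L * mult + r)))
  reps[, .(n_pairs = sum(n_pairs),
           matched_terminal_usd = round(mean(matched_terminal_usd)),
           fe_terminal_usd = round(mean(fe_terminal_usd))),
       by = surge_multiplier]
}))
grid[, gap_usd := fe_terminal_usd - matched_terminal_usd]
fwrite(grid, "results/06_surge_grid.csv")
print(grid)
message("terminal-phase gap grows with the end-of-life surge: ",
        paste(grid$gap_usd, collapse = " -> "))
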