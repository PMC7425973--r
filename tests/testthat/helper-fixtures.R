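library(data.table)

# hand-built claims rows with the full panel schema; unspecified flags are 0
fab_claims <- function(pid, months, expenditure = 0, dx_hcc = 0,
                       dx_other_cancer = 0, flags = list(), tx = list()) {
  months <- ym(months)
  n <- length(months)
  dt <- data.table(
    patient_id = as.integer(pid), month = months,
    expenditure_yen = rep_len(expenditure, n),
    dx_hcc = as.integer(rep_len(dx_hcc, n)),
    dx_other_cancer = as.integer(rep_len(dx_other_cancer, n)))
  for (cc in phasecost:::cci_columns()) {
    v <- if (cc %in% names(flags)) flags[[cc]] else 0L
    dt[, (cc) := as.integer(rep_len(v, n))]
  }
  for (tc in phasecost:::tx_columns()) {
    v <- if (tc %in% names(tx)) tx[[tc]] else 0L
    dt[, (tc) := as.integer(rep_len(v, n))]
  }
  dt
}

fab_demo <- function(pid, sex = "F", birth = "1950-01", death = NA) {
  data.table(patient_id = as.integer(pid), sex = sex,
             birth_month = ym(birth),
             death_month = if (length(death) == 1L && is.na(death))
               NA_integer_ else ym(death))
}

fab_register <- function(pid, index, death = NA,
                         treatment_type = "Surgical resection only") {
  data.table(patient_id = as.integer(pid), index_month = ym(index),
             death_month = if (length(death) == 1L && is.na(death))
               NA_integer_ else ym(death),
             treatment_type = treatment_type, eligible = TRUE,
             exclusion_reason = "")
}

# identity price adjustment (all revision rates 1) in yen units, so that
# injected yen amounts pass through estimators unchanged
flat_adjustment <- function(ppp = 1) {
  price_adjustment(rates = c("2010" = 1, "2012" = 1, "2014" = 1, "2016" = 1),
                   ppp_yen_per_usd = ppp)
}

# compact simulated population for integration-style tests
small_population <- function(seed = 1, n = 4000, ...) {
  cfg <- simulation_config(
    n_patients = n, study_start = "2011-04", study_end = "2015-03",
    seed = seed, hcc_monthly_hazard = 1.5e-3,
    post_hcc_death_hazard = 0.04, background_death_hazard = 0.004, ...)
  generate_population(cfg)
}
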