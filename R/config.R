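#' Simulation configuration for the synthetic claims generator
#'
#' Defines the statistical structure of a synthetic monthly claims panel:
#' a right-skewed gamma baseline expenditure process whose patient-level
#' mean scales with age band and comorbidity burden, hepatocellular
#' carcinoma (HCC) onset as a constant monthly hazard, phase-specific
#' incremental costs injected on top of the baseline for cases, competing
#' background and post-HCC mortality, and an end-of-life expenditure surge
#' applied to the baseline of *all* decedents (HCC and non-HCC alike) in
#' their last `eol_surge_months` months of life.
#'
#' Defaults emulate the conditions of a nationwide Japanese HCC claims
#' study: an April 2010 to March 2018 window, case characteristics (age
#' distribution centred near 72, 34.9% female, condition prevalences) taken
#' from its published cohort tables, a treatment-type mix equal to its
#' published initial-phase case distribution, and injected increments equal
#' to its published net estimates (fixed-effects estimates for the initial
#' and continuing phases, matched estimates for the terminal phase,
#' converted to yen and floored at zero).
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end Calendar months (`"YYYY-MM"`), inclusive.
#' @param seed Integer RNG seed; identical configs give bit-identical panels.
#' @param baseline_mean_yen Population mean of monthly baseline expenditure
#'   among utilized months (yen). Patient-level means are scaled by age band,
#'   comorbidity score and frailty, then normalized so the population mean is
#'   preserved.
#' @param baseline_shape Gamma shape of monthly baseline expenditure
#'   (smaller = more right-skewed).
#' @param age_dist Named probability vector over the 5-year age bands of
#'   [age_band()]. Default: a discretized normal with mean 72, SD 11,
#'   truncated to ages 20-99.
#' @param sex_prob_female Probability a patient is female.
#' @param cci_prevalence Named vector of 15 baseline condition prevalences
#'   (names as [cci_conditions()]). Conditions are comonotone: one latent
#'   uniform per patient with per-condition thresholds, so marginal
#'   prevalences are preserved while profiles cluster into nested severity
#'   patterns (strong multimorbidity clustering).
#' @param cci_onset_hazard Monthly hazard of onset for each condition a
#'   patient does not yet have (makes the comorbidity score time-dependent).
#' @param hcc_monthly_hazard Monthly hazard of first HCC diagnosis.
#' @param other_cancer_monthly_hazard Monthly hazard of a non-HCC cancer
#'   diagnosis flag (exercises the cancer-free lookback exclusion).
#' @param treatment_mix Named probability vector over [treatment_types()].
#' @param phase_increment_yen Data frame with columns `treatment_type`,
#'   `initial`, `continuing`, `terminal`: injected incremental cost
#'   (yen/month, `>= 0`) added to every month of the given true phase.
#' @param post_hcc_death_hazard Monthly death hazard from HCC onset onward.
#' @param background_death_hazard Monthly background death hazard.
#' @param eol_surge_months Number of final months of life (`k`) in which the
#'   baseline expenditure of every decedent is multiplied by
#'   `eol_surge_multiplier`.
#' @param eol_surge_multiplier Multiplier (`>= 0`, `1` = no surge).
#' @param zero_utilization_prob Probability that a month has no claims at
#'   all (baseline expenditure recorded as 0; injected treatment-phase
#'   increments still incur claims).
#' @param recurrence_prob Probability that a case follows a recurrence-like
#'   treatment trajectory (a gap of more than 6 treatment-free months after
#'   initial treatment, with the diagnosis flag persisting), which the
#'   cohort stage excludes.
#' @param age_cost_factor Multiplicative baseline-cost factor per 5-year age
#'   band relative to band 70-74.
#' @param cci_cost_factor Multiplicative baseline-cost factor per
#'   comorbidity score point.
#' @param frailty_sd_log SD (log scale) of a lognormal patient frailty on
#'   the baseline mean (mean-one).
#' @return A validated object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20000L,
                              study_start = "2010-04",
                              study_end = "2018-03",
                              seed = 1L,
                              baseline_mean_yen = 66000,
                              baseline_shape = 0.5,
                              age_dist = default_age_dist(),
                              sex_prob_female = 0.349,
                              cci_prevalence = default_cci_prevalence(),
                              cci_onset_hazard = 2e-4,
                              hcc_monthly_hazard = 3e-4,
                              other_cancer_monthly_hazard = 2e-4,
                              treatment_mix = default_treatment_mix(),
                              phase_increment_yen = default_phase_increments(),
                              post_hcc_death_hazard = 0.03,
                              background_death_hazard = 0.003,
                              eol_surge_months = 6L,
                              eol_surge_multiplier = 3,
                              zero_utilization_prob = 0.05,
                              recurrence_prob = 0,
                              age_cost_factor = 1.05,
                              cci_cost_factor = 1.08,
                              frailty_sd_log = 0.3) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         study_start = ym(study_start), study_end = ym(study_end),
         seed = as.integer(seed),
         baseline_mean_yen = baseline_mean_yen,
         baseline_shape = baseline_shape,
         age_dist = age_dist,
         sex_prob_female = sex_prob_female,
         cci_prevalence = cci_prevalence,
         cci_onset_hazard = cci_onset_hazard,
         hcc_monthly_hazard = hcc_monthly_hazard,
         other_cancer_monthly_hazard = other_cancer_monthly_hazard,
         treatment_mix = treatment_mix,
         phase_increment_yen = data.table::as.data.table(phase_increment_yen),
         post_hcc_death_hazard = post_hcc_death_hazard,
         background_death_hazard = background_death_hazard,
         eol_surge_months = as.integer(eol_surge_months),
         eol_surge_multiplier = eol_surge_multiplier,
         zero_utilization_prob = zero_utilization_prob,
         recurrence_prob = recurrence_prob,
         age_cost_factor = age_cost_factor,
         cci_cost_factor = cci_cost_factor,
         frailty_sd_log = frailty_sd_log),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation config: field '", field, "' ", why, call. = FALSE)
  }
  prob_fields <- c("sex_prob_female", "cci_onset_hazard", "hcc_monthly_hazard",
                   "other_cancer_monthly_hazard", "post_hcc_death_hazard",
                   "background_death_hazard", "zero_utilization_prob",
                   "recurrence_prob")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(f, "must be a probability in [0, 1]")
    }
  }
  if (cfg$n_patients < 1L) fail("n_patients", "must be >= 1")
  if (!is.finite(cfg$seed)) fail("seed", "must be a finite integer")
  if (cfg$study_start >= cfg$study_end) {
    fail("study_start", "must precede study_end")
  }
  if (!is.numeric(cfg$baseline_mean_yen) || cfg$baseline_mean_yen <= 0) {
    fail("baseline_mean_yen", "must be positive")
  }
  if (!is.numeric(cfg$baseline_shape) || cfg$baseline_shape <= 0) {
    fail("baseline_shape", "must be positive")
  }
  if (any(cfg$age_dist < 0) || abs(sum(cfg$age_dist) - 1) > 1e-6) {
    fail("age_dist", "must be non-negative and sum to 1")
  }
  p <- cfg$cci_prevalence
  if (length(p) != 15L || !setequal(names(p), cci_conditions()) ||
      any(p < 0 | p > 1)) {
    fail("cci_prevalence", "must be 15 named probabilities in [0, 1]")
  }
  mix <- cfg$treatment_mix
  if (!setequal(names(mix), treatment_types()) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-6) {
    fail("treatment_mix", "must cover the 16 treatment types and sum to 1")
  }
  inc <- cfg$phase_increment_yen
  need <- c("treatment_type", "initial", "continuing", "terminal")
  if (!all(need %in% names(inc)) ||
      !all(treatment_types() %in% inc$treatment_type)) {
    fail("phase_increment_yen",
         "must have columns treatment_type/initial/continuing/terminal covering all 16 types")
  }
  if (any(as.matrix(inc[, c("initial", "continuing", "terminal")]) < 0)) {
    fail("phase_increment_yen", "increments must be >= 0")
  }
  if (cfg$eol_surge_months < 1L) fail("eol_surge_months", "must be >= 1")
  if (!is.numeric(cfg$eol_surge_multiplier) || cfg$eol_surge_multiplier < 0) {
    fail("eol_surge_multiplier", "must be >= 0")
  }
  if (cfg$age_cost_factor <= 0) fail("age_cost_factor", "must be positive")
  if (cfg$cci_cost_factor <= 0) fail("cci_cost_factor", "must be positive")
  if (cfg$frailty_sd_log < 0) fail("frailty_sd_log", "must be >= 0")
  invisible(cfg)
}

#' @rdname simulation_config
#' @export
default_age_dist <- function() {
  bands <- age_band(seq(20L, 95L, by = 5L))
  lo <- seq(20, 95, by = 5)
  hi <- c(seq(25, 95, by = 5), 100)
  p <- stats::pnorm(hi, 72, 11) - stats::pnorm(lo, 72, 11)
  stats::setNames(p / sum(p), bands)
}

#' @rdname simulation_config
#' @export
default_cci_prevalence <- function() {
  c(mi = 0.070, chf = 0.314, pvd = 0.200, cvd = 0.267, dementia = 0.081,
    copd = 0.257, rheum = 0.056, ulcer = 0.474, mild_liver = 0.879,
    diabetes = 0.372, diabetes_comp = 0.231, paraplegia = 0.024,
    renal = 0.129, severe_liver = 0.306, aids = 0.001)[cci_conditions()]
}

#' @rdname simulation_config
#' @export
default_phase_increments <- function(ppp_yen_per_usd = 102.5) {
  ref <- reference_net_estimates()
  ref <- ref[treatment_type != "Total"]
  wide <- data.table::dcast(ref, treatment_type ~ phase,
                            value.var = c("fe_usd_pppm", "matched_usd_pppm"))
  out <- data.table::data.table(
    treatment_type = wide$treatment_type,
    initial = pmax(wide$fe_usd_pppm_initial, 0) * ppp_yen_per_usd,
    continuing = pmax(wide$fe_usd_pppm_continuing, 0) * ppp_yen_per_usd,
    terminal = pmax(wide$matched_usd_pppm_terminal, 0) * ppp_yen_per_usd
  )
  out[match(treatment_types(), treatment_type)]
}

#' Uniform phase increments across all treatment types
#'
#' Convenience for simulation studies where a single known truth per phase
#' is wanted (e.g. parameter-recovery checks): every treatment type gets the
#' same injected initial/continuing/terminal increment.
#'
#' @param initial,continuing,terminal Increments in yen/month (`>= 0`).
#' @return A data frame suitable for `phase_increment_yen`.
#' @export
uniform_phase_increments <- function(initial, continuing, terminal) {
  data.table::data.table(
    treatment_type = treatment_types(),
    initial = initial, continuing = continuing, terminal = terminal
  )
}
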