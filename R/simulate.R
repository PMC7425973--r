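#' Generate a synthetic claims population
#'
#' Draws a seeded synthetic cohort with the statistical structure the
#' downstream analyses assume: a gamma monthly baseline expenditure whose
#' patient mean scales with age band, weighted comorbidity score and a
#' lognormal frailty (normalized so the population mean equals
#' `baseline_mean_yen`); comonotone Charlson condition flags with optional
#' monthly onset; HCC onset, competing background/post-HCC death; injected
#' phase-specific incremental costs for cases; an end-of-life baseline
#' surge for all decedents; and zero-utilization months.
#'
#' Monthly expenditure is
#' `gamma baseline * surge * utilized + phase increment`, where
#' `surge = eol_surge_multiplier` in the last `eol_surge_months` months of
#' life of any decedent and 1 otherwise, `utilized` is a Bernoulli
#' (`1 - zero_utilization_prob`) indicator, and the increment is the
#' configured yen/month amount for the month's true phase and the case's
#' treatment type (0 for non-cases and pre months).
#'
#' @param config A [simulation_config()].
#' @return A list with `claims` (one row per patient-month: `patient_id`,
#'   `month`, `expenditure_yen`, `dx_hcc`, `dx_other_cancer`, 15 `cci_*`
#'   and 7 `tx_*` flags), `demographics` (`patient_id`, `sex`,
#'   `birth_month`, `death_month`), and `truth` (one row per patient:
#'   case status, true index/death months, treatment type, injected
#'   increments, recurrence-trajectory flag). Months are integer indices
#'   (see [ym()]).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  start <- cfg$study_start
  end <- cfg$study_end
  T_len <- end - start + 1L

  ## --- demographics ------------------------------------------------------
  sex <- ifelse(stats::runif(n) < cfg$sex_prob_female, "F", "M")
  bands <- names(cfg$age_dist)
  band_idx <- sample.int(length(bands), n, replace = TRUE, prob = cfg$age_dist)
  age_lo <- 20L + 5L * (band_idx - 1L)
  age_start <- age_lo + sample.int(5L, n, replace = TRUE) - 1L
  birth_month <- start - age_start * 12L - (sample.int(12L, n, replace = TRUE) - 1L)

  ## --- comorbidity profiles (comonotone baseline + onset) ----------------
  u_sev <- stats::runif(n)
  prev <- cfg$cci_prevalence[cci_conditions()]
  base_flags <- outer(u_sev, prev, `<`)   # n x 15
  colnames(base_flags) <- cci_conditions()
  onset_month <- matrix(NA_integer_, n, 15L,
                        dimnames = list(NULL, cci_conditions()))
  if (cfg$cci_onset_hazard > 0) {
    for (j in seq_len(15L)) {
      o <- start + 1L + stats::rgeom(n, cfg$cci_onset_hazard)
      o[base_flags[, j]] <- NA_integer_  # already present at baseline
      o[o > end] <- NA_integer_
      onset_month[, j] <- o
    }
  }

  ## --- disease onset and death -------------------------------------------
  hcc_onset <- if (cfg$hcc_monthly_hazard > 0) {
    start + stats::rgeom(n, cfg$hcc_monthly_hazard)
  } else rep(NA_integer_, n)
  hcc_onset[!is.na(hcc_onset) & hcc_onset > end] <- NA_integer_

  bg_death <- if (cfg$background_death_hazard > 0) {
    start + stats::rgeom(n, cfg$background_death_hazard)
  } else rep(NA_integer_, n)
  # HCC onset only counts if it happens while alive
  alive_until <- ifelse(is.na(bg_death), Inf, bg_death)
  hcc_onset[!is.na(hcc_onset) & hcc_onset > alive_until] <- NA_integer_
  is_case <- !is.na(hcc_onset)

  post_death <- rep(NA_real_, n)
  if (cfg$post_hcc_death_hazard > 0 && any(is_case)) {
    post_death[is_case] <- hcc_onset[is_case] +
      stats::rgeom(sum(is_case), cfg$post_hcc_death_hazard)
  }
  death <- pmin(ifelse(is.na(bg_death), Inf, bg_death),
                ifelse(is.na(post_death), Inf, post_death))
  death[death > end] <- NA_real_
  death <- as.integer(death)

  ## --- other-cancer flags, treatment assignment ---------------------------
  oc_onset <- if (cfg$other_cancer_monthly_hazard > 0) {
    start + stats::rgeom(n, cfg$other_cancer_monthly_hazard)
  } else rep(NA_integer_, n)
  oc_onset[!is.na(oc_onset) & oc_onset > end] <- NA_integer_

  tt <- rep(NA_character_, n)
  if (any(is_case)) {
    tt[is_case] <- sample(names(cfg$treatment_mix), sum(is_case),
                          replace = TRUE, prob = cfg$treatment_mix)
  }
  recurrent <- rep(FALSE, n)
  if (cfg$recurrence_prob > 0 && any(is_case)) {
    recurrent[is_case] <- stats::runif(sum(is_case)) < cfg$recurrence_prob
  }

  ## --- baseline patient means (normalized) --------------------------------
  w <- cci_weights()
  base_score <- as.numeric(base_flags %*% w)
  age_f <- cfg$age_cost_factor^(band_idx - 1L - 10L)  # band 70-74 = reference
  cci_f <- cfg$cci_cost_factor^base_score
  frailty <- if (cfg$frailty_sd_log > 0) {
    stats::rlnorm(n, -cfg$frailty_sd_log^2 / 2, cfg$frailty_sd_log)
  } else rep(1, n)
  # normalize by the exact expectations under the configured distributions
  e_age <- sum(cfg$age_dist * cfg$age_cost_factor^(seq_along(bands) - 1L - 10L))
  e_cci <- expected_cci_cost_factor(prev, w, cfg$cci_cost_factor)
  mu <- cfg$baseline_mean_yen * age_f * cci_f * frailty / (e_age * e_cci)

  ## --- panel --------------------------------------------------------------
  last <- pmin(ifelse(is.na(death), end, death), end)
  n_months <- last - start + 1L
  pid <- rep.int(seq_len(n), n_months)
  month <- start + sequence(n_months) - 1L

  panel <- data.table::data.table(patient_id = pid, month = month)
  panel[, `:=`(
    onset = hcc_onset[pid],
    death_m = death[pid]
  )]
  rel <- panel$month - panel$onset
  doff <- panel$death_m - panel$onset
  phase <- phase_for_offset(ifelse(is.na(rel), -999L, rel),
                            ifelse(is.na(doff), NA_integer_, doff))
  phase[is.na(rel)] <- NA_character_

  inc_map <- cfg$phase_increment_yen
  inc_wide <- as.matrix(inc_map[match(treatment_types(), inc_map$treatment_type),
                                c("initial", "continuing", "terminal")])
  rownames(inc_wide) <- treatment_types()
  tt_row <- match(tt[pid], treatment_types())
  ph_col <- match(phase, c("initial", "continuing", "terminal"))
  increment <- ifelse(is.na(tt_row) | is.na(ph_col), 0,
                      inc_wide[cbind(tt_row, ph_col)])

  surge <- rep(1, nrow(panel))
  dying <- !is.na(panel$death_m)
  in_eol <- dying & panel$month >= panel$death_m - (cfg$eol_surge_months - 1L)
  surge[in_eol] <- cfg$eol_surge_multiplier

  utilized <- stats::runif(nrow(panel)) >= cfg$zero_utilization_prob
  baseline <- stats::rgamma(nrow(panel), shape = cfg$baseline_shape,
                            rate = cfg$baseline_shape / mu[pid])
  panel[, expenditure_yen := baseline * surge * utilized + increment]

  ## diagnosis flags (persistent from onset)
  panel[, dx_hcc := as.integer(!is.na(onset) & month >= onset)]
  panel[, dx_other_cancer := {
    oc <- oc_onset[pid]
    as.integer(!is.na(oc) & month >= oc)
  }]

  ## condition flags: baseline profile plus later onsets
  for (j in seq_along(cci_conditions())) {
    cj <- cci_conditions()[j]
    bf <- base_flags[pid, j]
    om <- onset_month[pid, j]
    panel[, (paste0("cci_", cj)) := as.integer(bf | (!is.na(om) & month >= om))]
  }

  ## treatment-modality flags: delivery at the index month and the month
  ## after, then maintenance every 3 months; recurrence-trajectory cases
  ## instead stop after the index+1 month and resume a year later, creating
  ## the >= 7-month treatment-free gap that the recurrence rule detects.
  delivered <- !is.na(rel) & rel >= 0L &
    (rel <= 1L | (!recurrent[pid] & rel %% 3L == 0L) |
       (recurrent[pid] & rel >= 12L & rel %% 3L == 0L))
  type_mods <- treatment_type_modalities()
  tt_idx <- match(tt[pid], treatment_types())
  for (md in tx_modalities()) {
    md_by_type <- vapply(type_mods[treatment_types()],
                         function(x) md %in% x, logical(1))
    has_md <- !is.na(tt_idx) & md_by_type[ifelse(is.na(tt_idx), 1L, tt_idx)]
    panel[, (paste0("tx_", md)) := as.integer(delivered & has_md)]
  }
  panel[, c("onset", "death_m") := NULL]

  demographics <- data.table::data.table(
    patient_id = seq_len(n), sex = sex, birth_month = birth_month,
    death_month = death)
  truth <- data.table::data.table(
    patient_id = seq_len(n),
    is_hcc_case = is_case,
    hcc_index_month = hcc_onset,
    death_month = death,
    treatment_type = tt,
    inc_initial_yen = ifelse(is_case, inc_wide[tt_row0 <- match(tt, treatment_types()), 1L], NA_real_),
    inc_continuing_yen = ifelse(is_case, inc_wide[tt_row0, 2L], NA_real_),
    inc_terminal_yen = ifelse(is_case, inc_wide[tt_row0, 3L], NA_real_),
    is_recurrent = recurrent
  )
  list(claims = panel[], demographics = demographics, truth = truth)
}

# E[c^score] where the 15 comonotone flags are driven by one uniform:
# score(u) is a step function with jumps at the sorted prevalences.
expected_cci_cost_factor <- function(prev, weights, cost_factor) {
  ord <- order(prev, decreasing = TRUE)
  p <- prev[ord]
  w <- weights[ord]
  # u < p[k] for the k conditions with largest prevalence > u; walking the
  # breakpoints from u = 0 (all conditions) to u = 1 (none)
  cuts <- c(0, sort(unique(p)), 1)
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    if (hi <= lo) next
    mid <- (lo + hi) / 2
    score <- sum(w[p > mid])
    total <- total + (hi - lo) * cost_factor^score
  }
  total
}

# representative modality set delivered for each treatment-type label;
# chosen so that assign_treatment_type() round-trips to the same label.
treatment_type_modalities <- function() {
  list(
    "Surgical resection only" = "resection",
    "Surgical resection + LRT" = c("resection", "lrt"),
    "Surgical resection + TACE/TAE" = c("resection", "tace"),
    "Surgical resection + others" = c("resection", "radiotherapy"),
    "LRT only" = "lrt",
    "LRT+TACE/TAE" = c("lrt", "tace"),
    "LRT + chemotherapy" = c("lrt", "chemo"),
    "LRT + others" = c("lrt", "radiotherapy"),
    "TACE only" = "tace",
    "TACE + chemotherapy" = c("tace", "chemo"),
    "TACE + chemotherapy + sorafenib" = c("tace", "chemo", "sorafenib"),
    "TAE only" = "tae",
    "TAE + chemotherapy" = c("tae", "chemo"),
    "Sorafenib only" = "sorafenib",
    "Sorafenib + chemotherapy" = c("sorafenib", "chemo"),
    "Others" = "radiotherapy"
  )
}
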