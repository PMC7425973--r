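#' Read and write claims-panel CSV files
#'
#' The on-disk interchange format: one row per patient-month with columns
#' `patient_id`, `month` (`"YYYY-MM"`), `expenditure_yen`, `dx_hcc`,
#' `dx_other_cancer`, fifteen `cci_*` and seven `tx_*` 0/1 flags.
#' Demographics files carry `patient_id`, `sex`, `birth_month`,
#' `death_month` (empty when alive). In memory months are integer indices.
#'
#' @param claims,demographics In-memory tables (integer months).
#' @param path CSV path.
#' @name claims_io
NULL

#' @rdname claims_io
#' @export
write_claims <- function(claims, path) {
  out <- data.table::as.data.table(claims)
  out <- data.table::copy(out)[, month := ym_format(month)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname claims_io
#' @export
read_claims <- function(path) {
  cl <- data.table::fread(path, colClasses = list(character = "month"))
  cl[, month := ym(month)]
  cl[]
}

#' @rdname claims_io
#' @export
write_demographics <- function(demographics, path) {
  out <- data.table::copy(data.table::as.data.table(demographics))
  out[, birth_month := ym_format(birth_month)]
  out[, death_month := ifelse(is.na(death_month), "", ym_format(death_month))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname claims_io
#' @export
read_demographics <- function(path) {
  dem <- data.table::fread(path, colClasses = list(
    character = c("birth_month", "death_month")))
  dem[, birth_month := ym(birth_month)]
  dem[, death_month := {
    out <- rep(NA_integer_, .N)
    alive <- is.na(death_month) | death_month == ""
    out[!alive] <- ym(death_month[!alive])
    out
  }]
  dem[]
}

#' Validate a claims panel
#'
#' Schema and integrity checks: required columns, month format, 0/1 flag
#' domains, non-negative expenditures, and strictly increasing unique
#' months within patient. Returns a table of problems, empty on success.
#'
#' @param x A claims table or a CSV path.
#' @return A `data.table` with columns `check`, `detail` (one row per
#'   problem found).
#' @export
validate_claims <- function(x) {
  cl <- if (is.character(x)) read_claims(x) else data.table::as.data.table(x)
  errs <- list()
  add <- function(check, detail) {
    errs[[length(errs) + 1L]] <<- data.table::data.table(
      check = check, detail = detail)
  }
  need <- c("patient_id", "month", "expenditure_yen", "dx_hcc",
            "dx_other_cancer", cci_columns(), tx_columns())
  missing <- setdiff(need, names(cl))
  if (length(missing)) {
    add("schema", paste("missing column(s):", paste(missing, collapse = ", ")))
    return(data.table::rbindlist(errs))
  }
  if (is.character(cl$month)) {
    bad <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", cl$month)
    if (any(bad)) {
      add("month_format", paste("malformed month in row(s):",
                                paste(utils::head(which(bad), 5L), collapse = ", ")))
    }
  }
  neg <- which(cl$expenditure_yen < 0)
  for (r in utils::head(neg, 10L)) {
    add("negative_expenditure", paste0("row ", r, ": patient ",
                                       cl$patient_id[r]))
  }
  for (fc in c("dx_hcc", "dx_other_cancer", cci_columns(), tx_columns())) {
    v <- cl[[fc]]
    if (!all(v %in% c(0L, 1L))) {
      add("flag_domain", paste0("column ", fc, " has values outside {0,1}"))
    }
  }
  if (!is.character(cl$month)) {
    dup <- cl[, .(bad = anyDuplicated(month) > 0L,
                  unsorted = is.unsorted(month)), by = patient_id]
    for (p in dup[bad == TRUE, patient_id]) {
      add("duplicate_month", paste("patient", p))
    }
    for (p in dup[unsorted == TRUE & bad == FALSE, patient_id]) {
      add("unsorted_months", paste("patient", p))
    }
  }
  if (!length(errs)) {
    return(data.table::data.table(check = character(), detail = character()))
  }
  data.table::rbindlist(errs)
}

#' Run configuration for the full pipeline
#'
#' @param simulation A [simulation_config()], or `NULL` to read claims from
#'   `claims_csv`/`demographics_csv`.
#' @param claims_csv,demographics_csv Input CSV paths (when not simulating).
#' @param out_dir Output directory (created if needed).
#' @param adjustment A [price_adjustment()].
#' @param match_seed Integer seed for the random control draws (mandatory).
#' @param pre_window Fixed-effects pre-disease reference window (months).
#' @param cluster Cluster-robust fixed-effects standard errors?
#' @param round_report Round the comparison table for reporting?
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, claims_csv = NULL,
                       demographics_csv = NULL, out_dir = tempfile("phasecost_"),
                       adjustment = price_adjustment(), match_seed = NULL,
                       pre_window = 12L, cluster = FALSE,
                       round_report = TRUE) {
  if (is.null(simulation) && (is.null(claims_csv) || is.null(demographics_csv))) {
    stop("either a simulation config or claims/demographics CSV paths are required",
         call. = FALSE)
  }
  if (is.null(match_seed)) {
    stop("match_seed is mandatory: every stochastic stage must be seeded",
         call. = FALSE)
  }
  structure(list(simulation = simulation, claims_csv = claims_csv,
                 demographics_csv = demographics_csv, out_dir = out_dir,
                 adjustment = adjustment, match_seed = as.integer(match_seed),
                 pre_window = as.integer(pre_window), cluster = cluster,
                 round_report = round_report),
            class = "run_config")
}

#' Run the full estimation pipeline
#'
#' Orchestrates simulate (or load) -> validate -> cohort/phase
#' classification -> incident and death matching -> matched and
#' fixed-effects estimation -> method comparison, writing each stage's
#' table to `out_dir` together with a run manifest (seeds, configuration,
#' per-stage row counts). Identical configuration and seeds give
#' byte-identical output CSVs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with every stage's tables and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  if (!is.null(config$simulation)) {
    pop <- stage("simulate", generate_population(config$simulation))
    claims <- pop$claims
    demographics <- pop$demographics
  } else {
    pop <- NULL
    claims <- stage("load", read_claims(config$claims_csv))
    demographics <- read_demographics(config$demographics_csv)
  }
  problems <- stage("validate", validate_claims(claims))
  if (nrow(problems)) {
    stop("pipeline stage 'validate' failed: ", nrow(problems),
         " problem(s), first: ", problems$check[1L], " (",
         problems$detail[1L], ")", call. = FALSE)
  }
  register <- stage("cohort", build_case_register(claims, demographics))
  phase_maps <- stage("phases", build_phase_maps(register, claims))
  keys <- stage("stratum_keys", patient_month_keys(claims, demographics))
  inc <- stage("match_incident",
               match_incident(register, claims, demographics,
                              seed = config$match_seed, keys = keys))
  dth <- stage("match_death",
               match_death(register, claims, demographics,
                           seed = config$match_seed + 1L, keys = keys))
  matched_tbl <- data.table::rbindlist(list(
    stage("matched_incident",
          matched_net_estimates(inc$pairs, phase_maps, claims, register,
                                config$adjustment)),
    if (nrow(dth$pairs)) stage("matched_death",
          matched_net_estimates(dth$pairs, phase_maps, claims, register,
                                config$adjustment))
  ), use.names = TRUE)
  matched_cases <- register[patient_id %in% c(inc$pairs$case_id,
                                              dth$pairs$case_id)]
  fe_tbl <- data.table::rbindlist(list(
    stage("fe_incident",
          fixed_effects_estimates(
            register[patient_id %in% inc$pairs$case_id], phase_maps, claims,
            demographics, "incident", config$adjustment,
            pre_window = config$pre_window, cluster = config$cluster)),
    stage("fe_death",
          fixed_effects_estimates(
            register[patient_id %in% dth$pairs$case_id], phase_maps, claims,
            demographics, "death", config$adjustment,
            pre_window = config$pre_window, cluster = config$cluster))
  ), use.names = TRUE)
  comparison <- stage("compare",
                      method_comparison(matched_tbl, fe_tbl,
                                        round_report = config$round_report))

  od <- config$out_dir
  wr <- function(x, f) data.table::fwrite(x, file.path(od, f))
  reg_out <- data.table::copy(register)
  reg_out[, index_month := ifelse(is.na(index_month), "",
                                  ym_format(index_month))]
  reg_out[, death_month := ifelse(is.na(death_month), "",
                                  ym_format(death_month))]
  wr(reg_out, "case_register.csv")
  pm_out <- data.table::copy(phase_maps)[, month := ym_format(month)]
  wr(pm_out, "phase_maps.csv")
  wr(data.table::rbindlist(list(inc$pairs, dth$pairs), use.names = TRUE),
     "pairs.csv")
  unmatched <- data.table::rbindlist(list(
    if (nrow(inc$unmatched)) data.table::copy(inc$unmatched)[, cohort := "incident"],
    if (nrow(dth$unmatched)) data.table::copy(dth$unmatched)[, cohort := "death"]),
    use.names = TRUE)
  if (is.null(unmatched) || !nrow(unmatched)) {
    unmatched <- data.table::data.table(case_id = integer(),
                                        reason = character(),
                                        cohort = character())
  }
  wr(unmatched, "unmatched.csv")
  wr(matched_tbl, "matched_estimates.csv")
  wr(fe_tbl, "fe_estimates.csv")
  wr(comparison, "comparison.csv")

  n_eligible <- sum(register$eligible)
  n_death_eligible <- sum(register$eligible & !is.na(register$death_month))
  manifest <- list(
    seeds = list(
      simulation = if (!is.null(config$simulation)) config$simulation$seed,
      matching = config$match_seed),
    counts = list(
      patients = length(unique(claims$patient_id)),
      patient_months = nrow(claims),
      hcc_flagged = nrow(register),
      eligible_cases = n_eligible,
      excluded_recurrence = sum(register$exclusion_reason == "recurrence"),
      incident_matched = nrow(inc$pairs),
      incident_unmatched = nrow(inc$unmatched),
      death_eligible = n_death_eligible,
      death_matched = nrow(dth$pairs),
      death_unmatched = nrow(dth$unmatched)),
    options = list(pre_window = config$pre_window, cluster = config$cluster,
                   ppp_yen_per_usd = config$adjustment$ppp_yen_per_usd))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(claims = claims, demographics = demographics,
                 truth = if (!is.null(pop)) pop$truth,
                 register = register, phase_maps = phase_maps,
                 incident = inc, death = dth,
                 matched_estimates = matched_tbl, fe_estimates = fe_tbl,
                 comparison = comparison, manifest = manifest))
}
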