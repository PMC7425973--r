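#' @import data.table
NULL

# Phase label for a month at offset `rel` from the index month, given death
# at offset `death_offset` (NA if death unobserved). Encodes the phase
# conventions:
#   * standard: initial = {index-1, index, index+1}; terminal = the 6-month
#     block ending at the death month; continuing = everything between.
#   * death during the index month: initial = {index-1}, terminal = {index}.
#   * death 1 month after index: initial = {index-1, index}, terminal =
#     {index+1} (the death month is always terminal).
#   * death within 7 months of index: initial unchanged, terminal =
#     {index+2 ... death}, no continuing phase.
#   * no observed death: no terminal; continuing runs to the last observed
#     month.
# Months before the initial phase are "pre". Vectorized over `rel`.
phase_for_offset <- function(rel, death_offset = NA_integer_) {
  rel <- as.integer(rel)
  d <- as.integer(death_offset)
  n <- max(length(rel), length(d))
  rel <- rep_len(rel, n)
  d <- rep_len(d, n)
  out <- rep(NA_character_, n)

  out[rel < -1L] <- "pre"
  nodeath <- is.na(d)
  out[nodeath & rel >= -1L & rel <= 1L] <- "initial"
  out[nodeath & rel >= 2L] <- "continuing"

  dd <- !nodeath
  # exception: death during the index month
  i <- dd & d == 0L
  out[i & rel == -1L] <- "initial"
  out[i & rel == 0L] <- "terminal"
  # exception: death one month after the index month
  i <- dd & d == 1L
  out[i & rel >= -1L & rel <= 0L] <- "initial"
  out[i & rel == 1L] <- "terminal"
  # exception: death within 7 months of the index month
  i <- dd & d >= 2L & d <= 7L
  out[i & rel >= -1L & rel <= 1L] <- "initial"
  out[i & rel >= 2L & rel <= d] <- "terminal"
  # standard pattern
  i <- dd & d >= 8L
  out[i & rel >= -1L & rel <= 1L] <- "initial"
  out[i & rel >= 2L & rel <= d - 6L] <- "continuing"
  out[i & rel >= d - 5L & rel <= d] <- "terminal"

  out
}

#' Assign observed months to phases of care
#'
#' Partitions a case's observed months into `pre`, `initial`, `continuing`
#' and `terminal` phases around the index (first qualifying diagnosis)
#' month. See the package vignette for the full conventions; in brief the
#' initial phase is the 3-month window centred on the index month, the
#' terminal phase is the 6-month window ending at the death month, the
#' continuing phase is the contiguous block in between, and special rules
#' apply when death occurs within 7 months of the index month.
#'
#' @param index_month Index month (integer index or `"YYYY-MM"`).
#' @param death_month Death month, or `NA` if death is not observed.
#' @param last_month Last observed month (ignored when death is observed:
#'   observation then ends at death).
#' @param first_month First observed month; defaults to `index_month - 1`
#'   (no pre months).
#' @return A `data.table` with columns `month` (integer index) and `phase`.
#' @export
classify_phases <- function(index_month, death_month = NA, last_month = NA,
                            first_month = NA) {
  idx <- ym(index_month)
  dth <- if (length(death_month) == 1L && is.na(death_month)) NA_integer_ else ym(death_month)
  if (!is.na(dth) && dth < idx) {
    stop("death month precedes index month", call. = FALSE)
  }
  end <- if (!is.na(dth)) dth else ym(last_month)
  if (is.na(end)) {
    stop("need death_month or last_month to bound the phase map", call. = FALSE)
  }
  beg <- if (length(first_month) == 1L && is.na(first_month)) idx - 1L else ym(first_month)
  months <- seq.int(beg, end)
  data.table::data.table(
    month = months,
    phase = phase_for_offset(months - idx,
                             if (is.na(dth)) NA_integer_ else dth - idx)
  )
}

#' Find the index month of a primary-HCC case
#'
#' The index month is the first month with an HCC diagnosis flag that is
#' preceded by 12 fully observed months containing no cancer diagnosis flag
#' of any kind (the cancer-free lookback), for a patient aged at least 20
#' years at that month. Patients entering observation less than 12 months
#' before their first HCC flag are ineligible.
#'
#' @param timeline One patient's claims rows, sorted by month, with columns
#'   `month`, `dx_hcc`, `dx_other_cancer`.
#' @param birth_month Patient's birth month (integer index or `"YYYY-MM"`).
#' @return Integer index month, or `NA` if the patient never qualifies.
#' @export
find_index_month <- function(timeline, birth_month) {
  tl <- data.table::as.data.table(timeline)
  m <- ym(tl$month)
  if (is.unsorted(m, strictly = TRUE)) {
    stop("timeline months must be sorted and unique", call. = FALSE)
  }
  cancer <- (tl$dx_hcc > 0) | (tl$dx_other_cancer > 0)
  birth <- ym(birth_month)
  for (i in which(tl$dx_hcc > 0)) {
    window <- m >= m[i] - 12L & m < m[i]
    if (sum(window) < 12L) next        # lookback not fully observed
    if (any(cancer[window])) next      # prior cancer in the lookback
    if (age_years(birth, m[i]) < 20L) return(NA_integer_)
    return(m[i])
  }
  NA_integer_
}

#' Detect recurrence-like diagnosis trajectories
#'
#' A case is flagged as a recurrence when an HCC diagnosis month is preceded
#' by at least 7 consecutive months without any anticancer-treatment flag,
#' counting from the last treated month after initial treatment. Flagged
#' patients are excluded from all cohorts.
#'
#' @param timeline One patient's claims rows (columns `month` and the
#'   `tx_*` modality flags), sorted by month.
#' @param index_month The case's index month.
#' @return `TRUE` if a recurrence-pattern diagnosis exists.
#' @export
detect_recurrence <- function(timeline, index_month) {
  tl <- data.table::as.data.table(timeline)
  m <- ym(tl$month)
  txc <- intersect(tx_columns(), names(tl))
  treated <- rowSums(as.matrix(tl[, txc, with = FALSE])) > 0
  tx_months <- m[treated]
  dx_months <- m[tl$dx_hcc > 0 & m >= ym(index_month)]
  if (!length(tx_months) || !length(dx_months)) return(FALSE)
  # last treated month strictly before each diagnosis month
  pos <- findInterval(dx_months - 1L, tx_months)
  has_prior <- pos >= 1L
  gap <- dx_months[has_prior] - tx_months[pos[has_prior]] - 1L
  any(gap >= 7L)
}

#' Map a set of treatment modalities to a treatment-type label
#'
#' Deterministic and total over all subsets of the seven modality flags.
#' Precedence: any set containing surgical resection maps to one of the four
#' resection rows; otherwise any set containing locoregional therapy (LRT)
#' maps to one of the four LRT rows; otherwise the exact single- and
#' two/three-modality combinations are matched; everything else is
#' `"Others"`.
#'
#' @param modalities Character vector, a subset of
#'   `c("resection","lrt","tace","tae","sorafenib","chemo","radiotherapy")`.
#' @return One of [treatment_types()], or `NA` for an empty set (untreated
#'   patients are not cases).
#' @export
classify_modalities <- function(modalities) {
  s <- sort(unique(modalities))
  stopifnot(all(s %in% tx_modalities()))
  if (!length(s)) return(NA_character_)
  has <- function(...) setequal(s, c(...))
  emb <- s[s %in% c("tace", "tae")]
  if ("resection" %in% s) {
    rest <- setdiff(s, "resection")
    if (!length(rest)) return("Surgical resection only")
    if (setequal(rest, "lrt")) return("Surgical resection + LRT")
    if (length(rest) && all(rest %in% c("tace", "tae"))) {
      return("Surgical resection + TACE/TAE")
    }
    return("Surgical resection + others")
  }
  if ("lrt" %in% s) {
    rest <- setdiff(s, "lrt")
    if (!length(rest)) return("LRT only")
    if (length(rest) && all(rest %in% c("tace", "tae"))) return("LRT+TACE/TAE")
    if (setequal(rest, "chemo")) return("LRT + chemotherapy")
    return("LRT + others")
  }
  if (has("tace")) return("TACE only")
  if (has("tace", "chemo")) return("TACE + chemotherapy")
  if (has("tace", "chemo", "sorafenib")) return("TACE + chemotherapy + sorafenib")
  if (has("tae")) return("TAE only")
  if (has("tae", "chemo")) return("TAE + chemotherapy")
  if (has("sorafenib")) return("Sorafenib only")
  if (has("sorafenib", "chemo")) return("Sorafenib + chemotherapy")
  "Others"
}

#' Treatment type of a case from its claims timeline
#'
#' Collects the modalities flagged between the month before the index month
#' and death/censoring and maps them with [classify_modalities()].
#'
#' @param timeline One patient's claims rows with `month` and `tx_*` flags.
#' @param index_month Case index month.
#' @param end_month Death month or last observed month.
#' @return Treatment-type label, or `NA` if no modality was observed
#'   (untreated patients are excluded as cases).
#' @export
assign_treatment_type <- function(timeline, index_month, end_month) {
  tl <- data.table::as.data.table(timeline)
  m <- ym(tl$month)
  keep <- m >= ym(index_month) - 1L & m <= ym(end_month)
  mods <- tx_modalities()
  seen <- vapply(mods, function(md) {
    col <- paste0("tx_", md)
    col %in% names(tl) && any(tl[[col]][keep] > 0)
  }, logical(1))
  classify_modalities(mods[seen])
}

#' Case register: eligibility, exclusions and treatment types
#'
#' Screens every patient in a claims panel for primary-HCC case eligibility
#' (index month with a clean 12-month cancer-free lookback, age >= 20,
#' treated, non-recurrent) and records the exclusion reason otherwise.
#'
#' @param claims Claims panel (`data.table`) with one row per patient-month.
#' @param demographics Demographics table with `patient_id`, `sex`,
#'   `birth_month`, `death_month`.
#' @return A `data.table` with one row per patient ever flagged with HCC:
#'   `patient_id`, `index_month`, `death_month`, `treatment_type`,
#'   `eligible`, `exclusion_reason` (`""`, `"lookback_or_entry"`,
#'   `"age_under_20"`, `"recurrence"`, `"untreated"`).
#' @export
build_case_register <- function(claims, demographics) {
  cl <- data.table::as.data.table(claims)
  dem <- data.table::as.data.table(demographics)
  if (!is.numeric(cl$month)) cl <- data.table::copy(cl)[, month := ym(month)]
  flagged <- cl[dx_hcc > 0, .(first_dx = min(month)), by = patient_id]
  if (!nrow(flagged)) {
    return(data.table::data.table(
      patient_id = integer(), index_month = integer(),
      death_month = integer(), treatment_type = character(),
      eligible = logical(), exclusion_reason = character()))
  }
  dem2 <- dem[, .(patient_id, birth_month = ym(birth_month),
                  death_month = ym(death_month))]
  flagged <- merge(flagged, dem2, by = "patient_id", sort = TRUE)
  cl_flagged <- cl[patient_id %in% flagged$patient_id]
  data.table::setkey(cl_flagged, patient_id, month)

  rows <- lapply(seq_len(nrow(flagged)), function(i) {
    pid <- flagged$patient_id[i]
    tl <- cl_flagged[.(pid)]
    idx <- tryCatch(find_index_month(tl, flagged$birth_month[i]),
                    error = function(e) stop(e))
    death <- flagged$death_month[i]
    if (is.na(idx)) {
      first_dx <- flagged$first_dx[i]
      age <- age_years(flagged$birth_month[i], first_dx)
      reason <- if (age < 20L) "age_under_20" else "lookback_or_entry"
      return(data.table::data.table(
        patient_id = pid, index_month = NA_integer_, death_month = death,
        treatment_type = NA_character_, eligible = FALSE,
        exclusion_reason = reason))
    }
    end <- if (!is.na(death)) death else max(tl$month)
    tt <- assign_treatment_type(tl, idx, end)
    if (is.na(tt)) {
      return(data.table::data.table(
        patient_id = pid, index_month = idx, death_month = death,
        treatment_type = NA_character_, eligible = FALSE,
        exclusion_reason = "untreated"))
    }
    if (detect_recurrence(tl, idx)) {
      return(data.table::data.table(
        patient_id = pid, index_month = idx, death_month = death,
        treatment_type = tt, eligible = FALSE,
        exclusion_reason = "recurrence"))
    }
    data.table::data.table(
      patient_id = pid, index_month = idx, death_month = death,
      treatment_type = tt, eligible = TRUE, exclusion_reason = "")
  })
  data.table::rbindlist(rows)
}

#' Phase maps for all eligible cases
#'
#' @param register Output of [build_case_register()].
#' @param claims Claims panel (for each case's first/last observed month).
#' @return A `data.table` `patient_id`, `month`, `phase` covering every
#'   observed month of every eligible case.
#' @export
build_phase_maps <- function(register, claims) {
  reg <- data.table::as.data.table(register)[eligible == TRUE]
  cl <- data.table::as.data.table(claims)
  if (!is.numeric(cl$month)) cl <- data.table::copy(cl)[, month := ym(month)]
  span <- cl[patient_id %in% reg$patient_id,
             .(first_obs = min(month), last_obs = max(month)),
             by = patient_id]
  reg <- merge(reg, span, by = "patient_id", sort = TRUE)
  maps <- lapply(seq_len(nrow(reg)), function(i) {
    pm <- classify_phases(reg$index_month[i], reg$death_month[i],
                          last_month = reg$last_obs[i],
                          first_month = reg$first_obs[i])
    pm[, patient_id := reg$patient_id[i]]
    pm
  })
  out <- data.table::rbindlist(maps)
  data.table::setcolorder(out, c("patient_id", "month", "phase"))
  out[]
}
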