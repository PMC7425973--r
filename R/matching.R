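#' Exact-matching stratum key
#'
#' The matching stratum is the combination of sex, 5-year age band at the
#' anchor month, and the 15 Charlson condition indicators evaluated over the
#' 12-month window ending at the anchor month. Two patients match exactly
#' when their keys are equal.
#'
#' @param sex `"F"` or `"M"`.
#' @param birth_month Birth month (integer index or `"YYYY-MM"`).
#' @param flags Logical/0-1 vector of the 15 condition indicators, in
#'   [cci_conditions()] order (as evaluated at the anchor).
#' @param anchor_month Anchor month.
#' @return A single key string.
#' @export
build_match_key <- function(sex, birth_month, flags, anchor_month) {
  if (is.na(sex) || !sex %in% c("F", "M")) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (is.na(ym(birth_month))) stop("missing birth month", call. = FALSE)
  stopifnot(length(flags) == 15L)
  band <- age_band(age_years(ym(birth_month), ym(anchor_month)))
  paste(sex, band, paste(as.integer(as.logical(flags)), collapse = ""),
        sep = "|")
}

# Per patient-month key table: sex, age band and the 15 window-evaluated
# condition flags, bit-packed into one integer stratum key, plus a
# utilization indicator. Condition flags count as present if seen in any of
# the 12 months ending at the month (requires contiguous panels, which
# validate_claims() checks).
patient_month_keys <- function(claims, demographics) {
  cl <- data.table::as.data.table(claims)
  dem <- data.table::as.data.table(demographics)
  if (!is.numeric(cl$month)) cl <- data.table::copy(cl)[, month := ym(month)]
  cols <- cci_columns()
  kt <- cl[, c("patient_id", "month", "expenditure_yen", cols), with = FALSE]
  data.table::setorder(kt, patient_id, month)
  # rolling 12-month any-flag via global cumsums clipped at patient starts
  first_row <- kt[, .I[1L], by = patient_id]$V1
  row_first <- rep.int(first_row, diff(c(first_row, nrow(kt) + 1L)))
  r <- seq_len(nrow(kt))
  prev <- pmax(r - 12L, row_first - 1L)
  flag_key <- numeric(nrow(kt))
  for (j in seq_along(cols)) {
    cs <- cumsum(kt[[cols[j]]] > 0)
    seen <- cs - ifelse(prev == 0L, 0L, cs[prev])
    flag_key <- flag_key + (seen > 0L) * 2^(j - 1)
  }
  dem2 <- dem[, .(patient_id, sex, birth_month = ym(birth_month))]
  kt <- merge(kt, dem2, by = "patient_id", sort = FALSE)
  band_raw <- (age_years(kt$birth_month, kt$month) - 20L) %/% 5L
  band <- pmin(band_raw, 15L)
  kt[, key := ifelse(band_raw < 0L, NA_real_,  # under 20: never a stratum
                     flag_key + 2^15 * band + 2^19 * (sex == "F"))]
  kt[, utilized := expenditure_yen > 0]
  kt[, c("patient_id", "month", "key", "utilized"), with = FALSE]
}

match_pool_ids <- function(claims) {
  cl <- data.table::as.data.table(claims)
  ever_hcc <- unique(cl$patient_id[cl$dx_hcc > 0])
  setdiff(unique(cl$patient_id), ever_hcc)
}

run_match <- function(case_tab, cand_tab, seed, offsets) {
  set.seed(seed)
  cand_tab <- cand_tab[!is.na(key)]
  data.table::setkey(cand_tab, key, month)
  max_id <- if (nrow(cand_tab)) max(cand_tab$patient_id) else 0L
  used <- logical(max_id)
  n_cases <- nrow(case_tab)
  case_ids <- rep(NA_integer_, n_cases)
  ctrl_ids <- rep(NA_integer_, n_cases)
  offs <- rep(NA_integer_, n_cases)
  for (i in seq_len(n_cases)) {
    ck <- case_tab$key[i]
    if (is.na(ck)) next
    anchor <- case_tab$anchor_month[i]
    for (off in offsets) {
      cand <- cand_tab[.(ck, anchor + off), nomatch = NULL]$patient_id
      cand <- cand[!used[cand]]
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1L)]
        used[pick] <- TRUE
        case_ids[i] <- case_tab$patient_id[i]
        ctrl_ids[i] <- pick
        offs[i] <- off
        break
      }
    }
  }
  hit <- !is.na(ctrl_ids)
  list(pairs = data.table::data.table(case_id = case_ids[hit],
                                      control_id = ctrl_ids[hit],
                                      anchor_offset = offs[hit]),
       unmatched = if (all(hit)) {
         data.table::data.table(case_id = integer(), reason = character())
       } else {
         data.table::data.table(case_id = case_tab$patient_id[!hit],
                                reason = "no_eligible_control")
       })
}

#' Incident-cohort matching
#'
#' Matches each eligible case to one never-HCC control with an identical
#' stratum key who had healthcare utilization in the case's index month;
#' when no such control exists the window expands month by month to the
#' nearest utilization month within a year of the index (equidistant ties
#' resolved to the earlier month). Controls are drawn uniformly at random
#' within the chosen month and removed from the pool (matching without
#' replacement); cases are processed in ascending `patient_id` order.
#'
#' @param register Case register ([build_case_register()]); only rows with
#'   `eligible == TRUE` are matched.
#' @param claims,demographics Claims panel and demographics table covering
#'   cases and the control pool.
#' @param seed Integer seed for the random control draws.
#' @param max_offset Maximum month-window expansion (12 = up to one year).
#' @param keys Precomputed stratum-key table (internal
#'   `patient_month_keys()` output), to avoid recomputation when matching
#'   both cohorts on the same panel.
#' @return A list: `pairs` (`cohort`, `case_id`, `control_id`,
#'   `anchor_offset`) and `unmatched` (`case_id`, `reason`).
#' @export
match_incident <- function(register, claims, demographics, seed,
                           max_offset = 12L, keys = NULL) {
  reg <- data.table::as.data.table(register)[eligible == TRUE]
  data.table::setorder(reg, patient_id)
  kt <- if (is.null(keys)) patient_month_keys(claims, demographics) else keys
  pool <- match_pool_ids(claims)
  cand_tab <- kt[patient_id %in% pool & utilized == TRUE]
  case_tab <- merge(
    reg[, .(patient_id, anchor_month = index_month)],
    kt[, .(patient_id, month, key)],
    by.x = c("patient_id", "anchor_month"), by.y = c("patient_id", "month"),
    sort = TRUE)
  if (!nrow(cand_tab)) warning("empty control pool; no pairs formed")
  offsets <- c(0L, as.vector(rbind(-seq_len(max_offset), seq_len(max_offset))))
  res <- run_match(case_tab, cand_tab, seed, offsets)
  if (nrow(res$pairs)) res$pairs[, cohort := "incident"]
  res
}

#' Death-cohort matching
#'
#' Matches each eligible case with an observed death to one never-HCC
#' control who died in the same calendar month and has an identical stratum
#' key at that month. No window expansion; without replacement; seeded.
#'
#' @inheritParams match_incident
#' @return As [match_incident()], with `cohort = "death"` and
#'   `anchor_offset` always 0.
#' @export
match_death <- function(register, claims, demographics, seed, keys = NULL) {
  reg <- data.table::as.data.table(register)[eligible == TRUE & !is.na(death_month)]
  data.table::setorder(reg, patient_id)
  dem <- data.table::as.data.table(demographics)
  kt <- if (is.null(keys)) patient_month_keys(claims, demographics) else keys
  pool <- match_pool_ids(claims)
  dead <- dem[patient_id %in% pool & !is.na(death_month),
              .(patient_id, death_m = ym(death_month))]
  cand_tab <- merge(dead, kt, by.x = c("patient_id", "death_m"),
                    by.y = c("patient_id", "month"), sort = FALSE)
  data.table::setnames(cand_tab, "death_m", "month")
  case_tab <- merge(
    reg[, .(patient_id, anchor_month = ym(death_month))],
    kt[, .(patient_id, month, key)],
    by.x = c("patient_id", "anchor_month"), by.y = c("patient_id", "month"),
    sort = TRUE)
  if (!nrow(cand_tab)) warning("empty decedent control pool; no pairs formed")
  res <- run_match(case_tab, cand_tab, seed, offsets = 0L)
  if (nrow(res$pairs)) res$pairs[, cohort := "death"]
  res
}
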