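#' Price-revision adjustment and currency conversion parameters
#'
#' Japanese reimbursement prices are revised every two fiscal years (fiscal
#' years run April to March). To place all expenditures on a common 2018
#' price base, each service month's amount is multiplied by the revision
#' rate of its fiscal period. The defaults are the cumulative revision rates
#' relative to 2018 for fiscal 2010-2017, and the 2017 purchasing power
#' parity rate of 102.5 yen per US dollar.
#'
#' @param rates Named numeric vector of multipliers; names are the first
#'   fiscal year of each two-year period (`"2010"` covers fiscal 2010-2011,
#'   i.e. 2010-04 through 2012-03, and so on). Fiscal years at or beyond
#'   the base year get multiplier 1.
#' @param ppp_yen_per_usd Yen per US dollar.
#' @param base_fiscal_year Fiscal years `>= base_fiscal_year` are taken as
#'   already on the price base (multiplier 1).
#' @return An object of class `price_adjustment`.
#' @examples
#' adj <- price_adjustment()
#' adjust_expenditure(10000, ym("2010-06"), adj) # 10190
#' @export
price_adjustment <- function(rates = c("2010" = 1.019, "2012" = 1.004,
                                       "2014" = 1.1001, "2016" = 0.9916),
                             ppp_yen_per_usd = 102.5,
                             base_fiscal_year = 2018L) {
  stopifnot(is.numeric(rates), !is.null(names(rates)), all(rates > 0),
            is.numeric(ppp_yen_per_usd), ppp_yen_per_usd > 0)
  structure(
    list(rates = rates,
         ppp_yen_per_usd = as.numeric(ppp_yen_per_usd),
         base_fiscal_year = as.integer(base_fiscal_year)),
    class = "price_adjustment"
  )
}

# fiscal year (April-March) of an integer month index
fiscal_year <- function(month) {
  (as.integer(month) - 3L) %/% 12L
}

#' Deflate expenditures to the price base
#'
#' Multiplies each amount by the revision rate of its service month's fiscal
#' period. Months in fiscal years at or after the base year are left
#' unchanged; months before the earliest configured period are a
#' configuration error.
#'
#' @param amount_yen Numeric vector of amounts in yen.
#' @param month Integer month index (see [ym()]), recycled against
#'   `amount_yen`.
#' @param adjustment A [price_adjustment()] object.
#' @return Adjusted amounts in yen.
#' @export
adjust_expenditure <- function(amount_yen, month, adjustment = price_adjustment()) {
  stopifnot(inherits(adjustment, "price_adjustment"))
  fy <- fiscal_year(month)
  period_start <- as.integer(names(adjustment$rates))
  period_start <- sort(period_start)
  # each configured period covers two fiscal years
  mult <- rep(NA_real_, length(fy))
  mult[fy >= adjustment$base_fiscal_year] <- 1
  for (p in period_start) {
    rate <- adjustment$rates[[as.character(p)]]
    mult[fy == p | fy == p + 1L] <- rate
  }
  if (anyNA(mult)) {
    bad <- unique(fy[is.na(mult)])
    stop("service month(s) in fiscal year(s) not covered by the price ",
         "adjustment: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  amount_yen * mult
}

#' Convert yen to US dollars at the configured PPP rate
#'
#' @param amount_yen Numeric vector of amounts in yen.
#' @param adjustment A [price_adjustment()] object.
#' @return Amounts in US dollars.
#' @examples
#' yen_to_usd(102.5) # 1
#' @export
yen_to_usd <- function(amount_yen, adjustment = price_adjustment()) {
  stopifnot(inherits(adjustment, "price_adjustment"))
  amount_yen / adjustment$ppp_yen_per_usd
}

#' Between-method difference statistics
#'
#' The two estimation methods (matched comparison, fixed-effects analysis)
#' are compared by the proportional difference
#' `1 - matched / fixed_effects` (dimensionless; reported as a percentage)
#' and the absolute difference `fixed_effects - matched` (USD per patient
#' per month).
#'
#' @param matched_estimate,fe_estimate Numeric vectors of net expenditure
#'   estimates (same units).
#' @return [proportional_difference()] returns the dimensionless proportion
#'   (not percent); [absolute_difference()] the difference in the input
#'   units.
#' @examples
#' round(100 * proportional_difference(3353, 3684), 1) # 9.0
#' absolute_difference(208, 3026)                      # 2818
#' @export
proportional_difference <- function(matched_estimate, fe_estimate) {
  if (any(fe_estimate == 0, na.rm = TRUE)) {
    stop("proportional difference undefined where the fixed-effects ",
         "estimate is zero", call. = FALSE)
  }
  1 - matched_estimate / fe_estimate
}

#' @rdname proportional_difference
#' @export
absolute_difference <- function(matched_estimate, fe_estimate) {
  fe_estimate - matched_estimate
}

#' Method-comparison table
#'
#' Joins matched and fixed-effects net-estimate tables on treatment type and
#' phase and computes both difference statistics, mirroring the layout of a
#' published comparison table: one row per treatment type, proportional
#' differences in percent (one decimal) and absolute differences in whole
#' USD when `round_report = TRUE`.
#'
#' @param matched,fixed_effects Data frames with columns `treatment_type`,
#'   `phase`, `net_usd_pppm` (e.g. from [matched_net_estimates()] and
#'   [fixed_effects_estimates()]).
#' @param round_report Round for reporting (percentages to one decimal,
#'   dollars to whole units)?
#' @return A `data.table` with columns `treatment_type`, `phase`,
#'   `matched_usd_pppm`, `fe_usd_pppm`, `proportional_difference_pct`,
#'   `absolute_difference_usd`.
#' @export
method_comparison <- function(matched, fixed_effects, round_report = FALSE) {
  m <- data.table::as.data.table(matched)[, c("treatment_type", "phase", "net_usd_pppm")]
  f <- data.table::as.data.table(fixed_effects)[, c("treatment_type", "phase", "net_usd_pppm")]
  data.table::setnames(m, "net_usd_pppm", "matched_usd_pppm")
  data.table::setnames(f, "net_usd_pppm", "fe_usd_pppm")
  cmp <- merge(m, f, by = c("treatment_type", "phase"), all = FALSE)
  cmp[, `:=`(
    proportional_difference_pct =
      ifelse(fe_usd_pppm == 0, NA_real_,
             100 * (1 - matched_usd_pppm / fe_usd_pppm)),
    absolute_difference_usd = fe_usd_pppm - matched_usd_pppm
  )]
  if (any(cmp$fe_usd_pppm == 0)) {
    warning("proportional difference undefined (fixed-effects estimate 0) ",
            "for some rows; set to NA", call. = FALSE)
  }
  if (round_report) {
    cmp[, `:=`(
      proportional_difference_pct = round(proportional_difference_pct, 1),
      absolute_difference_usd = round(absolute_difference_usd)
    )]
  }
  cmp[]
}
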