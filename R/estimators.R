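#' Per-patient-per-month expenditure over a month set
#'
#' Arithmetic mean of (price-adjusted) monthly expenditures over the given
#' months; months with no utilization count as zero, exactly as recorded.
#'
#' @param timeline One patient's claims rows (`month`, `expenditure_yen`).
#' @param months Integer month indices (or `"YYYY-MM"`) to average over;
#'   only months present in the timeline contribute.
#' @param adjustment Optional [price_adjustment()]; when supplied, amounts
#'   are deflated to the price base (and stay in yen).
#' @return Mean expenditure per month.
#' @export
pppm <- function(timeline, months, adjustment = NULL) {
  tl <- data.table::as.data.table(timeline)
  m <- ym(tl$month)
  months <- ym(months)
  if (!length(months)) stop("empty month set: PPPM undefined", call. = FALSE)
  keep <- m %in% months
  if (!any(keep)) stop("no observed months in the requested set", call. = FALSE)
  x <- tl$expenditure_yen[keep]
  if (!is.null(adjustment)) x <- adjust_expenditure(x, m[keep], adjustment)
  mean(x)
}

# adjusted USD expenditure column for a claims table
adjusted_usd <- function(claims, adjustment) {
  cl <- data.table::as.data.table(claims)
  yen <- adjust_expenditure(cl$expenditure_yen, cl$month, adjustment)
  yen_to_usd(yen, adjustment)
}

#' Matched-comparison net expenditure estimates
#'
#' For each matched pair the case's phase months are aligned to the control
#' by the pair's anchor offset; the paired difference in price-adjusted USD
#' PPPM is averaged over pairs within treatment type (plus a pooled
#' `"Total"` row), with a paired-t 95% confidence interval.
#'
#' @param pairs Matched pairs (`case_id`, `control_id`, `anchor_offset`,
#'   `cohort`), e.g. `match_incident(...)$pairs`.
#' @param phase_maps Phase maps of the cases ([build_phase_maps()]).
#' @param claims Claims panel covering cases and controls.
#' @param register Case register (for treatment types).
#' @param adjustment A [price_adjustment()].
#' @param phases Phases to estimate (default: the phases the cohort
#'   supports).
#' @return A `data.table` with one row per treatment type and phase:
#'   `method`, `cohort`, `treatment_type`, `phase`, `n` (pairs),
#'   `case_usd_pppm`, `reference_usd_pppm` (control mean), `net_usd_pppm`,
#'   `ci_low`, `ci_high` (`NA` with a warning when `n < 2`).
#' @export
matched_net_estimates <- function(pairs, phase_maps, claims, register,
                                  adjustment = price_adjustment(),
                                  phases = NULL) {
  pr <- data.table::as.data.table(pairs)
  if (!nrow(pr)) stop("no matched pairs", call. = FALSE)
  cohort <- unique(pr$cohort)
  stopifnot(length(cohort) == 1L)
  if (is.null(phases)) {
    phases <- if (cohort == "death") "terminal" else c("initial", "continuing")
  }
  cl <- data.table::as.data.table(claims)
  if (!is.numeric(cl$month)) cl <- data.table::copy(cl)[, month := ym(month)]
  cl <- cl[, .(patient_id, month,
               usd = adjusted_usd(.SD, adjustment))]
  pm <- data.table::as.data.table(phase_maps)[phase %in% phases]

  # case phase months for each pair, shifted onto the control's calendar
  aligned <- merge(pm, pr[, .(case_id, control_id, anchor_offset)],
                   by.x = "patient_id", by.y = "case_id",
                   allow.cartesian = TRUE)
  data.table::setnames(aligned, "patient_id", "case_id")
  aligned[, control_month := month + anchor_offset]

  case_side <- merge(aligned, cl, by.x = c("case_id", "month"),
                     by.y = c("patient_id", "month"))
  case_pppm <- case_side[, .(case_pppm = mean(usd)),
                         by = .(case_id, control_id, phase)]
  ctrl_side <- merge(aligned, cl, by.x = c("control_id", "control_month"),
                     by.y = c("patient_id", "month"))
  ctrl_pppm <- ctrl_side[, .(control_pppm = mean(usd)),
                         by = .(case_id, control_id, phase)]
  d <- merge(case_pppm, ctrl_pppm, by = c("case_id", "control_id", "phase"))
  d[, diff := case_pppm - control_pppm]
  reg <- data.table::as.data.table(register)[, .(case_id = patient_id,
                                                 treatment_type)]
  d <- merge(d, reg, by = "case_id")

  pair_stats <- function(diff, case_pppm, control_pppm) {
    n <- length(diff)
    est <- mean(diff)
    half <- if (n >= 2L) {
      stats::qt(0.975, n - 1L) * stats::sd(diff) / sqrt(n)
    } else NA_real_
    list(method = "matched", cohort = cohort, n = n,
         case_usd_pppm = mean(case_pppm),
         reference_usd_pppm = mean(control_pppm),
         net_usd_pppm = est, ci_low = est - half, ci_high = est + half)
  }
  per_tt <- d[, pair_stats(diff, case_pppm, control_pppm),
              by = .(treatment_type, phase)]
  total <- d[, pair_stats(diff, case_pppm, control_pppm), by = .(phase)]
  total[, treatment_type := "Total"]
  out <- data.table::rbindlist(list(per_tt, total), use.names = TRUE,
                               fill = TRUE)
  if (any(out$n < 2L)) {
    warning("some strata have < 2 pairs: point estimate only, CI undefined",
            call. = FALSE)
  }
  data.table::setcolorder(out, c("method", "cohort", "treatment_type",
                                 "phase", "n"))
  out[]
}

#' Within-patient (fixed-effects) least squares
#'
#' Demeans the outcome and every regressor within patient and runs ordinary
#' least squares on the demeaned data; coefficients are numerically
#' identical to least squares with one dummy per patient. Residual degrees
#' of freedom are `N - G - k` (observations minus patients minus
#' regressors). Standard errors are conventional homoskedastic OLS by
#' default; `cluster = TRUE` gives CR1 cluster-robust errors by patient.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric design matrix (no intercept; it is absorbed by the
#'   patient effects).
#' @param id Patient grouping vector, same length as `y`.
#' @param cluster Use cluster-robust (by `id`) standard errors?
#' @return A list: `coefficients`, `se`, `vcov`, `df`, `n_obs`, `n_groups`.
#' @export
within_ols <- function(y, X, id, cluster = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  id <- as.factor(id)
  G <- nlevels(id)
  demean <- function(v) v - stats::ave(v, id)
  yd <- demean(y)
  Xd <- apply(X, 2L, demean)
  if (!is.matrix(Xd)) Xd <- matrix(Xd, ncol = ncol(X),
                                   dimnames = list(NULL, colnames(X)))
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("singular design after within-patient demeaning; ",
         "collinear or patient-invariant column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yd)
  resid <- yd - Xd %*% beta
  n <- length(y)
  k <- ncol(Xd)
  df <- n - G - k
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  XtX_inv <- chol2inv(qr.R(qrX))
  rownames(XtX_inv) <- colnames(XtX_inv) <- colnames(Xd)
  if (cluster) {
    Xe <- Xd * as.vector(resid)
    meat <- crossprod(rowsum(Xe, id))
    V <- (G / (G - 1)) * XtX_inv %*% meat %*% XtX_inv
  } else {
    sigma2 <- sum(resid^2) / df
    V <- sigma2 * XtX_inv
  }
  list(coefficients = stats::setNames(as.vector(beta), colnames(Xd)),
       se = sqrt(diag(V)), vcov = V, df = df, n_obs = n, n_groups = G)
}

#' Fixed-effects net expenditure estimates
#'
#' Builds a patient-month panel per cohort — a pre-disease reference window
#' of `pre_window` months ending two months before the index month, plus
#' the cohort's phase months (incident cohort: initial and continuing;
#' death cohort: terminal) — and regresses price-adjusted USD expenditure
#' on phase indicators, age in years and the weighted comorbidity score,
#' with patient fixed effects. Phase coefficients are the net estimates;
#' the reference level is the mean adjusted expenditure over pre months.
#'
#' @param register Case register; incident cohort uses all eligible cases,
#'   death cohort the eligible cases with observed death.
#' @param phase_maps Phase maps of the cases.
#' @param claims Claims panel.
#' @param demographics Demographics table (for birth months, hence the
#'   time-dependent age covariate).
#' @param cohort `"incident"` or `"death"`.
#' @param adjustment A [price_adjustment()].
#' @param pre_window Length (months) of the pre-disease reference window.
#' @param cluster Cluster-robust standard errors (by patient)?
#' @param by_treatment Also fit one model per treatment type (in addition
#'   to the pooled `"Total"` model)?
#' @return A `data.table` with one row per treatment type and phase:
#'   `method`, `cohort`, `treatment_type`, `phase`, `n` (patients),
#'   `reference_usd_pppm`, `net_usd_pppm`, `ci_low`, `ci_high`.
#' @export
fixed_effects_estimates <- function(register, phase_maps, claims,
                                    demographics,
                                    cohort = c("incident", "death"),
                                    adjustment = price_adjustment(),
                                    pre_window = 12L, cluster = FALSE,
                                    by_treatment = TRUE) {
  cohort <- match.arg(cohort)
  reg <- data.table::as.data.table(register)[eligible == TRUE]
  if (cohort == "death") reg <- reg[!is.na(death_month)]
  if (!nrow(reg)) stop("no eligible cases for the ", cohort, " cohort",
                       call. = FALSE)
  phases <- if (cohort == "incident") c("initial", "continuing") else "terminal"

  cl <- data.table::as.data.table(claims)
  if (!is.numeric(cl$month)) cl <- data.table::copy(cl)[, month := ym(month)]
  pm <- data.table::as.data.table(phase_maps)

  # pre months: window ending at index - 2 (index - 1 belongs to the
  # initial phase), intersected with observation
  pre <- reg[, .(patient_id, index_month)][
    , .(month = seq.int(index_month - 1L - pre_window, index_month - 2L)),
    by = patient_id]
  pre[, phase := "pre"]
  keep <- pm[phase %in% phases, .(patient_id, month, phase)]
  panel <- rbind(pre, keep)
  panel <- merge(panel, cl[, .(patient_id, month, expenditure_yen)],
                 by = c("patient_id", "month"))  # drops unobserved pre months
  panel[, usd := yen_to_usd(adjust_expenditure(expenditure_yen, month,
                                               adjustment), adjustment)]
  # require >= 1 pre and >= 1 phase month per patient
  ok <- panel[, .(has_pre = any(phase == "pre"),
                  has_phase = any(phase != "pre")), by = patient_id]
  panel <- panel[patient_id %in% ok[has_pre & has_phase, patient_id]]
  if (!nrow(panel) || all(panel$phase == "pre")) {
    stop("no cases with both pre-disease and in-phase months", call. = FALSE)
  }

  # time-dependent covariates
  dem_cols <- c("patient_id", "month", cci_columns())
  panel <- merge(panel, cl[, dem_cols, with = FALSE],
                 by = c("patient_id", "month"))
  panel[, cci := cci_score(.SD), .SDcols = cci_columns()]
  dem <- data.table::as.data.table(demographics)
  panel <- merge(panel, dem[, .(patient_id, birth_month = ym(birth_month))],
                 by = "patient_id")
  panel[, age := age_years(birth_month, month)]
  panel <- merge(panel, reg[, .(patient_id, treatment_type)], by = "patient_id")

  fit_one <- function(dd, label) {
    X <- cbind(vapply(phases, function(p) as.numeric(dd$phase == p),
                      numeric(nrow(dd))),
               age = dd$age, cci = dd$cci)
    colnames(X)[seq_along(phases)] <- phases
    # covariates without any within-patient variation cannot be identified
    # alongside the fixed effects; drop them rather than abort the fit
    keep_cols <- vapply(seq_len(ncol(X)), function(j) {
      v <- X[, j] - stats::ave(X[, j], dd$patient_id)
      any(abs(v) > 1e-10)
    }, logical(1))
    keep_cols[seq_along(phases)] <- TRUE
    fit <- within_ols(dd$usd, X[, keep_cols, drop = FALSE], dd$patient_id,
                      cluster = cluster)
    refv <- mean(dd$usd[dd$phase == "pre"])
    data.table::data.table(
      method = "fixed_effects", cohort = cohort, treatment_type = label,
      phase = phases,
      n = length(unique(dd$patient_id)),
      reference_usd_pppm = refv,
      net_usd_pppm = fit$coefficients[phases],
      ci_low = fit$coefficients[phases] - 1.96 * fit$se[phases],
      ci_high = fit$coefficients[phases] + 1.96 * fit$se[phases])
  }

  out <- list(fit_one(panel, "Total"))
  if (by_treatment) {
    for (tt in intersect(treatment_types(), unique(panel$treatment_type))) {
      dd <- panel[treatment_type == tt]
      if (length(unique(dd$patient_id)) < 2L) next
      if (!all(vapply(phases, function(p) any(dd$phase == p), logical(1)))) next
      out <- c(out, list(fit_one(dd, tt)))
    }
  }
  data.table::rbindlist(out)[]
}
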