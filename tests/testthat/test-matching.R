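test_that("match keys are deterministic and encode sex, band and flags", {
  flags <- as.integer(phasecost:::cci_conditions() == "mild_liver")
  k <- build_match_key("F", "1941-03", flags, "2013-05")
  expect_equal(k, paste0("F|70-74|", paste(flags, collapse = "")))
  expect_identical(build_match_key("F", "1941-03", flags, "2013-05"), k)
  expect_error(build_match_key("X", "1941-03", flags, "2013-05"), "sex")
  expect_error(build_match_key("F", NA, flags, "2013-05"), "birth")
})

test_that("age bands agree with an interval oracle over ages 20..100", {
  ages <- 20:100
  oracle <- cut(ages, breaks = c(seq(20, 95, by = 5), Inf), right = FALSE,
                labels = c(sprintf("%d-%d", seq(20, 90, 5), seq(24, 94, 5)),
                           "95+"))
  expect_equal(age_band(ages), as.character(oracle))
  expect_equal(age_band(20), "20-24")
  expect_equal(age_band(94), "90-94")
  expect_equal(age_band(95), "95+")
  expect_true(is.na(age_band(19)))
})

# maintenance treatment every third month keeps the persistent diagnosis
# flag from tripping the 7-month recurrence rule in hand-built cases
maintained_tx <- function(months, idx) {
  as.integer(months >= idx & ((months - idx) %% 3L == 0L | months == idx + 1L))
}

# two patients on identical months, everything zero-flagged; the case gets
# an HCC flag from the index month onward
matched_world <- function(control_months_utilized, case_index = "2013-05") {
  months <- seq(ym("2012-01"), ym("2014-12"))
  idx <- ym(case_index)
  case <- fab_claims(1, months, expenditure = 1000,
                     dx_hcc = as.integer(months >= idx),
                     tx = list(tx_resection = maintained_tx(months, idx)))
  ctrl <- fab_claims(2, months,
                     expenditure = 1000 * as.integer(months %in% ym(control_months_utilized)))
  claims <- rbind(case, ctrl)
  demo <- rbind(fab_demo(1, "F", "1950-01"), fab_demo(2, "F", "1950-01"))
  reg <- build_case_register(claims, demo)
  list(claims = claims, demo = demo, reg = reg)
}

test_that("incident matching expands the month window to the nearest utilization", {
  w <- matched_world("2013-05")
  res <- match_incident(w$reg, w$claims, w$demo, seed = 1)
  expect_equal(res$pairs$anchor_offset, 0L)
  expect_equal(res$pairs$control_id, 2L)

  w <- matched_world("2013-08")  # only 3 months after the index
  res <- match_incident(w$reg, w$claims, w$demo, seed = 1)
  expect_equal(res$pairs$anchor_offset, 3L)

  w <- matched_world("2012-02")  # 15 months before: beyond the 1-year window
  res <- match_incident(w$reg, w$claims, w$demo, seed = 1)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(res$unmatched$case_id, 1L)
})

test_that("equidistant expansion ties resolve to the earlier month", {
  months <- seq(ym("2012-01"), ym("2014-12"))
  idx <- ym("2013-05")
  case <- fab_claims(1, months, expenditure = 1000,
                     dx_hcc = as.integer(months >= idx),
                     tx = list(tx_resection = maintained_tx(months, idx)))
  early <- fab_claims(2, months,
                      expenditure = 1000 * as.integer(months == idx - 2L))
  late <- fab_claims(3, months,
                     expenditure = 1000 * as.integer(months == idx + 2L))
  claims <- rbind(case, early, late)
  demo <- data.table::rbindlist(lapply(1:3, fab_demo, sex = "F",
                                       birth = "1950-01"))
  reg <- build_case_register(claims, demo)
  res <- match_incident(reg, claims, demo, seed = 1)
  expect_equal(res$pairs$anchor_offset, -2L)
  expect_equal(res$pairs$control_id, 2L)
})

test_that("matching is without replacement and seeded", {
  months <- seq(ym("2012-01"), ym("2014-12"))
  idx <- ym("2013-05")
  mk_case <- function(pid) {
    fab_claims(pid, months, expenditure = 1000,
               dx_hcc = as.integer(months >= idx),
               tx = list(tx_resection = maintained_tx(months, idx)))
  }
  claims <- rbind(mk_case(1), mk_case(2),
                  fab_claims(3, months, expenditure = 1000))
  demo <- data.table::rbindlist(lapply(1:3, fab_demo, sex = "F",
                                       birth = "1950-01"))
  reg <- build_case_register(claims, demo)
  res <- match_incident(reg, claims, demo, seed = 1)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(nrow(res$unmatched), 1L)
  expect_equal(res$pairs$control_id, 3L)
  # ascending-id processing: case 1 claims the only control
  expect_equal(res$pairs$case_id, 1L)

  # same seed, same result (on a stochastic stratum: many controls)
  pop <- small_population(seed = 9, n = 2000)
  reg2 <- build_case_register(pop$claims, pop$demographics)
  a <- match_incident(reg2, pop$claims, pop$demographics, seed = 4)
  b <- match_incident(reg2, pop$claims, pop$demographics, seed = 4)
  expect_identical(a, b)
  expect_true(all(!duplicated(a$pairs$control_id)))
})

test_that("death-cohort matching requires the same death month, no expansion", {
  months <- seq(ym("2012-01"), ym("2014-12"))
  idx <- ym("2013-05")
  dth <- ym("2014-03")
  cmonths <- seq(months[1], dth)
  case <- fab_claims(1, cmonths, expenditure = 1000,
                     dx_hcc = as.integer(cmonths >= idx),
                     tx = list(tx_resection = maintained_tx(cmonths, idx)))
  mk_ctrl <- function(pid, dmonth) {
    fab_claims(pid, seq(months[1], ym(dmonth)), expenditure = 1000)
  }
  claims <- rbind(case, mk_ctrl(2, "2014-04"))
  demo <- rbind(fab_demo(1, "F", "1950-01", dth),
                fab_demo(2, "F", "1950-01", "2014-04"))
  reg <- build_case_register(claims, demo)
  res <- match_death(reg, claims, demo, seed = 1)
  expect_equal(nrow(res$pairs), 0L)   # control died one month later

  claims2 <- rbind(case, mk_ctrl(2, "2014-03"))
  demo2 <- rbind(fab_demo(1, "F", "1950-01", dth),
                 fab_demo(2, "F", "1950-01", "2014-03"))
  reg2 <- build_case_register(claims2, demo2)
  res2 <- match_death(reg2, claims2, demo2, seed = 1)
  expect_equal(res2$pairs$control_id, 2L)
  expect_equal(res2$pairs$anchor_offset, 0L)
})

test_that("matched pairs have identical stratum keys (covariate balance)", {
  pop <- small_population(seed = 11, n = 3000)
  reg <- build_case_register(pop$claims, pop$demographics)
  keys <- phasecost:::patient_month_keys(pop$claims, pop$demographics)
  inc <- match_incident(reg, pop$claims, pop$demographics, seed = 2,
                        keys = keys)
  expect_gt(nrow(inc$pairs), 20)
  anchors <- merge(inc$pairs,
                   reg[, .(case_id = patient_id, index_month)],
                   by = "case_id")
  anchors[, target := index_month + anchor_offset]
  ck <- merge(anchors, keys, by.x = c("case_id", "index_month"),
              by.y = c("patient_id", "month"))
  kk <- merge(anchors, keys, by.x = c("control_id", "target"),
              by.y = c("patient_id", "month"))
  balance <- merge(ck[, .(case_id, case_key = key)],
                   kk[, .(case_id, control_key = key)], by = "case_id")
  expect_equal(nrow(balance), nrow(inc$pairs))
  expect_equal(balance$case_key, balance$control_key)
  # controls never carry an HCC flag and utilized the anchor month
  hcc_ids <- unique(pop$claims[dx_hcc > 0, patient_id])
  expect_length(intersect(inc$pairs$control_id, hcc_ids), 0)
  expect_true(all(kk$utilized))
})

test_that("match rate is monotone non-decreasing in pool size", {
  pop <- small_population(seed = 13, n = 3000)
  reg <- build_case_register(pop$claims, pop$demographics)
  ctrl_ids <- setdiff(unique(pop$claims$patient_id),
                      unique(pop$claims[dx_hcc > 0, patient_id]))
  rate <- sapply(c(0.2, 0.5, 1), function(frac) {
    keep <- c(reg$patient_id,
              ctrl_ids[seq_len(floor(length(ctrl_ids) * frac))])
    cl <- pop$claims[patient_id %in% keep]
    dm <- pop$demographics[patient_id %in% keep]
    res <- match_incident(reg, cl, dm, seed = 3)
    nrow(res$pairs) / (nrow(res$pairs) + nrow(res$unmatched))
  })
  expect_true(all(diff(rate) >= 0))
})
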