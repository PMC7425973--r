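test_that("index month requires a clean 12-month cancer-free lookback", {
  months <- seq(ym("2012-01"), ym("2014-06"))
  tl <- fab_claims(1, months, dx_hcc = as.integer(months >= ym("2013-05")))
  expect_equal(find_index_month(tl, "1943-02"), ym("2013-05"))

  # other-cancer diagnosis inside the lookback window blocks eligibility
  tl2 <- data.table::copy(tl)
  tl2[month >= ym("2013-01"), dx_other_cancer := 1L]
  expect_true(is.na(find_index_month(tl2, "1943-02")))

  # under 20 at the qualifying month
  expect_true(is.na(find_index_month(tl, "1994-01")))

  # entering observation < 12 months before the first flag
  tl3 <- tl[month >= ym("2012-09")]
  expect_true(is.na(find_index_month(tl3, "1943-02")))

  expect_error(find_index_month(tl[c(2, 1)], "1943-02"), "sorted")
})

test_that("recurrence needs >= 7 treatment-free months before a diagnosis", {
  months <- seq(ym("2013-05"), ym("2015-06"))
  base <- fab_claims(1, months, dx_hcc = 1L)
  rec <- data.table::copy(base)
  # initial treatment through 2014-03, nothing 2014-04..2014-10 (7 months)
  rec[, tx_tace := as.integer(month <= ym("2014-03") | month >= ym("2014-11"))]
  expect_true(detect_recurrence(rec, "2013-05"))

  cont <- data.table::copy(base)[, tx_tace := 1L]
  expect_false(detect_recurrence(cont, "2013-05"))

  six <- data.table::copy(base)
  six[, tx_tace := as.integer(month <= ym("2014-03") | month >= ym("2014-10"))]
  expect_false(detect_recurrence(six, "2013-05"))
})

test_that("phase classification handles the standard pattern and exceptions", {
  m <- ym("2013-05")
  # death during the index month
  p <- classify_phases(m, m)
  expect_equal(p$phase, c("initial", "terminal"))
  expect_equal(p$month, c(m - 1L, m))
  # death one month after the index month
  p <- classify_phases(m, m + 1L)
  expect_equal(p$phase, c("initial", "initial", "terminal"))
  # death 5 months after the index month: terminal runs index+2..death
  p <- classify_phases(m, m + 5L)
  expect_equal(p$phase,
               c("initial", "initial", "initial", rep("terminal", 4L)))
  # standard: death 24 months after the index month
  p <- classify_phases(m, m + 24L)
  expect_equal(p[phase == "initial", month], c(m - 1L, m, m + 1L))
  expect_equal(p[phase == "continuing", month], seq(m + 2L, m + 18L))
  expect_equal(p[phase == "terminal", month], seq(m + 19L, m + 24L))
  # censored: no terminal, continuing to the last observed month
  p <- classify_phases(m, NA, last_month = m + 10L)
  expect_false("terminal" %in% p$phase)
  expect_equal(p[phase == "continuing", month], seq(m + 2L, m + 10L))
  # pre months labelled before the initial phase
  p <- classify_phases(m, m + 24L, first_month = m - 4L)
  expect_equal(p[phase == "pre", month], seq(m - 4L, m - 2L))

  expect_error(classify_phases(m, m - 1L), "death")
})

test_that("terminal block spans min(6, death - index - 1) months beyond the early exceptions", {
  m <- ym("2012-01")
  for (d in 2:40) {
    p <- classify_phases(m, m + d)
    expect_equal(sum(p$phase == "terminal"), min(6L, d - 1L))
  }
})

test_that("modality-set classification is total and matches the category table", {
  expect_equal(classify_modalities("resection"), "Surgical resection only")
  expect_equal(classify_modalities(c("tace", "chemo", "sorafenib")),
               "TACE + chemotherapy + sorafenib")
  expect_equal(classify_modalities(c("resection", "radiotherapy")),
               "Surgical resection + others")
  expect_equal(classify_modalities(c("resection", "tace", "tae")),
               "Surgical resection + TACE/TAE")
  expect_equal(classify_modalities(c("lrt", "tae")), "LRT+TACE/TAE")
  expect_equal(classify_modalities(c("lrt", "chemo", "sorafenib")),
               "LRT + others")
  expect_equal(classify_modalities("radiotherapy"), "Others")
  expect_true(is.na(classify_modalities(character())))

  # totality and determinism over all 2^7 modality subsets
  mods <- phasecost:::tx_modalities()
  for (bits in 1:(2^7 - 1)) {
    s <- mods[bitwAnd(bits, 2^(0:6)) > 0]
    lab <- classify_modalities(s)
    expect_true(lab %in% treatment_types())
    expect_identical(classify_modalities(rev(s)), lab)
  }

  # the generator's representative modality sets round-trip to their labels
  tm <- phasecost:::treatment_type_modalities()
  for (lab in names(tm)) {
    expect_identical(classify_modalities(tm[[lab]]), lab)
  }
})

test_that("treatment typing uses flags from index-1 through the end month", {
  months <- seq(ym("2013-01"), ym("2014-06"))
  tl <- fab_claims(1, months, dx_hcc = 1L)
  tl[month == ym("2013-06"), tx_resection := 1L]
  tl[month == ym("2013-01"), tx_chemo := 1L]  # before the index-1 window
  expect_equal(assign_treatment_type(tl, "2013-06", "2014-06"),
               "Surgical resection only")
  # untreated cases carry no label
  none <- fab_claims(2, months, dx_hcc = 1L)
  expect_true(is.na(assign_treatment_type(none, "2013-06", "2014-06")))
})

test_that("case register screens eligibility and excludes recurrence trajectories", {
  pop <- small_population(seed = 5, n = 2500, recurrence_prob = 0.25)
  reg <- build_case_register(pop$claims, pop$demographics)
  truth <- pop$truth

  # every eligible case is a true case with a matching index month
  eligible <- reg[eligible == TRUE]
  tru <- truth[match(eligible$patient_id, patient_id)]
  expect_true(all(tru$is_hcc_case))
  expect_equal(eligible$index_month, tru$hcc_index_month)
  expect_equal(eligible$treatment_type, tru$treatment_type)

  # recurrence trajectories that survive long enough to show the gap are
  # excluded; no non-recurrent case is excluded for recurrence
  excl_rec <- reg[exclusion_reason == "recurrence", patient_id]
  expect_true(all(truth[match(excl_rec, patient_id), is_recurrent]))
  # the treatment gap only becomes visible when the case is observed at
  # least 9 months past the index (diagnosis at >= 7 treatment-free months)
  obs_end <- pmin(ifelse(is.na(truth$death_month), ym("2015-03"),
                         truth$death_month), ym("2015-03"))
  long_rec <- truth[is_recurrent & !is.na(hcc_index_month) &
                      obs_end - hcc_index_month >= 9L]
  in_reg <- reg[patient_id %in% long_rec$patient_id]
  lookback_ok <- in_reg[!exclusion_reason %in%
                          c("lookback_or_entry", "age_under_20")]
  expect_true(all(lookback_ok$exclusion_reason == "recurrence"))

  # phase maps partition each eligible case's observed months
  pm <- build_phase_maps(reg, pop$claims)
  counts <- pm[, .N, by = .(patient_id, month)]
  expect_true(all(counts$N == 1L))
  expect_false(any(is.na(pm$phase)))
})
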