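test_that("pppm is the arithmetic mean with zero-utilization months retained", {
  tl <- fab_claims(1, c("2018-05", "2018-06", "2018-07"),
                   expenditure = c(100, 0, 200))
  expect_equal(pppm(tl, ym(c("2018-05", "2018-06", "2018-07"))), 100)
  expect_equal(pppm(tl, ym("2018-07")), 200)
  tl0 <- fab_claims(1, c("2018-05", "2018-06"), expenditure = 0)
  expect_equal(pppm(tl0, ym(c("2018-05", "2018-06"))), 0)
  expect_error(pppm(tl, integer()), "empty")
  # price adjustment applies per service month
  tl2 <- fab_claims(1, "2010-06", expenditure = 10000)
  expect_equal(pppm(tl2, ym("2010-06"), price_adjustment()), 10190)
})

test_that("matched estimates equal the mean paired difference with a t interval", {
  months <- seq(ym("2018-04"), ym("2018-06"))
  claims <- data.table::rbindlist(list(
    fab_claims(1, months, expenditure = 110),   # case 1
    fab_claims(2, months, expenditure = 100),   # its control: d = 10
    fab_claims(3, months, expenditure = 150),   # case 2
    fab_claims(4, months, expenditure = 120)))  # its control: d = 30
  pairs <- data.table::data.table(case_id = c(1L, 3L),
                                  control_id = c(2L, 4L),
                                  anchor_offset = 0L, cohort = "incident")
  pm <- data.table::rbindlist(lapply(c(1L, 3L), function(p) {
    data.table::data.table(patient_id = p, month = months, phase = "initial")
  }))
  reg <- rbind(fab_register(1, "2018-05"), fab_register(3, "2018-05"))
  est <- matched_net_estimates(pairs, pm, claims, reg,
                               adjustment = flat_adjustment())
  tot <- est[treatment_type == "Total"]
  expect_equal(tot$net_usd_pppm, 20)
  oracle <- t.test(c(10, 30))
  expect_equal(tot$ci_low, oracle$conf.int[1])
  expect_equal(tot$ci_high, oracle$conf.int[2])
  expect_equal(tot$n, 2L)
  expect_equal(tot$reference_usd_pppm, 110)

  # identical case and control timelines: estimate 0, CI contains 0
  claims2 <- rbind(fab_claims(1, months, expenditure = 100),
                   fab_claims(2, months, expenditure = 100),
                   fab_claims(3, months, expenditure = 100),
                   fab_claims(4, months, expenditure = 100))
  est2 <- matched_net_estimates(pairs, pm, claims2, reg,
                                adjustment = flat_adjustment())
  tot2 <- est2[treatment_type == "Total"]
  expect_equal(tot2$net_usd_pppm, 0)
  expect_true(tot2$ci_low <= 0 && tot2$ci_high >= 0)

  # anchor offsets shift the control months: control 4 is averaged over
  # 2018-06..2018-08 instead of 2018-04..2018-06
  pairs3 <- data.table::copy(pairs)[, anchor_offset := c(0L, 2L)]
  claims3 <- data.table::rbindlist(list(
    claims[patient_id != 4L],
    fab_claims(4, seq(ym("2018-04"), ym("2018-08")),
               expenditure = c(120, 120, 120, 90, 90))))
  est3 <- matched_net_estimates(pairs3, pm, claims3, reg,
                                adjustment = flat_adjustment())
  # d = (10, 150 - mean(120, 90, 90)) = (10, 50)
  expect_equal(est3[treatment_type == "Total", net_usd_pppm], 30)
})

test_that("single-pair strata yield a point estimate with undefined CI", {
  months <- seq(ym("2018-04"), ym("2018-06"))
  claims <- rbind(fab_claims(1, months, expenditure = 110),
                  fab_claims(2, months, expenditure = 100))
  pairs <- data.table::data.table(case_id = 1L, control_id = 2L,
                                  anchor_offset = 0L, cohort = "incident")
  pm <- data.table::data.table(patient_id = 1L, month = months,
                               phase = "initial")
  reg <- fab_register(1, "2018-05")
  expect_warning(
    est <- matched_net_estimates(pairs, pm, claims, reg,
                                 adjustment = flat_adjustment()),
    "< 2 pairs")
  expect_equal(est$net_usd_pppm, c(10, 10))
  expect_true(all(is.na(est$ci_low)))
})

test_that("within-patient OLS equals dummy-variable OLS", {
  # closed form: both patients rise by exactly 5 from pre to post
  y <- c(10, 15, 20, 25)
  X <- matrix(c(0, 1, 0, 1), ncol = 1, dimnames = list(NULL, "post"))
  id <- c(1, 1, 2, 2)
  fit <- within_ols(y, X, id)
  expect_equal(unname(fit$coefficients["post"]), 5)

  # oracle comparison on random small panels
  set.seed(42)
  for (r in 1:20) {
    n_pat <- 6L
    n_t <- 8L
    id <- rep(seq_len(n_pat), each = n_t)
    X <- cbind(a = rnorm(n_pat * n_t), b = rbinom(n_pat * n_t, 1, 0.4))
    y <- rnorm(n_pat)[id] + 2 * X[, "a"] - X[, "b"] + rnorm(n_pat * n_t)
    fit <- within_ols(y, X, id)
    dummy <- lm(y ~ X + factor(id))
    expect_equal(unname(fit$coefficients),
                 unname(coef(dummy)[c("Xa", "Xb")]), tolerance = 1e-8)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(dummy)))[c("Xa", "Xb")]),
                 tolerance = 1e-8)
    expect_equal(fit$df, dummy$df.residual)
  }
})

test_that("patient-invariant regressors are rejected as singular", {
  id <- rep(1:3, each = 4)
  X <- cbind(post = rep(c(0, 0, 1, 1), 3), sex = rep(c(1, 0, 1), each = 4))
  y <- rnorm(12)
  expect_error(within_ols(y, X, id), "sex")
})

test_that("cluster-robust errors differ but coefficients do not", {
  set.seed(7)
  id <- rep(1:10, each = 6)
  X <- cbind(x = rnorm(60))
  y <- rnorm(10)[id] + X[, 1] + rnorm(60)
  a <- within_ols(y, X, id)
  b <- within_ols(y, X, id, cluster = TRUE)
  expect_equal(a$coefficients, b$coefficients)
  expect_false(isTRUE(all.equal(a$se, b$se)))
})

test_that("degenerate single-patient panel recovers the level shift exactly", {
  months <- seq(ym("2018-04"), ym("2018-09"))
  claims <- fab_claims(1, months, expenditure = c(100, 100, 100, 250, 250, 250))
  pm <- data.table::data.table(patient_id = 1L, month = months,
                               phase = rep(c("pre", "terminal"), each = 3))
  y <- claims$expenditure_yen
  X <- matrix(as.numeric(pm$phase == "terminal"), ncol = 1,
              dimnames = list(NULL, "terminal"))
  fit <- within_ols(y, X, rep(1L, 6))
  expect_equal(unname(fit$coefficients["terminal"]), 150)
})

test_that("with balanced blocks and no covariates the FE coefficient is the mean within-patient contrast", {
  set.seed(31)
  n_pat <- 12L
  pre_m <- seq(ym("2018-04"), length.out = 4L)
  post_m <- seq(ym("2018-08"), length.out = 4L)
  rows <- lapply(seq_len(n_pat), function(p) {
    fab_claims(p, c(pre_m, post_m),
               expenditure = rnorm(8, mean = c(rep(100, 4), rep(300, 4)),
                                   sd = 20))
  })
  claims <- data.table::rbindlist(rows)
  pm <- data.table::rbindlist(lapply(seq_len(n_pat), function(p) {
    data.table::data.table(patient_id = p, month = c(pre_m, post_m),
                           phase = rep(c("pre", "initial"), each = 4))
  }))
  y <- claims$expenditure_yen
  X <- matrix(as.numeric(pm$phase == "initial"), ncol = 1,
              dimnames = list(NULL, "initial"))
  fit <- within_ols(y, X, claims$patient_id)
  contrast <- claims[, .(d = mean(expenditure_yen[5:8]) -
                           mean(expenditure_yen[1:4])), by = patient_id]
  expect_equal(unname(fit$coefficients["initial"]), mean(contrast$d))
})

test_that("fixed-effects estimation recovers an injected continuing increment", {
  cfg <- simulation_config(
    n_patients = 3500, study_start = "2011-04", study_end = "2015-03",
    seed = 17, hcc_monthly_hazard = 2e-3, post_hcc_death_hazard = 0.02,
    background_death_hazard = 0.003, eol_surge_multiplier = 1,
    phase_increment_yen = uniform_phase_increments(0, 30000, 0))
  pop <- generate_population(cfg)
  reg <- build_case_register(pop$claims, pop$demographics)
  pm <- build_phase_maps(reg, pop$claims)
  fe <- fixed_effects_estimates(reg, pm, pop$claims, pop$demographics,
                                "incident", adjustment = flat_adjustment(),
                                by_treatment = FALSE)
  cont <- fe[phase == "continuing"]
  expect_gt(cont$n, 100)
  # the 95% interval covers the injected truth
  expect_lte(cont$ci_low, 30000)
  expect_gte(cont$ci_high, 30000)
})
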