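test_that("split_dose partitions the inhaled dose and conserves mass", {
  expect_equal(split_dose(320, 0.38), c(lung = 121.6, gut = 198.4))
  expect_equal(split_dose(9, 0.385), c(lung = 3.4650, gut = 5.5350))
  set.seed(1)
  for (k in 1:25) {
    dose <- runif(1, 1, 1000)
    fr <- runif(1, 0.01, 0.99)
    s <- split_dose(dose, fr)
    expect_equal(unname(s[["lung"]] + s[["gut"]]), dose)
  }
  expect_error(split_dose(320, 0), "FR")
  expect_error(split_dose(320, 1), "FR")
  expect_error(split_dose(-1, 0.5), "dose")
})

test_that("lung concentration divides by lung volume in the drug's unit", {
  expect_equal(lung_concentration(121.6, 1.1, "budesonide"), 121.6 / 1.1)
  expect_equal(lung_concentration(0, 1.1, "budesonide"), 0)
  # 3.465 ug in 1.1 L = 3.15 ug/L = 3150 pg/mL
  expect_equal(lung_concentration(3.465, 1.1, "formoterol"), 3150)
  expect_error(lung_concentration(-1, 1.1, "budesonide"), "non-negative")
})

test_that("turnover derivatives honour stationarity, half-maximum and limits", {
  p <- default_parameters()
  ecp <- p$ecp
  fev1 <- p$fev1
  # baseline with no drug is an equilibrium
  expect_equal(ecp_rhs(ecp$BASE, 0, ecp), 0)
  expect_equal(fev1_rhs(fev1$BASE, 0, fev1), 0)
  # half-maximal effect at C = C50
  expect_equal(ecp_rhs(ecp$BASE, ecp$C50, ecp), -0.5 * ecp$kout * ecp$BASE)
  expect_equal(fev1_rhs(fev1$BASE, fev1$C50, fev1), 0.5 * fev1$kout * fev1$BASE)
  # saturating limits: full inhibition shuts production off entirely;
  # full stimulation doubles it, with steady state at 2 * BASE
  R <- 12
  expect_equal(ecp_rhs(R, 1e12, ecp), -ecp$kout * R, tolerance = 1e-9)
  expect_equal(fev1_rhs(2 * fev1$BASE, 1e12, fev1), 0, tolerance = 1e-6)
})

test_that("the ACT equation reproduces its component offsets", {
  co <- default_parameters()$co
  expect_equal(act_score(0, 19.7, 85.8, 19.7, 85.8, co), 19.7)
  expect_equal(act_score(0, 19.7 - 10, 85.8, 19.7, 85.8, co),
               19.7 + 10 * 0.00008)
  expect_equal(act_score(0, 19.7, 85.8 + 5, 19.7, 85.8, co),
               19.7 + 5 * 0.644)
  # unbounded by default; clipping only when configured
  expect_gt(act_score(0, 19.7, 120, 19.7, 85.8, co), 25)
  co_clip <- co_params(co$BASE_ACT, co$alpha, co$beta1, co$beta2, clip = TRUE)
  expect_equal(act_score(0, 19.7, 120, 19.7, 85.8, co_clip), 25)
})

test_that("PK derivatives vanish at zero state and conserve mass", {
  p <- default_parameters()
  expect_equal(pk_rhs(rep(0, 5), p$bud), rep(0, 5))
  expect_equal(pk_rhs(rep(0, 5), p$fmt), rep(0, 5))
  # d/dt of (all amounts + eliminated) is zero for any state
  set.seed(2)
  for (k in 1:10) {
    st <- runif(5, 0, 50)
    expect_equal(sum(pk_rhs(st, p$bud)), 0, tolerance = 1e-12)
    expect_equal(sum(pk_rhs(st, p$fmt)), 0, tolerance = 1e-12)
  }
})

test_that("one-compartment bolus matches the analytic exponential", {
  dp <- drug_params("formoterol", FR = 0.5, ka_lung = 1e4, ka_gut = 1e4,
                    Vc = 50, CL = 10, n_cpt = 1)
  # near-instant absorption approximates a central bolus; compare the
  # central amount ODE solution against A0 exp(-CL/Vc t) directly
  rhs <- function(t, y, parms) list(pk_rhs(y, dp))
  tt <- seq(0, 24, by = 0.5)
  sol <- deSolve::lsoda(c(0, 0, 100, 0, 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(sol[, 4], 100 * exp(-10 / 50 * tt), tolerance = 1e-6)
})

test_that("numeric integration matches the closed-form profile to 1e-6", {
  p <- default_parameters()
  sched <- build_schedule(standard_regimen("2bid", duration_weeks = 1))
  sched <- sched[sched$time < 24, ]
  doses <- dose_events(rep(sched$time, each = 2),
                       c("budesonide", "formoterol"), c(320, 9))
  tt <- seq(0.1, 23.9, by = 0.2)
  sol <- solve_individual(p, doses, tt)
  cf_b <- pk_profile(p$bud, sched$time, 320, tt)
  cf_f <- pk_profile(p$fmt, sched$time, 9, tt)
  expect_equal(sol$conc_bud, cf_b$conc, tolerance = 1e-6)
  expect_equal(sol$conc_fmt, cf_f$conc, tolerance = 1e-6)
  # mass balance: total in-system + eliminated equals administered
  n_doses <- sum(tt[length(tt)] >= sched$time)
  expect_equal(sol$abud[length(tt)], 320 * nrow(sched), tolerance = 1e-6)
  expect_equal(sol$afmt[length(tt)], 9 * nrow(sched), tolerance = 1e-6)
})

test_that("without dosing all responses stay at baseline and ACT drifts", {
  p <- default_parameters()
  tt <- c(0, 500, 1000, 2016)
  sol <- solve_individual(p, dose_events(numeric(0), character(0),
                                         numeric(0))[0, ], tt)
  expect_equal(sol$conc_bud, rep(0, 4))
  expect_equal(sol$conc_fmt, rep(0, 4))
  expect_equal(sol$ecp, rep(p$ecp$BASE, 4), tolerance = 1e-8)
  expect_equal(sol$fev1, rep(p$fev1$BASE, 4), tolerance = 1e-8)
  expect_equal(sol$act, 19.7 - 0.00083 * tt, tolerance = 1e-8)
})

test_that("a single formoterol puff leaves a mono-exponential lung depot", {
  p <- default_parameters()
  tt <- seq(0.01, 1, by = 0.01)
  sol <- solve_individual(p, dose_events(0, "formoterol", 9), tt)
  expected <- lung_concentration(3.465 * exp(-14.8 * tt), 1.1, "formoterol")
  expect_equal(sol$clung_fmt, expected, tolerance = 1e-6)
})

test_that("PK is dose-linear", {
  p <- default_parameters()
  tt <- seq(0.25, 36, by = 0.25)
  d1 <- dose_events(c(0, 12, 24), "budesonide", 320)
  d2 <- dose_events(c(0, 12, 24), "budesonide", 640)
  s1 <- solve_individual(p, d1, tt)
  s2 <- solve_individual(p, d2, tt)
  expect_equal(s2$conc_bud, 2 * s1$conc_bud, tolerance = 1e-7)
  expect_equal(s2$clung_bud, 2 * s1$clung_bud, tolerance = 1e-7)
})

test_that("pharmacology is monotone: ECP never above, FEV1 never below baseline", {
  p <- default_parameters()
  sched <- build_schedule(standard_regimen("2bid", duration_weeks = 2))
  doses <- dose_events(rep(sched$time, each = 2),
                       c("budesonide", "formoterol"), c(320, 9))
  sol <- solve_individual(p, doses, seq(0, 336, by = 4))
  expect_true(all(sol$ecp <= p$ecp$BASE + 1e-6))
  expect_true(all(sol$fev1 >= p$fev1$BASE - 1e-6))
})

test_that("12 weeks of 2 puffs b.i.d. raises FEV1 above baseline", {
  p <- default_parameters()
  ind <- data.frame(ID = 1, bud.FR = p$bud$FR, fmt.FR = p$fmt$FR,
                    ecp.BASE = p$ecp$BASE, ecp.kout = p$ecp$kout,
                    fev1.BASE = p$fev1$BASE, fev1.kout = p$fev1$kout)
  sched <- build_schedule(standard_regimen("2bid"))
  pd <- simulate_pd_cohort(p, ind, sched, c(0, 2016))
  expect_gt(pd$fev1[1, 2], p$fev1$BASE)
  expect_lt(pd$ecp[1, 2], p$ecp$BASE)
})

test_that("fast cohort propagation agrees with the adaptive ODE solution", {
  p <- default_parameters()
  ind <- data.frame(ID = 1, bud.FR = p$bud$FR, fmt.FR = p$fmt$FR,
                    ecp.BASE = p$ecp$BASE, ecp.kout = p$ecp$kout,
                    fev1.BASE = p$fev1$BASE, fev1.kout = p$fev1$kout)
  sched <- build_schedule(standard_regimen("2bid", duration_weeks = 4))
  eval_t <- c(0, 168, 672)
  pd <- simulate_pd_cohort(p, ind, sched, eval_t)
  doses <- dose_events(rep(sched$time, each = 2),
                       c("budesonide", "formoterol"), c(320, 9))
  sol <- solve_individual(p, doses, eval_t)
  expect_equal(pd$ecp[1, ], sol$ecp, tolerance = 1e-4)
  expect_equal(pd$fev1[1, ], sol$fev1, tolerance = 1e-4)
})
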