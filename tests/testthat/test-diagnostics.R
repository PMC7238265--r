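test_that("NCA computes Cmax, Tmax and trapezoidal AUClast", {
  r <- nca(c(0, 1, 2), c(0, 2, 1))
  expect_equal(r$cmax, 2)
  expect_equal(r$tmax, 1)
  expect_equal(r$auclast, 2.5)
  # constant profile: AUC = c * T
  r2 <- nca(seq(0, 10, by = 2), rep(3, 6))
  expect_equal(r2$auclast, 30)
  # additivity over contiguous sub-intervals
  tt <- c(0, 0.5, 1, 2, 3, 5, 8)
  cc <- c(0, 4, 3.2, 2, 1.4, 0.6, 0.1)
  whole <- nca(tt, cc)$auclast
  left <- sum(diff(tt[1:4]) * (cc[1:3] + cc[2:4]) / 2)
  right <- sum(diff(tt[4:7]) * (cc[4:6] + cc[5:7]) / 2)
  expect_equal(whole, left + right)
})

test_that("NCA applies the BLQ rules and refuses sparse profiles", {
  expect_error(nca(c(0, 1, 2), c(1, 2, 3), blq = c(TRUE, TRUE, TRUE)),
               "at least 3")
  expect_error(nca(c(0, 1), c(1, 2)), "at least 3")
  # embedded BLQ treated as missing, not zero
  r <- nca(c(0, 1, 2, 3, 4), c(1, 4, 99, 2, 1),
           blq = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(r$cmax, 4)
  expect_equal(r$n_points, 4)
  expect_equal(r$auclast, 0.5 * (1 + 4) + 2 * (4 + 2) / 2 + 0.5 * (2 + 1))
})

test_that("Day-1 NCA summary sits on the model's concentration scale", {
  d <- generate_trial(trial_design(n_subjects = 20), default_parameters(),
                      default_population(), seed = 31)
  s <- nca_day1(d, "budesonide")
  expect_true(all(c("Cmax", "AUClast") %in% s$summary$metric))
  # typical-value profile peaks around 0.7 ng/mL; population means with
  # 64% residual error should stay on that order of magnitude
  cmax <- s$summary$mean[s$summary$metric == "Cmax"]
  expect_gt(cmax, 0.2)
  expect_lt(cmax, 5)
})

test_that("VPC with all variability off collapses onto the typical curve", {
  p <- default_parameters()
  times <- c(0.5, 1, 2, 4, 8)
  typ <- pk_profile(p$bud, 0, 320, times)$conc
  observed <- data.frame(time = rep(times, 3), value = rep(typ, 3))
  sim0 <- function(r) observed
  v <- vpc(observed, sim0, n_rep = 10, seed = 1)
  expect_equal(v$observed, rep(typ, each = 3))
  expect_equal(v$lo, v$hi)
  expect_equal(v$mid, rep(typ, each = 3))
})

test_that("VPC bands are reproducible and cover self-simulated data", {
  p <- default_parameters()
  pop <- default_population()
  times <- c(0.5, 1, 2, 4, 8)
  sim_design <- function(seed) {
    set.seed(seed)
    ind <- sample_population(p, pop, 40)
    val <- unlist(lapply(seq_len(40), function(i) {
      dp <- p$bud
      dp$Vc <- ind$bud.Vc[i]
      dp$FR <- ind$bud.FR[i]
      f <- pk_profile(dp, 0, 320, times)$conc
      f * (1 + rnorm(length(f), 0, pop$residual$conc_BUD$prop))
    }))
    data.frame(time = rep(times, 40), value = val)
  }
  observed <- sim_design(999)
  simulate <- function(r) sim_design(1000 + r)
  v1 <- vpc(observed, simulate, n_rep = 60, seed = 5)
  v2 <- vpc(observed, simulate, n_rep = 60, seed = 5)
  expect_identical(v1, v2)
  inside <- v1$observed >= v1$lo & v1$observed <= v1$hi
  expect_gte(mean(inside), 0.9)
})

test_that("empty VPC bins merge into a neighbour", {
  observed <- data.frame(time = c(1, 1, 2, 2), value = c(1, 2, 3, 4))
  expect_message(
    v <- vpc(observed, function(r) observed, n_rep = 5,
             bins = c(1, 2, 10), seed = 1),
    "merged")
  expect_true(all(v$bin %in% c(1, 2)))
})

test_that("bootstrap intervals behave at the degenerate corners", {
  subs <- sim_toy_iv(12, omega = c(V = 0.2), sigma = 0.3, seed = 40)
  m <- toy_iv_model(omega = c(V = 0.2), sigma = list(prop = 0, add = 0.3))
  set.seed(1)
  fit <- fit_population(m, subs, fixed = c("omega.V", "sigma.add"),
                        n_starts = 1, se = FALSE)
  # single refit replicate: interval degenerates to that replicate
  b1 <- bootstrap_fit(fit, subs, n_boot = 1, mode = "refit", seed = 2)
  expect_equal(b1$ci$p5, b1$ci$p95)
  # linearized mode is seed-reproducible and brackets the point estimate
  b2 <- bootstrap_fit(fit, subs, n_boot = 200, mode = "linearized", seed = 3)
  b3 <- bootstrap_fit(fit, subs, n_boot = 200, mode = "linearized", seed = 3)
  expect_identical(b2$ci, b3$ci)
  expect_true(all(b2$ci$p5 <= c(fit$theta[["V"]], fit$theta[["CL"]]) + 1e-8))
  expect_true(all(b2$ci$p95 >= c(fit$theta[["V"]], fit$theta[["CL"]]) - 1e-8))
  # cloned identical subjects carry no between-subject information
  clones <- rep(subs[1], 12)
  set.seed(1)
  fitc <- fit_population(m, clones, fixed = c("omega.V", "sigma.add"),
                         n_starts = 1, se = FALSE)
  bc <- bootstrap_fit(fitc, clones, n_boot = 50, mode = "linearized", seed = 4)
  expect_true(all(abs(bc$ci$p95 - bc$ci$p5) < 1e-6 * abs(bc$ci$p50)))
})

test_that("linearized bootstrap intervals cover generating values on a toy", {
  subs <- sim_toy_iv(40, omega = c(V = 0.2), sigma = 0.3, seed = 41)
  m <- toy_iv_model(omega = c(V = 0.2), sigma = list(prop = 0, add = 0.3))
  set.seed(1)
  fit <- fit_population(m, subs, fixed = c("omega.V", "sigma.add"),
                        n_starts = 1, se = FALSE)
  b <- bootstrap_fit(fit, subs, n_boot = 400, mode = "linearized", seed = 6)
  truth <- c(V = 20, CL = 5)
  for (k in 1:2) {
    expect_gt(truth[k], b$ci$p5[k] * 0.98)
    expect_lt(truth[k], b$ci$p95[k] * 1.02)
  }
})
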