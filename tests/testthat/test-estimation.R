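test_that("with all IIV zero the objective is the exact Gaussian -2 log-likelihood", {
  subs <- sim_toy_iv(3, seed = 10)
  m0 <- toy_iv_model(omega = c(V = 0))
  r0 <- focei_ofv(m0, subs)
  exact <- 0
  for (sub in subs) {
    f <- 100 / 20 * exp(-5 / 20 * sub$times)
    exact <- exact - 2 * sum(dnorm(sub$dv, f, 0.5, log = TRUE))
  }
  expect_equal(r0$ofv, exact, tolerance = 1e-10)
})

test_that("Laplace marginal likelihood matches adaptive quadrature on a toy", {
  subs <- sim_toy_iv(1, seed = 10)
  m <- toy_iv_model()
  lap <- focei_ofv(m, subs)
  sub <- subs[[1]]
  integrand <- Vectorize(function(eta) {
    V <- 20 * exp(eta)
    f <- 100 / V * exp(-5 / V * sub$times)
    exp(sum(dnorm(sub$dv, f, 0.5, log = TRUE))) * dnorm(eta, 0, 0.3)
  })
  quad <- -2 * log(integrate(integrand, -2.5, 2.5, rel.tol = 1e-12)$value)
  expect_lt(abs(lap$ofv - quad), 0.01)
})

test_that("objective is invariant to subject order and row shuffles", {
  subs <- sim_toy_iv(6, seed = 2)
  m <- toy_iv_model()
  a <- focei_ofv(m, subs)$ofv
  b <- focei_ofv(m, rev(subs))$ofv
  expect_equal(a, b, tolerance = 1e-10)
  shuffled <- lapply(subs, function(s) {
    ix <- sample(seq_along(s$times))
    s$times <- s$times[ix]
    s$dv <- s$dv[ix]
    s
  })
  expect_equal(focei_ofv(m, shuffled)$ofv, a, tolerance = 1e-10)
})

test_that("fit recovers toy parameters and never worsens a start at the truth", {
  subs <- sim_toy_iv(40, times = c(0.25, 0.5, 1, 2, 4, 8, 12),
                     omega = c(V = 0.1), sigma = 0.1, seed = 30)
  m <- toy_iv_model(theta = c(V = 15, CL = 7), omega = c(V = 0.1),
                    sigma = list(prop = 0, add = 0.1))
  set.seed(1)
  f <- fit_population(m, subs, fixed = c("omega.V", "sigma.add"),
                      n_starts = 1, se = TRUE)
  expect_true(f$convergence)
  expect_lt(abs(f$theta[["V"]] - 20) / 20, 0.1)
  expect_lt(abs(f$theta[["CL"]] - 5) / 5, 0.1)
  expect_true(all(is.finite(f$rse_percent)))
  # restarting from the fitted optimum cannot increase the objective
  m2 <- toy_iv_model(theta = f$theta, omega = f$omega, sigma = f$sigma)
  set.seed(1)
  f2 <- fit_population(m2, subs, fixed = c("omega.V", "sigma.add"),
                       n_starts = 1, se = FALSE)
  expect_lte(f2$ofv, f$ofv + 1e-6)
})

test_that("fixing every parameter returns the initial values with an OFV", {
  subs <- sim_toy_iv(4, seed = 3)
  m <- toy_iv_model()
  f <- fit_population(m, subs,
                      fixed = c("V", "CL", "omega.V", "sigma.add"))
  expect_equal(f$theta, c(V = 20, CL = 5))
  expect_equal(f$ofv, focei_ofv(m, subs)$ofv)
  expect_true(f$convergence)
})

test_that("likelihood-ratio p-values hit the conventional thresholds", {
  # thresholds quoted to printed precision: 3.84 <-> p = 0.050, 6.64 <-> 0.010
  expect_equal(round(lrt(list(ofv = 103.84), list(ofv = 100), 1)$p, 3), 0.050)
  expect_equal(round(lrt(list(ofv = 106.64), list(ofv = 100), 1)$p, 3), 0.010)
  expect_equal(lrt(list(ofv = 100), list(ofv = 100), 1)$p, 1)
  expect_warning(lrt(list(ofv = 99), list(ofv = 100), 1), "higher OFV")
})

test_that("a pure-noise covariate rarely clears the inclusion threshold", {
  n_rep <- 60
  incl <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    subs <- sim_toy_flat(24, n_obs = 3, omega = 0.05, seed = 5000 + r)
    base <- toy_flat_model(omega = c(E0 = 0.05))
    f0 <- fit_population(base, subs, fixed = c("omega.E0", "sigma.add"),
                         n_starts = 1, se = FALSE)
    m1 <- add_relation(base, weight_candidate)
    f1 <- fit_population(m1, subs, fixed = c("omega.E0", "sigma.add"),
                         n_starts = 1, se = FALSE)
    incl[r] <- (f0$ofv - f1$ofv) >= 3.84
  }
  expect_gte(mean(!incl), 0.93)
})

test_that("stepwise covariate modeling handles empty pools and planted effects", {
  subs <- sim_toy_flat(12, weight_coef = 0.03, seed = 7001)
  base <- toy_flat_model()
  # empty pool: base returned untouched, empty trace
  res0 <- scm(base, subs, list(), fixed = c("omega.E0", "sigma.add"),
              n_starts = 1)
  expect_length(res0$model$relations, 0)
  expect_equal(nrow(res0$trace), 0)
  # a strong planted weight effect is included and survives backward
  res <- scm(base, subs, list(weight_candidate),
             fixed = c("omega.E0", "sigma.add"), n_starts = 1)
  expect_length(res$model$relations, 1)
  expect_equal(res$model$relations[[1]]$covariate, "weight")
  expect_true(any(res$trace$phase == "backward" &
                    res$trace$decision == "retained"))
  expect_gt(res$fit$theta[["beta.E0.weight"]], 0)
})

test_that("structure comparison picks the generating compartment count", {
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  # data from one-compartment kinetics
  subs1 <- sim_pk_subs(12, times, n_cpt = 1, seed = 21)
  set.seed(1)
  cs1 <- compare_structures(pk_toy_model(1), pk_toy_model(2), subs1,
                            fixed = pk_toy_fixed, n_starts = 1)
  expect_equal(cs1$n_cpt, 1L)
  # data with a pronounced distribution phase
  subs2 <- sim_pk_subs(12, times, n_cpt = 2, Q = 30, Vp = 200, seed = 22)
  set.seed(1)
  cs2 <- compare_structures(pk_toy_model(1), pk_toy_model(2), subs2,
                            fixed = pk_toy_fixed, n_starts = 1)
  expect_equal(cs2$n_cpt, 2L)
  expect_gte(cs2$delta_ofv, stats::qchisq(0.95, 2))
  # identical objective values (degenerate tie) prefer the simpler model
  cs3 <- compare_structures(pk_toy_model(1), pk_toy_model(1), subs1,
                            fixed = pk_toy_fixed, n_starts = 1)
  expect_equal(cs3$n_cpt, 1L)
})
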