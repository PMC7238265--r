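# Small models and simulators shared across tests.

# One-compartment IV-bolus model: conc = dose / V * exp(-CL/V * t), additive
# residual error, exponential IIV on V. Subjects are prepared structures
# (times, dv, cov) consumed directly by focei_ofv / fit_population.
toy_iv_model <- function(theta = c(V = 20, CL = 5), omega = c(V = 0.3),
                         sigma = list(prop = 0, add = 0.5), dose = 100,
                         relations = list()) {
  nlme_model(
    predict = function(p, sub) dose / p$V * exp(-p$CL / p$V * sub$times),
    theta = theta, omega = omega, sigma = sigma,
    prepare = identity, relations = relations
  )
}

sim_toy_iv <- function(n, times = c(0.25, 0.5, 1, 2, 4, 8),
                       theta = c(V = 20, CL = 5), omega = c(V = 0.3),
                       sigma = 0.5, dose = 100, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    V <- theta[["V"]] * exp(rnorm(1, 0, omega[["V"]]))
    f <- dose / V * exp(-theta[["CL"]] / V * times)
    list(id = i, times = times, dv = f + rnorm(length(times), 0, sigma),
         doses = NULL, cov = list())
  })
}

# Flat baseline model: y_ij = E0_i + eps, with an optional linear weight
# effect on E0. Used for LRT calibration and SCM behaviour studies.
toy_flat_model <- function(theta = c(E0 = 10), omega = c(E0 = 0.2),
                           sigma_add = 1) {
  nlme_model(
    predict = function(p, sub) rep(p$E0, length(sub$times)),
    theta = theta, omega = omega,
    sigma = list(prop = 0, add = sigma_add),
    prepare = identity
  )
}

sim_toy_flat <- function(n, n_obs = 2, E0 = 10, omega = 0.2, sigma = 1,
                         weight_coef = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    wt <- rnorm(1, 70, 12)
    mu <- E0 * (1 + weight_coef * (wt - 70)) * exp(rnorm(1, 0, omega))
    list(id = i, times = seq_len(n_obs), dv = mu + rnorm(n_obs, 0, sigma),
         doses = NULL, cov = list(weight = wt))
  })
}

weight_candidate <- list(parameter = "E0", covariate = "weight",
                         relation = "linear", ref = 70, init = 0)

# Population spec with every variance term switched off.
zero_population <- function() {
  pop <- default_population()
  pop$iiv[] <- 0
  for (ep in names(pop$residual)) {
    pop$residual[[ep]]$prop <- 0
    pop$residual[[ep]]$add <- 0
  }
  pop
}
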