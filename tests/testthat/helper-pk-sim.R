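# Prepared-subject PK simulator for structural-comparison tests: single
# inhaled dose at t = 0, proportional residual error, exponential IIV on Vc.
sim_pk_subs <- function(n, times, Vc = 20, CL = 10, Q = NULL, Vp = NULL,
                        n_cpt = 1, ka_lung = 15, ka_gut = 0.05, FR = 0.5,
                        dose = 100, omega_Vc = 0.2, sigma_prop = 0.15,
                        seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dp <- drug_params("budesonide", FR = FR, ka_lung = ka_lung,
                      ka_gut = ka_gut, Vc = Vc * exp(rnorm(1, 0, omega_Vc)),
                      CL = CL, Q = Q, Vp = Vp, n_cpt = n_cpt)
    f <- pk_profile(dp, 0, dose, times)$conc
    list(id = i, times = times, dv = f * (1 + rnorm(length(f), 0, sigma_prop)),
         doses = data.frame(time = 0, amt = dose), cov = list())
  })
}

pk_toy_model <- function(n_cpt, Vc = 20, CL = 10, Q = 30, Vp = 100,
                         omega_Vc = 0.2, sigma_prop = 0.15) {
  init <- if (n_cpt == 2) {
    drug_params("budesonide", FR = 0.5, ka_lung = 15, ka_gut = 0.05,
                Vc = Vc, CL = CL, Q = Q, Vp = Vp, n_cpt = 2)
  } else {
    drug_params("budesonide", FR = 0.5, ka_lung = 15, ka_gut = 0.05,
                Vc = Vc, CL = CL, n_cpt = 1)
  }
  pk_fit_model(init, omega = c(Vc = omega_Vc),
               sigma = list(prop = sigma_prop, add = 0))
}

pk_toy_fixed <- c("ka_lung", "ka_gut", "FR", "omega.Vc", "sigma.prop")
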