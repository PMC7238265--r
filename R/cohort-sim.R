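#' Fast cohort simulation of the turnover PD states
#'
#' Propagates the sputum-ECP and FEV1 turnover states for a whole cohort at
#' once, exploiting the model's structure: the lung amount of each drug is an
#' exact mono-exponential between dose events, and the fractional
#' concentration-effect term integrates in closed form over any interval
#' (`int C/(C50+C) dt = log((C50 + C1)/(C50 + C2)) / ka`). Each scalar
#' turnover ODE, linear in R, is advanced with an exponential integrator
#' using the exact interval-average of its forcing; short sub-steps after
#' every dose resolve the fast absorption transient. Accuracy against the
#' full adaptive ODE solution is at the 1e-5 relative level (see tests)
#' while remaining O(n) in the cohort size.
#'
#' Evaluations at a time that coincides with a dose event are made pre-dose
#' (trough convention), so an evaluation at t = 0 sees the untreated state.
#'
#' @param params Typical-value [parameter_set()] (provides ka, V_lung, C50,
#'   Imax/Emax shared by the cohort).
#' @param ind Data frame from [sample_population()] with per-subject
#'   `bud.FR`, `fmt.FR`, `ecp.BASE`, `ecp.kout`, `fev1.BASE`, `fev1.kout`.
#' @param schedule Data frame `time`, `bud`, `fmt`: total inhaled ug of each
#'   drug at each administration time.
#' @param eval_times Times (h) at which the states are recorded.
#' @return List of matrices `ecp`, `fev1` (subjects x eval_times).
#' @export
simulate_pd_cohort <- function(params, ind, schedule, eval_times) {
  stopifnot(inherits(params, "parameter_set"), all(eval_times >= 0))
  n <- nrow(ind)
  eval_times <- sort(unique(eval_times))
  bounds <- sort(unique(c(0, schedule$time, eval_times)))
  # sub-step offsets resolving the absorption transient after each boundary
  offsets <- c(0.02, 0.06, 0.15, 0.4, 1, 2.5, 6)

  ka_b <- params$bud$ka_lung; ka_f <- params$fmt$ka_lung
  Vl <- params$ecp$V_lung
  uf_b <- conc_unit_factor("budesonide"); uf_f <- conc_unit_factor("formoterol")
  c50_e <- params$ecp$C50; c50_f <- params$fev1$C50
  imax <- params$ecp$emax; emax <- params$fev1$emax
  kout_e <- ind$ecp.kout; kin_e <- ind$ecp.kout * ind$ecp.BASE
  kout_f <- ind$fev1.kout; kin_f <- ind$fev1.kout * ind$fev1.BASE

  A_b <- numeric(n); A_f <- numeric(n)
  R_e <- ind$ecp.BASE; R_f <- ind$fev1.BASE
  ecp_out <- matrix(NA_real_, n, length(eval_times))
  fev1_out <- matrix(NA_real_, n, length(eval_times))

  dose_at <- function(t) {
    i <- which(schedule$time == t)
    if (length(i) == 0) NULL else schedule[i, , drop = FALSE]
  }

  step <- function(h) {
    # budesonide inhibition of ECP production
    C1b <- A_b / Vl * uf_b
    C2b <- C1b * exp(-ka_b * h)
    int_b <- log((c50_e + C1b) / (c50_e + C2b)) / ka_b
    abar_e <- kin_e * (1 - imax * int_b / h)
    dec_e <- exp(-kout_e * h)
    R_e <<- R_e * dec_e + abar_e / kout_e * (1 - dec_e)
    # formoterol stimulation of FEV1 production
    C1f <- A_f / Vl * uf_f
    C2f <- C1f * exp(-ka_f * h)
    int_f <- log((c50_f + C1f) / (c50_f + C2f)) / ka_f
    abar_f <- kin_f * (1 + emax * int_f / h)
    dec_f <- exp(-kout_f * h)
    R_f <<- R_f * dec_f + abar_f / kout_f * (1 - dec_f)
    A_b <<- A_b * exp(-ka_b * h)
    A_f <<- A_f * exp(-ka_f * h)
  }

  for (k in seq_along(bounds)) {
    t1 <- bounds[k]
    # record any evaluation at this boundary before applying a dose
    ei <- match(t1, eval_times)
    if (!is.na(ei)) {
      ecp_out[, ei] <- R_e
      fev1_out[, ei] <- R_f
    }
    d <- dose_at(t1)
    if (!is.null(d)) {
      if (sum(d$bud) > 0) A_b <- A_b + ind$bud.FR * sum(d$bud)
      if (sum(d$fmt) > 0) A_f <- A_f + ind$fmt.FR * sum(d$fmt)
    }
    if (k == length(bounds)) break
    t2 <- bounds[k + 1]
    cuts <- unique(c(t1 + offsets[t1 + offsets < t2], t2))
    prev <- t1
    for (tc in cuts) {
      step(tc - prev)
      prev <- tc
    }
  }
  list(ecp = ecp_out, fev1 = fev1_out, eval_times = eval_times)
}
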