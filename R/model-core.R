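#' Split an inhaled dose between lung and gut
#'
#' A fraction `FR` of every inhaled dose deposits in the lung; the swallowed
#' remainder enters the gut. Mass is conserved exactly.
#'
#' @param dose Dose amount (ug), positive.
#' @param FR Fraction deposited in the lung, strictly inside (0, 1).
#' @return Named numeric vector `c(lung = , gut = )` in ug.
#' @export
#' @examples
#' split_dose(320, 0.38)   # 121.6 ug to lung, 198.4 ug to gut
split_dose <- function(dose, FR) {
  if (!is.numeric(dose) || any(dose <= 0)) stop("dose must be positive")
  if (!is.numeric(FR) || any(FR <= 0) || any(FR >= 1)) {
    stop("FR must lie strictly inside (0, 1)")
  }
  c(lung = FR * dose, gut = (1 - FR) * dose)
}

#' Lung concentration from lung amount
#'
#' Divides the amount of drug in the lung compartment by the lung volume
#' (typical value 1.1 L) and converts to the drug's concentration unit:
#' ng/mL for budesonide, pg/mL for formoterol. This concentration is the
#' driver of the indirect-response PD models.
#'
#' @param amount_lung Amount in the lung compartment (ug), non-negative.
#' @param V_lung Lung volume (L), positive.
#' @param drug_id `"budesonide"` or `"formoterol"`.
#' @return Concentration in the drug's unit.
#' @export
#' @examples
#' lung_concentration(121.6, 1.1, "budesonide")   # 110.55 ng/mL
#' lung_concentration(3.465, 1.1, "formoterol")   # 3150 pg/mL
lung_concentration <- function(amount_lung, V_lung = 1.1, drug_id) {
  if (any(amount_lung < 0)) stop("amount_lung must be non-negative")
  if (V_lung <= 0) stop("V_lung must be positive")
  amount_lung / V_lung * conc_unit_factor(drug_id)
}

#' Fractional concentration-effect term
#'
#' Hill-type (Emax with slope 1) fractional effect C / (C50 + C), used both
#' for inhibition and stimulation of the production rate.
#' @keywords internal
effect_fraction <- function(C, C50) C / (C50 + C)

#' Turnover derivative for sputum ECP
#'
#' dR/dt = kin * (1 - Imax * C / (IC50 + C)) - kout * R, with the production
#' rate kin = kout * BASE fixed by baseline stationarity and C the budesonide
#' lung concentration (ng/mL).
#'
#' @param R Current sputum ECP (ng/mL), non-negative.
#' @param C_lung_bud Budesonide lung concentration (ng/mL), non-negative.
#' @param p [turnover_params()] with `mode = "inhibit_kin"`.
#' @return dR/dt (ng/mL per h).
#' @export
ecp_rhs <- function(R, C_lung_bud, p) {
  stopifnot(inherits(p, "turnover_params"), p$mode == "inhibit_kin")
  p$kin * (1 - p$emax * effect_fraction(C_lung_bud, p$C50)) - p$kout * R
}

#' Turnover derivative for FEV1
#'
#' dR/dt = kin * (1 + Emax * C / (EC50 + C)) - kout * R, with
#' kin = kout * BASE and C the formoterol lung concentration (pg/mL).
#'
#' @param R Current FEV1 (% predicted), positive.
#' @param C_lung_fmt Formoterol lung concentration (pg/mL), non-negative.
#' @param p [turnover_params()] with `mode = "stimulate_kin"`.
#' @return dR/dt (percentage points per h).
#' @export
fev1_rhs <- function(R, C_lung_fmt, p) {
  stopifnot(inherits(p, "turnover_params"), p$mode == "stimulate_kin")
  p$kin * (1 + p$emax * effect_fraction(C_lung_fmt, p$C50)) - p$kout * R
}

#' ACT score from the disease-progression model
#'
#' Computes the clinical-outcome equation pointwise: the baseline score
#' drifts at the natural progression rate while reversible biomarker
#' changes (ECP suppression, FEV1 gain) add offsets.
#'
#' @param t Time since treatment start (h), non-negative.
#' @param R_ECP Current sputum ECP (ng/mL).
#' @param R_FEV1 Current FEV1 (% predicted).
#' @param BASE_ECP,BASE_FEV1 Individual baselines for the two markers.
#' @param p [co_params()].
#' @return ACT score (unbounded unless `p$clip`).
#' @export
#' @examples
#' p <- default_parameters()
#' act_score(0, 19.7, 85.8, 19.7, 85.8, p$co)  # baseline: 19.7
act_score <- function(t, R_ECP, R_FEV1, BASE_ECP, BASE_FEV1, p) {
  stopifnot(inherits(p, "co_params"), all(t >= 0))
  score <- p$BASE_ACT - p$alpha * t +
    p$beta1 * (BASE_ECP - R_ECP) + p$beta2 * (R_FEV1 - BASE_FEV1)
  if (p$clip) score <- pmin(25, pmax(5, score))
  score
}

# ---- closed-form PK -------------------------------------------------------

#' Disposition exponents and unit-input coefficients
#'
#' For a linear 1- or 2-compartment model with first-order input at rate
#' `ka`, the central concentration after a unit depot dose is a sum of
#' exponentials sum(coef_j * exp(-rate_j * t)). Used for superposition over
#' dose events.
#' @noRd
input_exponentials <- function(dp, ka) {
  k10 <- dp$CL / dp$Vc
  if (dp$n_cpt == 1L) {
    lam <- k10
    if (abs(ka - lam) < 1e-10 * max(ka, lam)) ka <- ka * (1 + 1e-8)
    co <- ka / (ka - lam) / dp$Vc
    list(rates = c(lam, ka), coefs = c(co, -co))
  } else {
    k12 <- dp$Q / dp$Vc
    k21 <- dp$Q / dp$Vp
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    l1 <- (s + disc) / 2
    l2 <- (s - disc) / 2
    for (l in c(l1, l2)) {
      if (abs(ka - l) < 1e-10 * max(ka, l)) ka <- ka * (1 + 1e-8)
    }
    c1 <- ka * (k21 - l1) / ((ka - l1) * (l2 - l1)) / dp$Vc
    c2 <- ka * (k21 - l2) / ((ka - l2) * (l1 - l2)) / dp$Vc
    c3 <- ka * (k21 - ka) / ((l1 - ka) * (l2 - ka)) / dp$Vc
    list(rates = c(l1, l2, ka), coefs = c(c1, c2, c3))
  }
}

#' Closed-form plasma and lung profiles for one drug
#'
#' Superposes the analytic solution of the linear absorption/disposition
#' system over a sequence of inhaled dose events. Plasma concentration is
#' `A_central / Vc` converted to the drug's reporting unit; lung amount
#' decays mono-exponentially from each deposited fraction.
#'
#' @param dp [drug_params()].
#' @param dose_times Times of inhaled doses (h).
#' @param dose_amounts Total inhaled amounts (ug), recycled against
#'   `dose_times`.
#' @param times Output time grid (h).
#' @return `data.frame(time, conc, amount_lung, conc_lung)` with `conc` in
#'   the drug's plasma unit and `conc_lung` in its PD-driver unit.
#' @export
pk_profile <- function(dp, dose_times, dose_amounts, times) {
  stopifnot(inherits(dp, "drug_params"))
  dose_amounts <- rep_len(dose_amounts, length(dose_times))
  conc <- numeric(length(times))
  a_lung <- numeric(length(times))
  bases <- list(lung = input_exponentials(dp, dp$ka_lung),
                gut = input_exponentials(dp, dp$ka_gut))
  for (i in seq_along(dose_times)) {
    td <- dose_times[i]
    amt <- split_dose(dose_amounts[i], dp$FR)
    on <- times >= td
    if (!any(on)) next
    dt <- times[on] - td
    contrib <- numeric(sum(on))
    for (depot in c("lung", "gut")) {
      b <- bases[[depot]]
      for (j in seq_along(b$rates)) {
        contrib <- contrib + amt[[depot]] * b$coefs[j] * exp(-b$rates[j] * dt)
      }
    }
    conc[on] <- conc[on] + contrib
    a_lung[on] <- a_lung[on] + amt[["lung"]] * exp(-dp$ka_lung * dt)
  }
  uf <- conc_unit_factor(dp$drug_id)
  data.frame(time = times, conc = conc * uf, amount_lung = a_lung,
             conc_lung = lung_concentration(a_lung, drug_id = dp$drug_id))
}

# ---- ODE right-hand sides -------------------------------------------------

#' PK derivatives for one drug
#'
#' State order: lung, gut, central, peripheral, cumulative eliminated
#' (all ug). The eliminated state closes the mass balance. One-compartment
#' models carry a dormant peripheral state (derivative zero).
#'
#' @param state Numeric state vector of length 5.
#' @param dp [drug_params()].
#' @return Derivative vector (ug/h).
#' @export
pk_rhs <- function(state, dp) {
  stopifnot(inherits(dp, "drug_params"), length(state) == 5)
  a_lung <- state[1]; a_gut <- state[2]; a_c <- state[3]; a_p <- state[4]
  d_lung <- -dp$ka_lung * a_lung
  d_gut <- -dp$ka_gut * a_gut
  d_c <- dp$ka_lung * a_lung + dp$ka_gut * a_gut - (dp$CL / dp$Vc) * a_c
  d_p <- 0
  if (dp$n_cpt == 2L) {
    d_c <- d_c - (dp$Q / dp$Vc) * a_c + (dp$Q / dp$Vp) * a_p
    d_p <- (dp$Q / dp$Vc) * a_c - (dp$Q / dp$Vp) * a_p
  }
  d_elim <- (dp$CL / dp$Vc) * a_c
  c(d_lung, d_gut, d_c, d_p, d_elim)
}

#' Dose event list
#'
#' @param time Event times (h), non-negative.
#' @param drug_id `"budesonide"` or `"formoterol"`, recycled.
#' @param amount Inhaled amounts (ug), positive, recycled.
#' @return `data.frame(time, drug_id, amount, route)`.
#' @export
dose_events <- function(time, drug_id, amount) {
  n <- max(length(time), length(drug_id), length(amount))
  time <- rep_len(time, n); amount <- rep_len(amount, n)
  drug_id <- rep_len(drug_id, n)
  stopifnot(all(time >= 0), all(amount > 0),
            all(drug_id %in% c("budesonide", "formoterol")))
  data.frame(time = time, drug_id = drug_id, amount = amount,
             route = rep("inhaled", n), stringsAsFactors = FALSE)
}

#' Solve the full individual PK/PD/CO system
#'
#' Integrates both drugs' PK (lung/gut/central/peripheral/eliminated), the
#' two turnover states, and evaluates the ACT equation pointwise on the
#' requested grid. Dose events are handled by instantaneous additions to the
#' lung and gut depots at the event times (integration restarts, no impulse
#' smoothing); the PD states are continuous across events. Uses a stiff-safe
#' adaptive integrator (`deSolve::lsoda`) with rtol 1e-8 / atol 1e-10.
#'
#' @param params [parameter_set()].
#' @param doses [dose_events()] data frame (possibly zero rows).
#' @param times Sorted output grid (h) starting at or after 0.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `time`, `conc_bud` (ng/mL), `conc_fmt`
#'   (pg/mL), `clung_bud` (ng/mL), `clung_fmt` (pg/mL), `ecp` (ng/mL),
#'   `fev1` (%), `act`, plus total amount columns `abud`, `afmt` (ug) used
#'   for mass-balance checks.
#' @export
solve_individual <- function(params, doses, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "parameter_set"), !is.unsorted(times),
            all(times >= 0))
  if (nrow(doses) > 0 && max(doses$time) > max(times)) {
    stop("dose events extend beyond the output horizon")
  }
  # state: bud[lung,gut,c,p,elim], fmt[lung,gut,c,p,elim], ecp, fev1
  y0 <- c(rep(0, 10), params$ecp$BASE, params$fev1$BASE)
  nms <- c(paste0("b", 1:5), paste0("f", 1:5), "ecp", "fev1")
  names(y0) <- nms
  rhs <- function(t, y, parms) {
    db <- pk_rhs(y[1:5], params$bud)
    df <- pk_rhs(y[6:10], params$fmt)
    cb <- lung_concentration(max(y[1], 0), params$ecp$V_lung, "budesonide")
    cf <- lung_concentration(max(y[6], 0), params$fev1$V_lung, "formoterol")
    list(c(db, df,
           ecp_rhs(y[11], cb, params$ecp),
           fev1_rhs(y[12], cf, params$fev1)))
  }
  ev <- NULL
  if (nrow(doses) > 0) {
    ev_rows <- do.call(rbind, lapply(seq_len(nrow(doses)), function(i) {
      dp <- if (doses$drug_id[i] == "budesonide") params$bud else params$fmt
      amt <- split_dose(doses$amount[i], dp$FR)
      pre <- if (doses$drug_id[i] == "budesonide") "b" else "f"
      data.frame(var = paste0(pre, 1:2), time = doses$time[i],
                 value = as.numeric(amt), method = "add")
    }))
    ev <- ev_rows[order(ev_rows$time), ]
  }
  grid <- sort(unique(c(times, if (!is.null(ev)) ev$time)))
  sol <- try(deSolve::lsoda(y0, grid, rhs, parms = NULL, rtol = rtol,
                            atol = atol,
                            events = if (is.null(ev)) NULL else list(data = ev)),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(grid)) {
    bad_t <- if (inherits(sol, "try-error")) NA_real_ else grid[nrow(sol) + 1]
    stop("integrator failure near t = ", bad_t, " h")
  }
  sol <- as.data.frame(sol)
  sol <- sol[sol$time %in% times, ]
  ufb <- conc_unit_factor("budesonide")
  uff <- conc_unit_factor("formoterol")
  out <- data.frame(
    time = sol$time,
    conc_bud = sol$b3 / params$bud$Vc * ufb,
    conc_fmt = sol$f3 / params$fmt$Vc * uff,
    clung_bud = lung_concentration(pmax(sol$b1, 0), params$ecp$V_lung,
                                   "budesonide"),
    clung_fmt = lung_concentration(pmax(sol$f1, 0), params$fev1$V_lung,
                                   "formoterol"),
    ecp = sol$ecp,
    fev1 = sol$fev1,
    abud = sol$b1 + sol$b2 + sol$b3 + sol$b4 + sol$b5,
    afmt = sol$f1 + sol$f2 + sol$f3 + sol$f4 + sol$f5
  )
  out$act <- act_score(out$time, out$ecp, out$fev1,
                       params$ecp$BASE, params$fev1$BASE, params$co)
  rownames(out) <- NULL
  out
}
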