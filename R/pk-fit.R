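#' Closed-form central concentration for fitting
#'
#' Lean superposition evaluator used inside the estimation inner loops:
#' takes a plain parameter list (fields `FR`, `ka_lung`, `ka_gut`, `Vc`,
#' `CL`, and `Q`/`Vp` when `n_cpt = 2`) and returns the plasma
#' concentration in the drug's reporting unit. Invalid parameter regions
#' explored by the optimizer yield non-finite values rather than errors.
#' @keywords internal
pk_conc <- function(p, n_cpt, drug_id, dose_times, dose_amts, times) {
  if (any(!is.finite(unlist(p, use.names = FALSE))) ||
      p$Vc <= 0 || p$CL <= 0 || p$FR <= 0 || p$FR >= 1) {
    return(rep(NaN, length(times)))
  }
  dp <- list(Vc = p$Vc, CL = p$CL, Q = p$Q, Vp = p$Vp, n_cpt = n_cpt)
  bl <- input_exponentials(dp, p$ka_lung)
  bg <- input_exponentials(dp, p$ka_gut)
  # superposition, vectorized over the times x doses grid
  dt <- outer(times, dose_times, `-`)
  on <- dt >= 0
  dt[!on] <- 0
  conc <- numeric(length(times))
  for (j in seq_along(bl$rates)) {
    conc <- conc + bl$coefs[j] * ((exp(-bl$rates[j] * dt) * on) %*%
                                    (p$FR * dose_amts))
  }
  for (j in seq_along(bg$rates)) {
    conc <- conc + bg$coefs[j] * ((exp(-bg$rates[j] * dt) * on) %*%
                                    ((1 - p$FR) * dose_amts))
  }
  as.vector(conc) * conc_unit_factor(drug_id)
}

#' Population PK model for one inhaled drug
#'
#' Builds an [nlme_model()] whose prediction is the closed-form plasma
#' concentration of the drug under its subject's dose history. Theta holds
#' the structural parameters (`Vc`, `CL`, `ka_lung`, `ka_gut`, `FR`, plus
#' `Q`/`Vp` for two-compartment disposition); which of them are estimated
#' is decided at fit time through the `fixed` argument of
#' [fit_population()]. BLQ observations are excluded by the prepare step
#' (M1).
#'
#' @param init [drug_params()] initial values.
#' @param omega Named IIV SD vector (names among theta).
#' @param sigma Residual model, e.g. `list(prop = 0.64, add = 0)`.
#' @param n_cpt Disposition structure; defaults to `init$n_cpt`. May be set
#'   to 1 on a two-compartment `init` to build the reduced structural
#'   variant (the `Q`/`Vp` entries are then dropped).
#' @param blq BLQ handling: `"M1"` (default) drops censored observations;
#'   `"M3"` keeps them as left-censored likelihood contributions at the
#'   drug's LLOQ, which removes the downward bias M1 induces when the
#'   censored fraction is large (formoterol).
#' @return An [nlme_model()] prepared for the drug's `conc_*` endpoint.
#' @export
pk_fit_model <- function(init, omega, sigma, n_cpt = NULL,
                         blq = c("M1", "M3")) {
  blq <- match.arg(blq)
  stopifnot(inherits(init, "drug_params"))
  n_cpt <- as.integer(n_cpt %||% init$n_cpt)
  drug_id <- init$drug_id
  theta <- c(Vc = init$Vc, CL = init$CL, ka_lung = init$ka_lung,
             ka_gut = init$ka_gut, FR = init$FR)
  if (n_cpt == 2L) {
    if (is.null(init$Q)) stop("two-compartment variant requires Q and Vp")
    theta <- c(theta, Q = init$Q, Vp = init$Vp)
  }
  dvid <- if (drug_id == "budesonide") "conc_BUD" else "conc_FMT"
  cmt <- if (drug_id == "budesonide") 1 else 2
  nlme_model(
    predict = function(p, sub) {
      pk_conc(p, n_cpt, drug_id, sub$doses$time, sub$doses$amt, sub$times)
    },
    theta = theta, omega = omega, sigma = sigma,
    prepare = function(data) {
      prepare_subjects(data, dvid = dvid, cmt = cmt, keep_blq = blq == "M3")
    },
    cens_lloq = if (blq == "M3") lloq(drug_id)
  )
}
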