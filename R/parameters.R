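#' Drug-specific pharmacokinetic parameters
#'
#' Structural PK parameters for one inhaled drug. Absorption runs through two
#' parallel first-order depots: a fraction `FR` of each inhaled dose deposits
#' in the lung (rate `ka_lung`), the swallowed remainder `1 - FR` in the gut
#' (rate `ka_gut`). Disposition is linear, one-compartment (`n_cpt = 1`) or
#' two-compartment (`n_cpt = 2`, requiring `Q` and `Vp`).
#'
#' @param drug_id `"budesonide"` or `"formoterol"`.
#' @param FR Fraction of the dose deposited in the lung, in (0, 1).
#' @param ka_lung,ka_gut First-order absorption rate constants (1/h).
#' @param Vc Central volume of distribution (L).
#' @param CL Clearance (L/h).
#' @param Q Inter-compartmental clearance (L/h), two-compartment only.
#' @param Vp Peripheral volume (L), two-compartment only.
#' @param n_cpt Number of disposition compartments, 1 or 2.
#' @return An object of class `drug_params`.
#' @export
#' @examples
#' drug_params("formoterol", FR = 0.385, ka_lung = 14.8, ka_gut = 0.0524,
#'             Vc = 1250, CL = 292, n_cpt = 1)
drug_params <- function(drug_id, FR, ka_lung, ka_gut, Vc, CL,
                        Q = NULL, Vp = NULL, n_cpt = 1) {
  drug_id <- match.arg(drug_id, c("budesonide", "formoterol"))
  stopifnot(is.numeric(FR), length(FR) == 1)
  if (!(FR > 0 && FR < 1)) {
    stop("FR must lie strictly inside (0, 1), got ", FR)
  }
  for (nm in c("ka_lung", "ka_gut", "Vc", "CL")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(nm, " must be a positive finite scalar")
    }
  }
  n_cpt <- as.integer(n_cpt)
  if (!n_cpt %in% c(1L, 2L)) stop("n_cpt must be 1 or 2")
  if (n_cpt == 2L) {
    if (is.null(Q) || is.null(Vp)) stop("Q and Vp are required when n_cpt = 2")
    if (Q <= 0 || Vp <= 0) stop("Q and Vp must be positive")
  } else if (!is.null(Q) || !is.null(Vp)) {
    stop("Q and Vp must be absent when n_cpt = 1")
  }
  structure(
    list(drug_id = drug_id, FR = FR, ka_lung = ka_lung, ka_gut = ka_gut,
         Vc = Vc, CL = CL, Q = Q, Vp = Vp, n_cpt = n_cpt),
    class = "drug_params"
  )
}

#' Indirect-response (turnover) model parameters
#'
#' Parameters of a turnover model dR/dt = kin * h(C) - kout * R in which the
#' lung concentration of the driving drug either inhibits the production rate
#' (`mode = "inhibit_kin"`, budesonide on sputum ECP) or stimulates it
#' (`mode = "stimulate_kin"`, formoterol on FEV1). The production rate is
#' derived from baseline stationarity, kin = kout * BASE, so it is not a free
#' parameter.
#'
#' @param endpoint `"ECP"` or `"FEV1"`.
#' @param mode `"inhibit_kin"` or `"stimulate_kin"`.
#' @param BASE Baseline response (ng/mL for ECP, percent predicted for FEV1).
#' @param kout Loss rate constant (1/h).
#' @param emax Maximum fractional effect (Imax for inhibition, Emax for
#'   stimulation); inhibition requires `0 < emax <= 1`.
#' @param C50 Lung concentration giving half the maximum effect, in the
#'   driving drug's concentration unit (ng/mL budesonide, pg/mL formoterol).
#' @param V_lung Lung volume (L) used to convert lung amount to concentration.
#' @return An object of class `turnover_params`.
#' @export
turnover_params <- function(endpoint, mode, BASE, kout, emax = 1, C50,
                            V_lung = 1.1) {
  endpoint <- match.arg(endpoint, c("ECP", "FEV1"))
  mode <- match.arg(mode, c("inhibit_kin", "stimulate_kin"))
  stopifnot(BASE > 0, kout > 0, C50 > 0, V_lung > 0, emax > 0)
  if (mode == "inhibit_kin" && emax > 1) {
    stop("Imax > 1 would drive production negative; require 0 < Imax <= 1")
  }
  structure(
    list(endpoint = endpoint, mode = mode, BASE = BASE, kout = kout,
         kin = kout * BASE, emax = emax, C50 = C50, V_lung = V_lung),
    class = "turnover_params"
  )
}

#' Clinical-outcome (ACT) model parameters
#'
#' The Asthma Control Test score follows a symptomatic disease-progression
#' model: the score drifts from its baseline at natural rate `alpha` while
#' reversible drug-induced changes in the two PD markers add offsets,
#'
#' `ACT(t) = BASE_ACT - alpha * t + beta1 * (BASE_ECP - R_ECP(t))
#'           + beta2 * (R_FEV1(t) - BASE_FEV1)`.
#'
#' Scores >= 20 are well-controlled, 15-19 partially controlled, < 15
#' uncontrolled.
#'
#' @param BASE_ACT Baseline ACT score.
#' @param alpha Natural disease-progression rate (score/h).
#' @param beta1 Offset per unit decrease in sputum ECP (score per ng/mL).
#' @param beta2 Offset per FEV1 percentage point gained (score per point).
#' @param thresholds Category cutoffs `c(uncontrolled_below, well_from)`.
#' @param clip If `TRUE`, scores are clipped to the instrument range [5, 25];
#'   the model equation itself is unbounded and clipping is off by default.
#' @return An object of class `co_params`.
#' @export
co_params <- function(BASE_ACT, alpha, beta1, beta2,
                      thresholds = c(15, 20), clip = FALSE) {
  stopifnot(alpha >= 0, length(thresholds) == 2)
  if (!(thresholds[1] < thresholds[2])) {
    stop("category thresholds must be strictly increasing")
  }
  structure(
    list(BASE_ACT = BASE_ACT, alpha = alpha, beta1 = beta1, beta2 = beta2,
         thresholds = as.numeric(thresholds), clip = isTRUE(clip)),
    class = "co_params"
  )
}

#' Assemble a full structural parameter set
#'
#' @param bud,fmt [drug_params()] for budesonide and formoterol.
#' @param ecp,fev1 [turnover_params()] for sputum ECP and FEV1.
#' @param co [co_params()] for the ACT outcome model.
#' @return An object of class `parameter_set`.
#' @seealso [default_parameters()] for the final-model values.
#' @export
parameter_set <- function(bud, fmt, ecp, fev1, co) {
  stopifnot(inherits(bud, "drug_params"), bud$drug_id == "budesonide",
            inherits(fmt, "drug_params"), fmt$drug_id == "formoterol",
            inherits(ecp, "turnover_params"), ecp$endpoint == "ECP",
            inherits(fev1, "turnover_params"), fev1$endpoint == "FEV1",
            inherits(co, "co_params"))
  structure(list(bud = bud, fmt = fmt, ecp = ecp, fev1 = fev1, co = co),
            class = "parameter_set")
}

#' Final-model parameter values
#'
#' Reads the structural parameter defaults shipped with the package
#' (`inst/extdata/table2_final.cfg`), the single source of the final-model
#' typical values: two-compartment budesonide and one-compartment formoterol
#' PK with lung/gut dose splitting, turnover PD for sputum ECP and FEV1, and
#' the ACT disease-progression equation. Maximum-effect parameters Imax and
#' Emax default to 1 (full effect).
#'
#' @param path Optional path to an alternative config file.
#' @return A [parameter_set()].
#' @export
#' @examples
#' p <- default_parameters()
#' p$bud$CL   # 18.4 L/h
#' p$co$BASE_ACT
default_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_final.cfg", package = "pkpdco",
                        mustWork = TRUE)
  }
  cfg <- read_config(path)
  g <- function(key) {
    if (!key %in% names(cfg)) stop("config is missing key '", key, "'")
    cfg[[key]]
  }
  parameter_set(
    bud = drug_params("budesonide",
      FR = g("pk.bud.FR"), ka_lung = g("pk.bud.ka_lung"),
      ka_gut = g("pk.bud.ka_gut"), Vc = g("pk.bud.Vc"), CL = g("pk.bud.CL"),
      Q = g("pk.bud.Q"), Vp = g("pk.bud.Vp"), n_cpt = 2),
    fmt = drug_params("formoterol",
      FR = g("pk.fmt.FR"), ka_lung = g("pk.fmt.ka_lung"),
      ka_gut = g("pk.fmt.ka_gut"), Vc = g("pk.fmt.Vc"), CL = g("pk.fmt.CL"),
      n_cpt = 1),
    ecp = turnover_params("ECP", "inhibit_kin",
      BASE = g("pd.ecp.BASE"), kout = g("pd.ecp.kout"),
      emax = g("pd.ecp.Imax"), C50 = g("pd.ecp.IC50"),
      V_lung = g("pd.V_lung")),
    fev1 = turnover_params("FEV1", "stimulate_kin",
      BASE = g("pd.fev1.BASE"), kout = g("pd.fev1.kout"),
      emax = g("pd.fev1.Emax"), C50 = g("pd.fev1.EC50"),
      V_lung = g("pd.V_lung")),
    co = co_params(
      BASE_ACT = g("co.BASE_ACT"), alpha = g("co.alpha"),
      beta1 = g("co.beta1"), beta2 = g("co.beta2"))
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  budesonide : %d-cpt, Vc %.4g L, CL %.4g L/h, FR %.3g\n",
              x$bud$n_cpt, x$bud$Vc, x$bud$CL, x$bud$FR))
  cat(sprintf("  formoterol : %d-cpt, Vc %.4g L, CL %.4g L/h, FR %.3g\n",
              x$fmt$n_cpt, x$fmt$Vc, x$fmt$CL, x$fmt$FR))
  cat(sprintf("  sputum ECP : BASE %.4g ng/mL, kout %.3g /h, IC50 %.3g ng/mL\n",
              x$ecp$BASE, x$ecp$kout, x$ecp$C50))
  cat(sprintf("  FEV1       : BASE %.4g %%, kout %.3g /h, EC50 %.3g pg/mL\n",
              x$fev1$BASE, x$fev1$kout, x$fev1$C50))
  cat(sprintf("  ACT        : BASE %.4g, alpha %.3g /h, beta1 %.3g, beta2 %.3g\n",
              x$co$BASE_ACT, x$co$alpha, x$co$beta1, x$co$beta2))
  invisible(x)
}
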