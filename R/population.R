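#' Population variability specification
#'
#' Bundles the stochastic layers of the model: inter-individual variability
#' (IIV) magnitudes, residual-error models per endpoint, and covariate-effect
#' definitions.
#'
#' @param iiv Named numeric vector of IIV magnitudes, interpreted as the SD
#'   of the random effect on the log scale (the common "CV%" reporting,
#'   omega = CV/100). Names use dotted parameter paths (`"bud.Vc"`,
#'   `"co.BASE_ACT"`); `"bud.FR"` is special-cased to the logit scale so
#'   sampled fractions stay inside (0, 1).
#' @param residual Named list per endpoint (`conc_BUD`, `conc_FMT`, `ECP`,
#'   `FEV1`, `ACT`), each `list(model = "additive"|"proportional"|"combined",
#'   prop = , add = )`.
#' @param covariates A [covariate_model()] or `NULL`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(iiv, residual, covariates = NULL) {
  stopifnot(is.numeric(iiv), !is.null(names(iiv)), all(iiv >= 0))
  for (ep in names(residual)) {
    r <- residual[[ep]]
    stopifnot(r$model %in% c("additive", "proportional", "combined"))
    if (!is.null(r$prop) && r$prop < 0) stop("negative proportional sigma")
    if (!is.null(r$add) && r$add < 0) stop("negative additive sigma")
  }
  if (!is.null(covariates)) stopifnot(inherits(covariates, "covariate_model"))
  structure(list(iiv = iiv, residual = residual, covariates = covariates),
            class = "population_spec")
}

#' Final-model population specification
#'
#' IIV and residual-error magnitudes of the final model, read from the same
#' shipped config as [default_parameters()]: exponential IIV on the central
#' volumes, formoterol clearance, PD baselines and loss rates, and the ACT
#' baseline; logit-scale IIV on the budesonide lung-deposition fraction;
#' proportional residual error on the concentration and PD endpoints and
#' additive error (SD 2.32 score units) on ACT.
#'
#' @param path Optional alternative config path.
#' @return A [population_spec()].
#' @export
default_population <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_final.cfg", package = "pkpdco",
                        mustWork = TRUE)
  }
  cfg <- read_config(path)
  iiv_keys <- names(cfg)[startsWith(names(cfg), "iiv.")]
  iiv <- vapply(iiv_keys, function(k) cfg[[k]], numeric(1))
  names(iiv) <- sub("^iiv\\.", "", iiv_keys)
  eps <- c("conc_BUD", "conc_FMT", "ECP", "FEV1", "ACT")
  residual <- lapply(eps, function(ep) {
    list(model = cfg[[paste0("rv.", ep, ".model")]],
         prop = cfg[[paste0("rv.", ep, ".prop")]],
         add = cfg[[paste0("rv.", ep, ".add")]])
  })
  names(residual) <- eps
  population_spec(iiv = iiv, residual = residual)
}

#' Covariate-effect model
#'
#' A list of (parameter, covariate, relation, coefficient) entries applied to
#' the typical value of a parameter before IIV. Relations: `linear`
#' `TV * (1 + coef * (x - ref))`, `power` `TV * (x / ref)^coef`,
#' `exponential` `TV * exp(coef * (x - ref))`, and `categorical`
#' `TV * (1 + coef)` for subjects in `level`.
#'
#' @param relations List of lists with fields `parameter`, `covariate`,
#'   `relation`, `coefficient`, and optionally `ref` (default: covariate
#'   median) or `level` (categorical).
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(relations = list()) {
  allowed <- c("sex", "age", "weight", "height", "duration", "genotype")
  for (r in relations) {
    stopifnot(is.character(r$parameter),
              r$relation %in% c("linear", "power", "exponential", "categorical"))
    if (!r$covariate %in% allowed) {
      stop("unknown covariate '", r$covariate, "'; expected one of: ",
           paste(allowed, collapse = ", "))
    }
  }
  structure(list(relations = relations), class = "covariate_model")
}

#' Apply covariate relations to a typical value
#' @keywords internal
apply_covariates <- function(tv, parameter, cov_model, covariates) {
  if (is.null(cov_model) || length(cov_model$relations) == 0) return(tv)
  for (r in cov_model$relations) {
    if (r$parameter != parameter) next
    x <- covariates[[r$covariate]]
    if (is.null(x)) stop("covariate '", r$covariate, "' missing from data")
    ref <- r$ref
    if (is.null(ref) && r$relation != "categorical") {
      ref <- stats::median(as.numeric(x))
    }
    tv <- switch(r$relation,
      linear = tv * (1 + r$coefficient * (as.numeric(x) - ref)),
      power = tv * (as.numeric(x) / ref)^r$coefficient,
      exponential = tv * exp(r$coefficient * (as.numeric(x) - ref)),
      categorical = tv * (1 + r$coefficient * as.numeric(x == r$level))
    )
  }
  tv
}

#' Look up a dotted parameter path in a parameter set
#' @keywords internal
param_lookup <- function(params, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("bad parameter path '", key, "'")
  block <- params[[parts[1]]]
  if (is.null(block)) stop("unknown parameter block '", parts[1], "'")
  nm <- parts[2]
  alias <- c(IC50 = "C50", EC50 = "C50", Imax = "emax", Emax = "emax")
  if (nm %in% names(alias)) nm <- alias[[nm]]
  if (!nm %in% names(block)) stop("unknown parameter '", key, "'")
  list(block = parts[1], field = nm, value = block[[nm]])
}

#' Sample individual parameters for a virtual population
#'
#' Draws exponential random effects `P_i = TV * exp(eta)`,
#' `eta ~ N(0, omega^2)`, around the typical values (after any covariate
#' relations), for every parameter named in the IIV specification. The
#' budesonide deposition fraction uses logit-scale IIV so that sampled
#' values respect 0 < FR < 1. Parameters without IIV are replicated at
#' their typical value. Draws are made parameter-by-parameter in the fixed
#' order of `pop$iiv`, so a given seed always yields the same population.
#'
#' @param params Typical-value [parameter_set()].
#' @param pop [population_spec()].
#' @param n Number of subjects.
#' @param covariates Optional data frame of per-subject covariates
#'   (n rows) consumed by the covariate model.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Data frame with one row per subject: every IIV'd parameter plus
#'   the fixed fields needed downstream.
#' @export
#' @examples
#' ind <- sample_population(default_parameters(), default_population(),
#'                          n = 5, seed = 1)
#' ind$co.BASE_ACT
sample_population <- function(params, pop, n, covariates = NULL, seed = NULL) {
  stopifnot(inherits(params, "parameter_set"), inherits(pop, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("covariates must have one row per subject")
  }
  keys <- union(names(pop$iiv),
                c("bud.Vc", "bud.FR", "fmt.Vc", "fmt.CL", "fmt.FR",
                  "ecp.BASE", "ecp.kout", "fev1.BASE", "fev1.kout",
                  "co.BASE_ACT"))
  out <- data.frame(ID = seq_len(n))
  for (key in keys) {
    info <- param_lookup(params, key)
    tv <- apply_covariates(rep(info$value, n), key, pop$covariates, covariates)
    om <- if (key %in% names(pop$iiv)) pop$iiv[[key]] else 0
    if (om > 0) {
      eta <- stats::rnorm(n, 0, om)
      if (info$field == "FR") {
        out[[key]] <- stats::plogis(stats::qlogis(tv) + eta)
      } else {
        out[[key]] <- tv * exp(eta)
      }
    } else {
      out[[key]] <- tv
    }
  }
  if (!is.null(covariates)) out <- cbind(out, covariates)
  out
}

#' Apply a residual-error model to predictions
#'
#' Proportional: `y = f * (1 + eps)`; additive: `y = f + eps`; combined:
#' both terms with independent draws. Deterministic given the RNG state
#' (or `seed`).
#'
#' @param prediction Numeric vector of model predictions (finite).
#' @param endpoint Endpoint name, one of `names(spec$residual)`.
#' @param spec [population_spec()] (or any list with a `residual` field).
#' @param seed Optional integer seed.
#' @return Simulated observations, same length as `prediction`.
#' @export
apply_residual <- function(prediction, endpoint, spec, seed = NULL) {
  stopifnot(all(is.finite(prediction)))
  if (!is.null(seed)) set.seed(seed)
  r <- spec$residual[[endpoint]]
  if (is.null(r)) stop("no residual model for endpoint '", endpoint, "'")
  n <- length(prediction)
  y <- prediction
  if (r$model %in% c("proportional", "combined")) {
    y <- y * (1 + stats::rnorm(n, 0, r$prop))
  }
  if (r$model %in% c("additive", "combined")) {
    y <- y + stats::rnorm(n, 0, r$add)
  }
  y
}

#' Censor concentrations at the lower limit of quantification
#'
#' Observations strictly below the assay LLOQ are flagged BLQ (values at the
#' limit are retained). Negative values arising from additive error
#' components are floored at zero before the check. Only concentration
#' endpoints are ever censored; PD and ACT observations pass through.
#'
#' @param observation Numeric vector of simulated/measured concentrations.
#' @param drug_id `"budesonide"` or `"formoterol"`.
#' @return `data.frame(value, blq)`; `value` is the floored observation and
#'   `blq` is `TRUE` where it fell below the LLOQ.
#' @export
#' @examples
#' censor_lloq(c(0.05, 0.2), "budesonide")  # first is BLQ (LLOQ 0.1 ng/mL)
censor_lloq <- function(observation, drug_id) {
  lim <- lloq(drug_id)
  value <- pmax(observation, 0)
  data.frame(value = value, blq = value < lim)
}
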