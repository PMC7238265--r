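#' Nonlinear mixed-effects model definition
#'
#' A lightweight model container for the approximate marginal-likelihood
#' estimator. Individual parameters are built from the typical values by
#' first applying any covariate relations, then exponential random effects
#' `P_i = TV_i * exp(eta)` for every parameter named in `omega`.
#'
#' @param predict `function(p, sub)` returning the prediction vector for one
#'   subject, where `p` is the named list of individual parameters and `sub`
#'   the prepared per-subject structure (fields `times`, `dv`, `doses`,
#'   `cov`, as produced by `prepare`).
#' @param theta Named numeric vector of typical values (initial estimates).
#' @param omega Named numeric vector of IIV SDs (log scale); names must be a
#'   subset of `names(theta)`. Entries of 0 disable the random effect.
#' @param sigma Residual model: `list(prop = , add = )`, either may be 0 but
#'   not both.
#' @param prepare `function(data)` splitting a dataset into a list of
#'   per-subject structures; the default handles the package's event-table
#'   format via [prepare_subjects()].
#' @param relations Optional list of covariate relations (see
#'   [covariate_model()]); each must carry a `coef_name` naming its
#'   coefficient inside `theta` and a `ref` reference value.
#' @param transform Named character vector mapping theta names to `"log"`
#'   (positive parameters, default) or `"identity"` (sign-free, used for
#'   covariate coefficients).
#' @param cens_lloq Censoring limit for M3 likelihood contributions: when
#'   set, prepared subjects' `times_cens` observations contribute
#'   `-2 log Phi((LLOQ - f)/sd)` instead of being dropped. `NULL` (default)
#'   is the M1 method (censored rows excluded).
#' @return An object of class `nlme_model`.
#' @export
nlme_model <- function(predict, theta, omega = numeric(0),
                       sigma = list(prop = 0, add = 1),
                       prepare = NULL, relations = list(),
                       transform = NULL, cens_lloq = NULL) {
  stopifnot(is.function(predict), is.numeric(theta), !is.null(names(theta)))
  if (length(omega) > 0) {
    stopifnot(!is.null(names(omega)), all(names(omega) %in% names(theta)),
              all(omega >= 0))
  }
  sigma$prop <- sigma$prop %||% 0
  sigma$add <- sigma$add %||% 0
  if (sigma$prop < 0 || sigma$add < 0) stop("negative sigma")
  if (sigma$prop == 0 && sigma$add == 0) stop("residual model is degenerate")
  tr <- rep("log", length(theta))
  names(tr) <- names(theta)
  if (!is.null(transform)) tr[names(transform)] <- transform
  for (r in relations) {
    if (is.null(r$coef_name) || !r$coef_name %in% names(theta)) {
      stop("covariate relation lacks a coef_name present in theta")
    }
    tr[r$coef_name] <- "identity"
  }
  structure(
    list(predict = predict, theta = theta, omega = omega, sigma = sigma,
         prepare = prepare %||% prepare_subjects, relations = relations,
         transform = tr, cens_lloq = cens_lloq),
    class = "nlme_model"
  )
}

#' Individual parameters from typical values, covariates and random effects
#' @keywords internal
make_ind_params <- function(model, theta, eta, sub) {
  p <- as.list(theta)
  for (r in model$relations) {
    x <- sub$cov[[r$covariate]]
    if (is.null(x)) stop("covariate '", r$covariate, "' missing for subject")
    coef <- theta[[r$coef_name]]
    p[[r$parameter]] <- switch(r$relation,
      linear = p[[r$parameter]] * (1 + coef * (as.numeric(x) - r$ref)),
      power = p[[r$parameter]] * (as.numeric(x) / r$ref)^coef,
      exponential = p[[r$parameter]] * exp(coef * (as.numeric(x) - r$ref)),
      categorical = p[[r$parameter]] * (1 + coef * as.numeric(x == r$level)))
  }
  for (nm in names(eta)) p[[nm]] <- p[[nm]] * exp(eta[[nm]])
  p
}

#' Finite-difference Hessian
#' @keywords internal
fd_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Subject-level exact conditional -2 log-likelihood
#'
#' -2 log [ p(y | eta) p(eta) ] with eta-dependent residual variance
#' (proportional error evaluated at the conditional prediction, i.e. with
#' eta-epsilon interaction).
#' @keywords internal
subject_neg2ll <- function(model, theta, omega_act, sub) {
  s2p <- model$sigma$prop^2
  s2a <- model$sigma$add^2
  m3 <- !is.null(model$cens_lloq) && length(sub$times_cens %||% numeric(0)) > 0
  sub_cens <- if (m3) {
    s <- sub
    s$times <- sub$times_cens
    s
  }
  function(eta) {
    names(eta) <- names(omega_act)
    p <- make_ind_params(model, theta, eta, sub)
    f <- model$predict(p, sub)
    if (any(!is.finite(f))) return(1e10)
    v <- s2a + s2p * f^2
    if (any(v <= 0)) return(1e10)
    val <- sum(log(2 * pi * v) + (sub$dv - f)^2 / v)
    if (m3) {
      fc <- model$predict(p, sub_cens)
      if (any(!is.finite(fc))) return(1e10)
      vc <- s2a + s2p * fc^2
      # vc = 0 (prediction 0 under pure proportional error) degenerates to a
      # step: below the limit with certainty
      z <- (model$cens_lloq - fc) / sqrt(vc)
      z[is.nan(z)] <- 0
      val <- val - 2 * sum(stats::pnorm(z, log.p = TRUE))
    }
    if (length(eta) > 0) {
      val <- val + sum(log(2 * pi * omega_act^2) + eta^2 / omega_act^2)
    }
    if (!is.finite(val)) 1e10 else val
  }
}

#' Approximate marginal -2 log-likelihood (objective function value)
#'
#' Computes the population objective function value by the Laplace
#' approximation around each subject's empirical-Bayes mode, with the
#' residual variance of the proportional component evaluated at the
#' conditional prediction (first-order-conditional-with-interaction
#' behaviour). With all IIV zero the value reduces to the exact Gaussian
#' -2 log-likelihood of the residual model.
#'
#' @param model An [nlme_model()].
#' @param data Dataset (event-table data frame) or an already-prepared
#'   subject list.
#' @param theta,omega,sigma Optional overrides of the model's values.
#' @param eta_start Optional matrix of inner-optimization warm starts
#'   (subjects x eta dims).
#' @return List of class `ofv_result`: `ofv` (total), `by_subject`, `eta`
#'   (empirical-Bayes modes), `ok` (all subjects finite).
#' @export
focei_ofv <- function(model, data, theta = NULL, omega = NULL, sigma = NULL,
                      eta_start = NULL) {
  stopifnot(inherits(model, "nlme_model"))
  if (!is.null(theta)) model$theta[names(theta)] <- theta
  if (!is.null(omega)) model$omega[names(omega)] <- omega
  if (!is.null(sigma)) model$sigma <- sigma
  subs <- if (is.data.frame(data)) model$prepare(data) else data
  if (length(subs) == 0) stop("no subjects with usable observations")
  omega_act <- model$omega[model$omega > 0]
  d <- length(omega_act)
  n <- length(subs)
  ofv_i <- numeric(n)
  eta_hat <- matrix(0, n, d, dimnames = list(NULL, names(omega_act)))
  for (i in seq_len(n)) {
    fn <- subject_neg2ll(model, model$theta, omega_act, subs[[i]])
    if (d == 0) {
      ofv_i[i] <- fn(numeric(0))
      next
    }
    start <- if (!is.null(eta_start)) eta_start[i, ] else numeric(d)
    opt <- stats::nlminb(start, fn, control = list(iter.max = 200))
    if (any(abs(opt$par) > 6 * omega_act) || opt$objective >= 1e10) {
      # retry from zero if a warm start wandered off
      opt0 <- stats::nlminb(numeric(d), fn, control = list(iter.max = 200))
      if (opt0$objective < opt$objective) opt <- opt0
    }
    eta_hat[i, ] <- opt$par
    H <- fd_hessian(fn, opt$par) / 2       # Hessian of -log joint
    dt <- det(H)
    if (!is.finite(dt) || dt <= 0) {
      ofv_i[i] <- Inf
      next
    }
    ofv_i[i] <- opt$objective - d * log(2 * pi) + log(dt)
  }
  structure(list(ofv = sum(ofv_i), by_subject = ofv_i, eta = eta_hat,
                 ok = all(is.finite(ofv_i))),
            class = "ofv_result")
}

# ---- parameter packing ----------------------------------------------------

pack_pars <- function(model, fixed) {
  th <- model$theta
  est_t <- setdiff(names(th), fixed)
  om <- model$omega[model$omega > 0]
  est_o <- names(om)[!paste0("omega.", names(om)) %in% fixed]
  est_s <- c(if (model$sigma$prop > 0 && !"sigma.prop" %in% fixed) "prop",
             if (model$sigma$add > 0 && !"sigma.add" %in% fixed) "add")
  par <- c(
    vapply(est_t, function(nm) {
      if (model$transform[nm] == "log") log(th[nm]) else th[nm]
    }, numeric(1)),
    log(om[est_o]),
    vapply(est_s, function(cmp) log(model$sigma[[cmp]]), numeric(1))
  )
  names(par) <- c(paste0("t.", est_t, recycle0 = TRUE),
                  paste0("o.", est_o, recycle0 = TRUE),
                  paste0("s.", est_s, recycle0 = TRUE))
  list(par = par, est_t = est_t, est_o = est_o, est_s = est_s)
}

unpack_pars <- function(model, packing, par) {
  k <- 0
  for (nm in packing$est_t) {
    k <- k + 1
    model$theta[nm] <- if (model$transform[nm] == "log") exp(par[k]) else par[k]
  }
  for (nm in packing$est_o) {
    k <- k + 1
    model$omega[nm] <- exp(par[k])
  }
  for (cmp in packing$est_s) {
    k <- k + 1
    model$sigma[[cmp]] <- exp(par[k])
  }
  model
}

#' Fit a population model by approximate marginal likelihood
#'
#' Minimizes the [focei_ofv()] objective over the non-fixed typical values,
#' IIV magnitudes and residual SDs. Positive parameters are optimized on the
#' log scale (covariate coefficients on the identity scale); multi-start
#' jittering guards against local minima. Standard errors come from the
#' inverse numerical Hessian of the objective at the optimum.
#'
#' Supports the sequential workflow used for the full model (fit PK, fix,
#' fit PK/PD, fix, fit PK/PD/CO) through the `fixed` argument: any theta
#' name, `"omega.<name>"`, `"sigma.prop"` or `"sigma.add"` can be held at
#' its initial value.
#'
#' @param model An [nlme_model()] whose `theta`/`omega`/`sigma` hold the
#'   initial estimates.
#' @param data Event-table data frame (or prepared subject list).
#' @param fixed Character vector of parameter names to fix.
#' @param n_starts Number of optimization starts (first start is the
#'   initial value, the rest are jittered; jitter draws use the current RNG
#'   state).
#' @param jitter SD of the start jitter on the estimation scale.
#' @param se Compute standard errors? Default `TRUE`.
#' @param iter_max Outer iteration cap per start.
#' @return Object of class `fit_result`: `theta`, `omega`, `sigma` at the
#'   optimum, `se` and `rse_percent` (for estimated parameters), `ofv`,
#'   `convergence` flag, `eta` empirical-Bayes modes, `n_subjects`,
#'   `packing` metadata and the updated `model`.
#' @export
fit_population <- function(model, data, fixed = character(), n_starts = 3,
                           jitter = 0.2, se = TRUE, iter_max = 150) {
  stopifnot(inherits(model, "nlme_model"))
  subs <- if (is.data.frame(data)) model$prepare(data) else data
  packing <- pack_pars(model, fixed)
  # inner empirical-Bayes optimizations always start cold so the objective
  # is a deterministic function of par (finite-difference gradients in the
  # outer optimizer require this)
  objective <- function(par) {
    m <- unpack_pars(model, packing, par)
    res <- try(focei_ofv(m, subs), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  if (length(packing$par) == 0) {
    # everything fixed: evaluate and return the initial values
    res <- focei_ofv(model, subs)
    return(structure(
      list(theta = model$theta, omega = model$omega, sigma = model$sigma,
           se = numeric(0), rse_percent = numeric(0), ofv = res$ofv,
           convergence = TRUE, eta = res$eta, n_subjects = length(subs),
           packing = packing, model = model, fixed = fixed),
      class = "fit_result"))
  }
  # central-difference gradient with a step well above the objective's
  # numerical noise floor (~1e-5, set by inner optimization termination);
  # nlminb's internal forward differences use a much smaller step and can
  # stall on that noise at the very first iteration
  gradient <- function(par) {
    vapply(seq_along(par), function(k) {
      ek <- replace(numeric(length(par)), k, 1e-3)
      (objective(par + ek) - objective(par - ek)) / 2e-3
    }, numeric(1))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- packing$par
    if (s > 1) start <- start + stats::rnorm(length(start), 0, jitter)
    opt <- stats::nlminb(start, objective, gradient = gradient,
                         control = list(iter.max = iter_max,
                                        rel.tol = 1e-8))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  fitted <- unpack_pars(model, packing, best$par)
  final <- focei_ofv(fitted, subs)
  # nlminb codes 8/14 ("false/singular convergence") routinely appear when
  # finite-difference gradient noise exceeds the remaining objective
  # improvement; the returned point is still the best found, so they are
  # treated as (soft) convergence and the message is kept in the result
  converged <- best$convergence == 0 ||
    grepl("relative convergence|X-convergence|false convergence|singular convergence",
          best$message %||% "")
  se_nat <- rse <- rep(NA_real_, length(best$par))
  names(se_nat) <- names(rse) <- names(best$par)
  if (se) {
    H <- try(fd_hessian(objective, best$par, h = 1e-3), silent = TRUE)
    if (!inherits(H, "try-error")) {
      cov <- try(2 * solve(H), silent = TRUE)  # OFV = -2 logL
      if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
        se_t <- sqrt(diag(cov))
        for (k in seq_along(best$par)) {
          nm <- names(best$par)[k]
          if (startsWith(nm, "t.") &&
              fitted$transform[sub("^t\\.", "", nm)] == "identity") {
            se_nat[k] <- se_t[k]
            rse[k] <- 100 * se_t[k] / abs(best$par[k])
          } else {
            est <- exp(best$par[k])
            se_nat[k] <- se_t[k] * est       # delta method from log scale
            rse[k] <- 100 * se_t[k]
          }
        }
      }
    }
  }
  structure(
    list(theta = fitted$theta, omega = fitted$omega, sigma = fitted$sigma,
         se = se_nat, rse_percent = rse, ofv = final$ofv,
         convergence = converged && is.finite(final$ofv),
         message = best$message, eta = final$eta, n_subjects = length(subs),
         packing = packing, model = fitted, fixed = fixed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> OFV:", format(x$ofv, digits = 8),
      if (x$convergence) "(converged)" else "(NOT converged)", "\n")
  cat("theta:\n")
  print(signif(x$theta, 4))
  if (length(x$omega)) {
    cat("omega (log-scale SD):\n")
    print(signif(x$omega, 4))
  }
  cat(sprintf("sigma: prop %.4g, add %.4g\n", x$sigma$prop, x$sigma$add))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `dOFV = OFV_reduced - OFV_full` referred to a chi-square distribution.
#' The conventional pharmacometric thresholds are 3.84 (p < 0.05) and 6.64
#' (p < 0.01) for one degree of freedom.
#'
#' @param fit_reduced,fit_full [fit_population()] results (or any object
#'   with an `ofv` field) for nested models.
#' @param df Degrees of freedom (number of extra parameters).
#' @return List `delta_ofv`, `p`, `df`.
#' @export
#' @examples
#' lrt(list(ofv = 103.84), list(ofv = 100), df = 1)$p  # 0.050
lrt <- function(fit_reduced, fit_full, df = 1) {
  d <- fit_reduced$ofv - fit_full$ofv
  if (d < -1e-6) {
    warning("full model has higher OFV than reduced (optimizer failure?)")
  }
  p <- stats::pchisq(max(d, 0), df = df, lower.tail = FALSE)
  list(delta_ofv = d, p = p, df = df)
}

#' Add a covariate relation to a model
#'
#' @param model An [nlme_model()].
#' @param cand List with `parameter`, `covariate`, `relation`, `ref` (or
#'   `level` for categorical), and optionally `init` for the coefficient.
#' @return The extended model; the coefficient is a new theta entry named
#'   `beta.<parameter>.<covariate>` on the identity scale.
#' @export
add_relation <- function(model, cand) {
  coef_name <- paste0("beta.", cand$parameter, ".", cand$covariate)
  if (coef_name %in% names(model$theta)) stop("relation already present")
  cand$coef_name <- coef_name
  model$theta[coef_name] <- cand$init %||% 0.1
  model$transform[coef_name] <- "identity"
  model$relations <- c(model$relations, list(cand))
  model
}

#' Remove a covariate relation from a model
#' @keywords internal
drop_relation <- function(model, coef_name) {
  keep <- vapply(model$relations, function(r) r$coef_name != coef_name,
                 logical(1))
  model$relations <- model$relations[keep]
  model$theta <- model$theta[setdiff(names(model$theta), coef_name)]
  model$transform <- model$transform[setdiff(names(model$transform), coef_name)]
  model
}

#' Stepwise covariate modeling
#'
#' Greedy forward inclusion followed by backward elimination: each forward
#' round fits every remaining candidate on top of the current model and
#' accepts the best one if it lowers the objective by at least
#' `forward_dofv` (3.84, p < 0.05, df 1); backward elimination then removes
#' every included relation whose removal worsens the objective by less than
#' `backward_dofv` (6.64, p < 0.01). Candidate fits that fail are skipped
#' and logged in the trace.
#'
#' @param model Base [nlme_model()] (no candidate relations).
#' @param data Dataset.
#' @param candidates List of candidate relations (see [add_relation()]).
#' @param forward_dofv,backward_dofv Inclusion/retention thresholds.
#' @param ... Passed to [fit_population()] (e.g. `n_starts`, `se`).
#' @return List `model` (final), `fit` (final fit), `trace` (data frame:
#'   `step`, `phase`, `candidate`, `delta_ofv`, `decision`).
#' @export
scm <- function(model, data, candidates, forward_dofv = 3.84,
                backward_dofv = 6.64, ...) {
  subs <- if (is.data.frame(data)) model$prepare(data) else data
  trace <- list()
  note <- function(step, phase, candidate, dofv, decision) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = step, phase = phase, candidate = candidate,
      delta_ofv = dofv, decision = decision)
  }
  cand_label <- function(cand) {
    paste0(cand$parameter, "~", cand$covariate, " (", cand$relation, ")")
  }
  current <- model
  current_fit <- fit_population(current, subs, se = FALSE, ...)
  pool <- candidates
  step <- 0
  while (length(pool) > 0) {
    step <- step + 1
    dofvs <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (k in seq_along(pool)) {
      m2 <- add_relation(current, pool[[k]])
      f2 <- try(fit_population(m2, subs, se = FALSE, ...), silent = TRUE)
      if (inherits(f2, "try-error") || !f2$convergence) {
        note(step, "forward", cand_label(pool[[k]]), NA, "fit failed, skipped")
        next
      }
      dofvs[k] <- current_fit$ofv - f2$ofv
      fits[[k]] <- list(model = m2, fit = f2)
    }
    if (all(is.na(dofvs)) || max(dofvs, na.rm = TRUE) < forward_dofv) {
      for (k in seq_along(pool)) {
        if (!is.na(dofvs[k])) {
          note(step, "forward", cand_label(pool[[k]]), dofvs[k], "not included")
        }
      }
      break
    }
    best <- which.max(dofvs)
    for (k in seq_along(pool)) {
      if (is.na(dofvs[k])) next
      note(step, "forward", cand_label(pool[[k]]), dofvs[k],
           if (k == best) "included" else "not best")
    }
    current <- fits[[best]]$model
    current_fit <- fits[[best]]$fit
    pool <- pool[-best]
  }
  # backward elimination
  repeat {
    rels <- current$relations
    if (length(rels) == 0) break
    dropped <- FALSE
    for (r in rels) {
      step <- step + 1
      m_red <- drop_relation(current, r$coef_name)
      f_red <- try(fit_population(m_red, subs, se = FALSE, ...), silent = TRUE)
      if (inherits(f_red, "try-error")) {
        note(step, "backward", r$coef_name, NA, "reduced fit failed, retained")
        next
      }
      dofv <- f_red$ofv - current_fit$ofv   # worsening on removal
      if (dofv < backward_dofv) {
        note(step, "backward", r$coef_name, dofv, "removed")
        current <- m_red
        current_fit <- f_red
        dropped <- TRUE
        break
      } else {
        note(step, "backward", r$coef_name, dofv, "retained")
      }
    }
    if (!dropped) break
  }
  list(model = current, fit = current_fit,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), phase = character(0),
                    candidate = character(0), delta_ofv = numeric(0),
                    decision = character(0)))
}

#' Compare one- versus two-compartment disposition
#'
#' Fits both structural variants of a drug's PK model and selects the
#' two-compartment model only if it lowers the objective by at least the
#' chi-square criterion for its two extra parameters (Q, Vp):
#' `qchisq(0.95, 2) = 5.99`. Ties or failures of the richer model fall back
#' to the simpler structure.
#'
#' @param model_1cpt,model_2cpt [nlme_model()] variants for the same data.
#' @param data PK dataset.
#' @param dofv_threshold Selection threshold (default 5.99, df 2 at 0.05).
#' @param ... Passed to [fit_population()].
#' @return List `n_cpt` (1 or 2), `fit_1cpt`, `fit_2cpt`, `delta_ofv`.
#' @export
compare_structures <- function(model_1cpt, model_2cpt, data,
                               dofv_threshold = stats::qchisq(0.95, 2), ...) {
  f1 <- fit_population(model_1cpt, data, se = FALSE, ...)
  f2 <- try(fit_population(model_2cpt, data, se = FALSE, ...), silent = TRUE)
  if (inherits(f2, "try-error") || !f2$convergence) {
    return(list(n_cpt = 1L, fit_1cpt = f1, fit_2cpt = NULL,
                delta_ofv = NA_real_))
  }
  d <- f1$ofv - f2$ofv
  list(n_cpt = if (d >= dofv_threshold) 2L else 1L,
       fit_1cpt = f1, fit_2cpt = f2, delta_ofv = d)
}
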