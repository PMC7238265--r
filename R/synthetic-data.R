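#' Trial design definition
#'
#' Encodes the sampling layout of the 12-week open-label trial the model was
#' built on: 53 moderate-asthma adults on 2 puffs b.i.d. of the 160/4.5 ug
#' combination; rich PK sampling on Days 1 and 7 at 0 (pre-dose), 10, 20,
#' 30, 45 min and 1, 2, 3, 4, 5, 6, 7, 9, 11 h post-dose plus trough samples
#' on Days 3-5 (12 h after the preceding evening dose); FEV1 at weeks -2, 0,
#' 1, 4, 8, 12; sputum ECP at the lung-function visits from week 0; ACT at
#' weeks 0, 1, 4, 8, 12.
#'
#' @param n_subjects Number of subjects.
#' @param reg Dosing [regimen()].
#' @param pk_day_starts Morning-dose times (h) of the rich PK days.
#' @param pk_offsets Post-dose sampling offsets (h); 0 is the pre-dose
#'   sample of the visit.
#' @param trough_times Additional pre-dose trough sample times (h).
#' @param fev1_weeks,ecp_weeks,act_weeks Evaluation weeks per endpoint;
#'   week -2 rows are run-in observations at the subject's baseline.
#' @param runin_ecp Include a week -2 ECP row? Off by default (the run-in
#'   visit schedule for sputum sampling is ambiguous).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 53, reg = standard_regimen("2bid"),
                         pk_day_starts = c(0, 144),
                         pk_offsets = c(0, 10, 20, 30, 45) / 60,
                         pk_offsets_h = c(1, 2, 3, 4, 5, 6, 7, 9, 11),
                         trough_times = c(48, 72, 96),
                         fev1_weeks = c(-2, 0, 1, 4, 8, 12),
                         ecp_weeks = c(0, 1, 4, 8, 12),
                         act_weeks = c(0, 1, 4, 8, 12),
                         runin_ecp = FALSE) {
  offs <- sort(unique(c(pk_offsets, pk_offsets_h)))
  pk_times <- sort(unique(c(outer(pk_day_starts, offs, `+`), trough_times)))
  if (runin_ecp) ecp_weeks <- sort(unique(c(-2, ecp_weeks)))
  structure(
    list(n_subjects = n_subjects, reg = reg, pk_times = pk_times,
         pk_day_starts = pk_day_starts,
         fev1_weeks = fev1_weeks, ecp_weeks = ecp_weeks,
         act_weeks = act_weeks),
    class = "trial_design"
  )
}

#' Sample trial demographics
#'
#' Draws per-subject covariates matching the study population: age
#' ~ N(41, 13^2) truncated to [20, 70] years, weight ~ N(70, 14^2) kg,
#' height ~ N(168, 9^2) cm, 33:20 male:female ratio, ADRB2 Arg16Gly
#' genotype frequencies 16/25/12 (AA/AG/GG), and asthma duration
#' ~ N(7.0, 6.9^2) years truncated positive.
#'
#' @param n Number of subjects.
#' @param seed Optional seed.
#' @return Data frame `sex`, `age`, `weight`, `height`, `duration`,
#'   `genotype`.
#' @export
sample_demographics <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  data.frame(
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(33, 20) / 53),
    age = round(rtrunc(n, 41, 13, 20, 70), 1),
    weight = round(rtrunc(n, 70, 14, 30, Inf), 1),
    height = round(rtrunc(n, 168, 9, 120, Inf), 1),
    duration = round(rtrunc(n, 7.0, 6.9, 0.1, Inf), 1),
    genotype = sample(c("AA", "AG", "GG"), n, replace = TRUE,
                      prob = c(16, 25, 12) / 53),
    stringsAsFactors = FALSE
  )
}

#' Generate a trial-shaped synthetic dataset
#'
#' Simulates the full trial through the PK/PD/CO model and emits a
#' NONMEM-style event table: explicit dose rows, PK observations with
#' proportional residual error and LLOQ censoring (BLQ rows keep their
#' floored value but are flagged and marked `MDV = 1`), PD and ACT
#' observations with their residual models, and covariate columns. Week -2
#' run-in rows are generated at the subject's baseline with residual error
#' only. Deterministic given `seed`.
#'
#' @param design A [trial_design()].
#' @param params Typical-value [parameter_set()].
#' @param pop [population_spec()]; its covariate model (if any) shapes the
#'   individual parameters.
#' @param seed Integer seed (required).
#' @return Event-table data frame (see [validate_dataset()]).
#' @export
#' @examples
#' d <- generate_trial(trial_design(n_subjects = 3), default_parameters(),
#'                     default_population(), seed = 1)
#' table(d$DVID[d$EVID == 0])
generate_trial <- function(design, params, pop, seed) {
  stopifnot(inherits(design, "trial_design"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  n <- design$n_subjects
  demo <- sample_demographics(n)
  ind <- sample_population(params, pop, n, covariates = demo)
  sched <- build_schedule(design$reg)

  pd_times <- sort(unique(c(pmax(design$fev1_weeks, 0),
                            pmax(design$ecp_weeks, 0),
                            design$act_weeks) * hours_per_week))
  pd <- simulate_pd_cohort(params, ind, sched, pd_times)

  rows <- vector("list", n)
  cov_row <- function(i) {
    list(SEX = demo$sex[i], AGE = demo$age[i], WT = demo$weight[i],
         HT = demo$height[i], DUR = demo$duration[i], GENO = demo$genotype[i])
  }
  obs_row <- function(i, time, dv, dvid, blq = 0, mdv = NULL) {
    data.frame(ID = i, TIME = time, AMT = NA_real_, EVID = 0, CMT = NA_real_,
               DV = dv, MDV = mdv %||% as.integer(blq), DVID = dvid,
               BLQ = blq, ADDL = 0, II = 0, cov_row(i),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    sub_rows <- list()
    # dose rows (explicit)
    sub_rows$dose <- data.frame(
      ID = i, TIME = rep(sched$time, 2),
      AMT = c(sched$bud, sched$fmt), EVID = 1,
      CMT = rep(c(1, 2), each = nrow(sched)), DV = NA_real_, MDV = 1,
      DVID = "dose", BLQ = 0, ADDL = 0, II = 0, cov_row(i),
      stringsAsFactors = FALSE)
    # PK observations with the subject's own PK parameters
    dp_b <- params$bud
    dp_b$Vc <- ind$bud.Vc[i]; dp_b$FR <- ind$bud.FR[i]
    dp_f <- params$fmt
    dp_f$Vc <- ind$fmt.Vc[i]; dp_f$CL <- ind$fmt.CL[i]; dp_f$FR <- ind$fmt.FR[i]
    used <- sched$time <= max(design$pk_times)
    for (drug in c("budesonide", "formoterol")) {
      dp <- if (drug == "budesonide") dp_b else dp_f
      amt <- if (drug == "budesonide") sched$bud else sched$fmt
      pred <- pk_profile(dp, sched$time[used], amt[used], design$pk_times)$conc
      ep <- if (drug == "budesonide") "conc_BUD" else "conc_FMT"
      obs <- apply_residual(pred, ep, pop)
      cen <- censor_lloq(obs, drug)
      sub_rows[[ep]] <- obs_row(i, design$pk_times, cen$value, ep,
                                blq = as.integer(cen$blq))
    }
    # PD and ACT observations
    at <- function(w) match(max(w, 0) * hours_per_week, pd$eval_times)
    for (w in design$ecp_weeks) {
      pred <- if (w < 0) ind$ecp.BASE[i] else pd$ecp[i, at(w)]
      sub_rows[[paste0("ecp", w)]] <-
        obs_row(i, w * hours_per_week, apply_residual(pred, "ECP", pop),
                "ECP", mdv = 0)
    }
    for (w in design$fev1_weeks) {
      pred <- if (w < 0) ind$fev1.BASE[i] else pd$fev1[i, at(w)]
      sub_rows[[paste0("fev1", w)]] <-
        obs_row(i, w * hours_per_week, apply_residual(pred, "FEV1", pop),
                "FEV1", mdv = 0)
    }
    for (w in design$act_weeks) {
      pred <- ind$co.BASE_ACT[i] - params$co$alpha * w * hours_per_week +
        params$co$beta1 * (ind$ecp.BASE[i] - pd$ecp[i, at(w)]) +
        params$co$beta2 * (pd$fev1[i, at(w)] - ind$fev1.BASE[i])
      sub_rows[[paste0("act", w)]] <-
        obs_row(i, w * hours_per_week, apply_residual(pred, "ACT", pop),
                "ACT", mdv = 0)
    }
    sub <- do.call(rbind, sub_rows)
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  out$DV <- round(out$DV, 6)
  rownames(out) <- NULL
  validate_dataset(out)
  out
}

#' Generate covariate-effect test datasets
#'
#' Produces small PK datasets with a known covariate effect (or none) for
#' exercising stepwise covariate modeling: individual parameters are drawn
#' around typical values modified by the requested relation, covariates are
#' drawn independently of the random effects, and observations follow the
#' drug's residual model.
#'
#' @param parameter Dotted parameter path, e.g. `"fmt.CL"`.
#' @param covariate Covariate name (see [covariate_model()]).
#' @param coefficient Effect size; 0 gives a null dataset.
#' @param relation Relation type, default `"power"`.
#' @param n Number of subjects.
#' @param params,pop Model and population; defaults are the final model.
#' @param seed Integer seed (required).
#' @return Event-table data frame restricted to the drug of `parameter`.
#' @export
generate_covariate_data <- function(parameter, covariate, coefficient,
                                    relation = "power", n = 50,
                                    params = default_parameters(),
                                    pop = default_population(), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  cm <- covariate_model(list(list(
    parameter = parameter, covariate = covariate, relation = relation,
    coefficient = coefficient,
    ref = switch(covariate, age = 41, weight = 70, height = 168,
                 duration = 7, 1)
  )))
  pop$covariates <- if (coefficient != 0) cm else NULL
  drug <- strsplit(parameter, ".", fixed = TRUE)[[1]][1]
  design <- trial_design(
    n_subjects = n,
    reg = standard_regimen("2bid", duration_weeks = 1),
    pk_day_starts = 0, trough_times = numeric(0),
    fev1_weeks = numeric(0), ecp_weeks = numeric(0), act_weeks = numeric(0)
  )
  d <- generate_trial(design, params, pop, seed = seed)
  keep_dvid <- if (drug == "bud") "conc_BUD" else "conc_FMT"
  keep_cmt <- if (drug == "bud") 1 else 2
  d[(d$EVID == 0 & d$DVID == keep_dvid) |
      (d$EVID == 1 & d$CMT == keep_cmt), ]
}
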