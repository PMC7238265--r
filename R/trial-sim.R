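#' Dosing regimen definition
#'
#' A fixed regimen of the budesonide/formoterol 160/4.5 ug combination
#' inhaler: `puffs_per_admin` puffs taken `admins_per_day` times per day for
#' `duration_weeks` weeks. Twice-daily administrations are at 0 h and 12 h;
#' once-daily at 0 h every 24 h. A multi-puff administration is a single
#' combined dose event.
#'
#' @param label Regimen label (e.g. `"2puff_bid"`).
#' @param puffs_per_admin Integer >= 1.
#' @param admins_per_day 1 (q.d.) or 2 (b.i.d.).
#' @param duration_weeks Treatment duration in weeks, positive.
#' @param budesonide_per_puff,formoterol_per_puff Per-puff amounts (ug).
#' @return An object of class `regimen`.
#' @export
#' @examples
#' regimen("2puff_bid", 2, 2, 12)
regimen <- function(label, puffs_per_admin, admins_per_day, duration_weeks,
                    budesonide_per_puff = 160, formoterol_per_puff = 4.5) {
  stopifnot(puffs_per_admin >= 1, admins_per_day %in% c(1, 2),
            duration_weeks > 0)
  structure(
    list(label = label, puffs_per_admin = as.integer(puffs_per_admin),
         admins_per_day = as.integer(admins_per_day),
         duration_weeks = duration_weeks,
         budesonide_per_puff = budesonide_per_puff,
         formoterol_per_puff = formoterol_per_puff),
    class = "regimen"
  )
}

#' The three simulated regimens
#'
#' Shorthand for the regimens compared in the dose-optimization simulation:
#' `"2bid"` (2 puffs twice daily, the trial regimen), `"1bid"` (1 puff twice
#' daily) and `"2qd"` (2 puffs once daily), each for 12 weeks.
#'
#' @param which One of `"2bid"`, `"1bid"`, `"2qd"`.
#' @param duration_weeks Duration, default 12.
#' @return A [regimen()].
#' @export
standard_regimen <- function(which = c("2bid", "1bid", "2qd"),
                             duration_weeks = 12) {
  which <- match.arg(which)
  switch(which,
    "2bid" = regimen("2puff_bid", 2, 2, duration_weeks),
    "1bid" = regimen("1puff_bid", 1, 2, duration_weeks),
    "2qd" = regimen("2puff_qd", 2, 1, duration_weeks)
  )
}

#' Expand a regimen into a dose schedule
#'
#' @param reg A [regimen()].
#' @return Data frame `time` (h), `bud`, `fmt` (total ug per administration).
#' @export
#' @examples
#' head(build_schedule(standard_regimen("2bid")))
build_schedule <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  n_days <- reg$duration_weeks * 7
  offsets <- if (reg$admins_per_day == 2L) c(0, 12) else 0
  times <- as.vector(outer(offsets, (seq_len(n_days) - 1) * 24, `+`))
  times <- sort(times)
  data.frame(
    time = times,
    bud = reg$puffs_per_admin * reg$budesonide_per_puff,
    fmt = reg$puffs_per_admin * reg$formoterol_per_puff
  )
}

#' Classify an ACT score into control categories
#'
#' Scores >= 20 are well-controlled, 15 <= score < 20 partially controlled,
#' < 15 uncontrolled.
#'
#' @param score Numeric vector of finite ACT scores.
#' @param thresholds `c(uncontrolled_below, well_from)`.
#' @return Factor with levels `well`, `partial`, `uncontrolled`.
#' @export
#' @examples
#' classify_act(c(20, 19.7, 14.999))
classify_act <- function(score, thresholds = c(15, 20)) {
  stopifnot(all(is.finite(score)))
  factor(ifelse(score >= thresholds[2], "well",
                ifelse(score >= thresholds[1], "partial", "uncontrolled")),
         levels = c("well", "partial", "uncontrolled"))
}

#' Simulate a virtual clinical trial
#'
#' Samples a virtual population, runs every subject through the PK/PD model
#' under the given regimen, and evaluates the ACT score (with additive
#' residual error drawn independently at each evaluation) at the requested
#' weeks. The week-0 evaluation is made pre-first-dose. All random draws
#' happen up front in a fixed order, so two calls with the same `seed` and
#' `n` produce the identical population (and identical week-0 scores) even
#' when the regimen differs -- enabling paired regimen comparisons.
#'
#' @param n Number of subjects.
#' @param reg A [regimen()], or `NULL` for an untreated cohort (natural
#'   disease progression only).
#' @param eval_weeks Evaluation weeks (0 = pre-dose baseline).
#' @param params Typical-value [parameter_set()].
#' @param pop [population_spec()].
#' @param seed Integer seed (required: the simulation is stochastic).
#' @param residual Draw ACT residual error? Default `TRUE`.
#' @return Object of class `trial_sim`: list with `act` (n x weeks matrix),
#'   `ecp`, `fev1` matrices, `eval_weeks`, `regimen`, `n`, `seed`.
#' @export
#' @examples
#' ts <- simulate_trial(50, standard_regimen("2bid"), c(0, 12),
#'                      default_parameters(), default_population(), seed = 1)
#' colMeans(ts$act)
simulate_trial <- function(n, reg, eval_weeks, params, pop, seed,
                           residual = TRUE) {
  stopifnot(n >= 1, is.null(reg) || inherits(reg, "regimen"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  ind <- sample_population(params, pop, n)
  eps <- if (residual) {
    matrix(stats::rnorm(n * length(eval_weeks), 0,
                        pop$residual$ACT$add %||% 0),
           n, length(eval_weeks))
  } else {
    matrix(0, n, length(eval_weeks))
  }
  sched <- if (is.null(reg)) {
    data.frame(time = numeric(0), bud = numeric(0), fmt = numeric(0))
  } else {
    build_schedule(reg)
  }
  eval_h <- eval_weeks * hours_per_week
  pd <- simulate_pd_cohort(params, ind, sched, eval_h)
  idx <- match(eval_h, pd$eval_times)
  act <- matrix(NA_real_, n, length(eval_weeks))
  for (j in seq_along(eval_weeks)) {
    act[, j] <- ind$co.BASE_ACT - params$co$alpha * eval_h[j] +
      params$co$beta1 * (ind$ecp.BASE - pd$ecp[, idx[j]]) +
      params$co$beta2 * (pd$fev1[, idx[j]] - ind$fev1.BASE) +
      eps[, j]
    if (params$co$clip) act[, j] <- pmin(25, pmax(5, act[, j]))
  }
  colnames(act) <- paste0("week", eval_weeks)
  structure(
    list(act = act, ecp = pd$ecp[, idx, drop = FALSE],
         fev1 = pd$fev1[, idx, drop = FALSE], eval_weeks = eval_weeks,
         regimen = if (is.null(reg)) "untreated" else reg$label,
         n = n, seed = seed),
    class = "trial_sim"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate control status across scenarios
#'
#' Counts and percentages of subjects in each ACT control category per
#' evaluation week and scenario, in the layout of a dose-regimen comparison
#' table.
#'
#' @param sims List of [simulate_trial()] results sharing `n` and
#'   `eval_weeks`.
#' @param thresholds Category cutoffs, see [classify_act()].
#' @return Data frame `week`, `scenario`, `category`, `count`, `percent`.
#' @export
control_table <- function(sims, thresholds = c(15, 20)) {
  if (inherits(sims, "trial_sim")) sims <- list(sims)
  ns <- vapply(sims, function(s) s$n, numeric(1))
  if (length(unique(ns)) != 1) stop("scenarios must share n")
  wk <- sims[[1]]$eval_weeks
  for (s in sims) {
    if (!identical(s$eval_weeks, wk)) stop("scenarios must share eval weeks")
  }
  rows <- list()
  for (s in sims) {
    for (j in seq_along(wk)) {
      cl <- classify_act(s$act[, j], thresholds)
      cnt <- table(cl)
      rows[[length(rows) + 1]] <- data.frame(
        week = wk[j], scenario = s$regimen, category = names(cnt),
        count = as.integer(cnt),
        percent = 100 * as.integer(cnt) / s$n
      )
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category,
                         levels = c("well", "partial", "uncontrolled"))
  out[order(out$week, out$scenario, out$category), ]
}
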