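#' Visual predictive check
#'
#' Compares observed percentiles against simulation-based percentile bands.
#' Observations are binned by nominal sampling time (the trial has fixed
#' schedules, so bins are the scheduled times by default); for each of
#' `n_rep` simulated replicates of the design the same percentiles are
#' computed per bin, and the band for each percentile is the spread of that
#' percentile across replicates. Bins with no observed values are merged
#' into their left neighbour (with a message). Deterministic given `seed`.
#'
#' Two simulation modes mirror the ambiguity in how "simulation in 1000
#' subjects" can be realized: `"replicate"` simulates `n_rep` copies of the
#' study design, while `"cohort"` simulates a single large cohort of
#' `n_subjects` and uses within-cohort percentile uncertainty from
#' resampling the cohort into design-sized groups.
#'
#' @param observed Data frame with columns `time`, `value`.
#' @param simulate `function(rep)` returning a data frame `time`, `value`
#'   for one simulated replicate of the design.
#' @param n_rep Number of simulated replicates (replicate mode) or cohort
#'   groups (cohort mode).
#' @param probs Percentiles tracked, default 5th/50th/95th.
#' @param band Coverage of the simulated band, default 95%.
#' @param bins Optional numeric vector of bin centers; default: unique
#'   observed times.
#' @param seed Integer seed (required).
#' @return Object of class `vpc_result`: data frame with per bin and
#'   percentile the observed value and the simulated band (`lo`, `mid`,
#'   `hi`), plus `n_obs` per bin.
#' @export
vpc <- function(observed, simulate, n_rep = 200,
                probs = c(0.05, 0.5, 0.95), band = 0.95, bins = NULL,
                seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  stopifnot(all(c("time", "value") %in% names(observed)))
  if (is.null(bins)) bins <- sort(unique(observed$time))
  assign_bin <- function(t) bins[max.col(-abs(outer(t, bins, `-`)))]
  observed$bin <- assign_bin(observed$time)
  counts <- table(factor(observed$bin, levels = bins))
  while (any(counts == 0) && length(bins) > 1) {
    empty <- which(counts == 0)[1]
    message("VPC: empty bin at t = ", bins[empty], " merged with neighbour")
    bins <- bins[-empty]
    observed$bin <- assign_bin(observed$time)
    counts <- table(factor(observed$bin, levels = bins))
  }
  obs_q <- lapply(bins, function(b) {
    stats::quantile(observed$value[observed$bin == b], probs, names = FALSE)
  })
  sim_q <- array(NA_real_, c(n_rep, length(bins), length(probs)))
  for (r in seq_len(n_rep)) {
    s <- simulate(r)
    s$bin <- assign_bin(s$time)
    for (bi in seq_along(bins)) {
      v <- s$value[s$bin == bins[bi]]
      if (length(v) > 0) {
        sim_q[r, bi, ] <- stats::quantile(v, probs, names = FALSE)
      }
    }
  }
  a <- (1 - band) / 2
  out <- do.call(rbind, lapply(seq_along(bins), function(bi) {
    do.call(rbind, lapply(seq_along(probs), function(pi) {
      x <- sim_q[, bi, pi]
      data.frame(bin = bins[bi], percentile = probs[pi],
                 observed = obs_q[[bi]][pi],
                 lo = stats::quantile(x, a, na.rm = TRUE, names = FALSE),
                 mid = stats::median(x, na.rm = TRUE),
                 hi = stats::quantile(x, 1 - a, na.rm = TRUE, names = FALSE),
                 n_obs = as.integer(counts[bi]))
    }))
  }))
  structure(out, class = c("vpc_result", "data.frame"))
}

#' Nonparametric bootstrap for a population fit
#'
#' Resamples subjects with replacement and reports per-parameter 5th-95th
#' percentile intervals. Two modes: `"refit"` (case resampling with full
#' refits at a reduced iteration budget, starting from the point estimate)
#' and the fast `"linearized"` mode, which resamples subject-level score
#' contributions around the linearization point and applies a one-step
#' Newton update per replicate. Failed replicate fits are excluded and
#' counted.
#'
#' @param fit A [fit_population()] result (the point estimate).
#' @param data The original dataset (or prepared subject list).
#' @param n_boot Number of bootstrap replicates.
#' @param mode `"linearized"` (default) or `"refit"`.
#' @param seed Integer seed (required).
#' @param iter_max Refit iteration budget (refit mode).
#' @return Object of class `bootstrap_result`: `ci` (data frame
#'   `parameter`, `p5`, `p50`, `p95` on the natural scale), `estimates`
#'   (replicates x parameters), `n_fail`, `mode`.
#' @export
bootstrap_fit <- function(fit, data, n_boot = 1000,
                          mode = c("linearized", "refit"), seed,
                          iter_max = 30) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  stopifnot(inherits(fit, "fit_result"))
  model <- fit$model
  subs <- if (is.data.frame(data)) model$prepare(data) else data
  n <- length(subs)
  if (n < 2) stop("bootstrap needs at least 2 subjects")
  packing <- fit$packing
  par_hat <- pack_pars(model, fit$fixed)$par
  p <- length(par_hat)
  est <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, names(par_hat)))
  n_fail <- 0
  if (mode == "linearized") {
    # per-subject score vectors and total Hessian at the estimate
    obj_sub <- function(par, i) {
      m <- unpack_pars(model, packing, par)
      focei_ofv(m, subs[i])$ofv
    }
    h <- 1e-3
    G <- matrix(0, n, p)
    for (i in seq_len(n)) {
      for (k in seq_len(p)) {
        ek <- replace(numeric(p), k, h)
        G[i, k] <- (obj_sub(par_hat + ek, i) - obj_sub(par_hat - ek, i)) /
          (2 * h)
      }
    }
    H <- fd_hessian(function(par) {
      m <- unpack_pars(model, packing, par)
      focei_ofv(m, subs)$ofv
    }, par_hat, h = 1e-3)
    Hinv <- try(solve(H), silent = TRUE)
    if (inherits(Hinv, "try-error")) {
      stop("Hessian at the estimate is singular; use mode = 'refit'")
    }
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      score <- colSums(G[ix, , drop = FALSE])
      est[b, ] <- par_hat - as.vector(Hinv %*% score)
    }
  } else {
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      f <- try(fit_population(model, subs[ix], fixed = fit$fixed,
                              n_starts = 1, se = FALSE, iter_max = iter_max),
               silent = TRUE)
      if (inherits(f, "try-error") || !f$convergence) {
        n_fail <- n_fail + 1
        next
      }
      est[b, ] <- pack_pars(f$model, fit$fixed)$par
    }
  }
  # natural scale: exp() for log-transformed entries
  nat <- est
  for (k in seq_len(p)) {
    nm <- names(par_hat)[k]
    is_ident <- startsWith(nm, "t.") &&
      model$transform[sub("^t\\.", "", nm)] == "identity"
    if (!is_ident) nat[, k] <- exp(est[, k])
  }
  ci <- do.call(rbind, lapply(seq_len(p), function(k) {
    q <- stats::quantile(nat[, k], c(0.05, 0.5, 0.95), na.rm = TRUE,
                         names = FALSE)
    data.frame(parameter = names(par_hat)[k], p5 = q[1], p50 = q[2],
               p95 = q[3])
  }))
  structure(list(ci = ci, estimates = nat, n_fail = n_fail, mode = mode),
            class = "bootstrap_result")
}

#' Noncompartmental analysis of a concentration profile
#'
#' Cmax and Tmax by direct lookup, AUClast by the linear trapezoidal rule
#' up to the last quantifiable point. BLQ handling: leading and trailing
#' BLQ points are dropped; embedded BLQ points are treated as missing (no
#' zero substitution). At least three quantifiable points are required.
#'
#' @param time Sampling times (h), sorted.
#' @param conc Concentrations (any unit).
#' @param blq Logical vector flagging BLQ points; default none.
#' @return List `cmax`, `tmax`, `auclast`, `n_points`.
#' @export
#' @examples
#' nca(c(0, 1, 2), c(0, 2, 1))  # cmax 2 at tmax 1, AUClast 2.5
nca <- function(time, conc, blq = NULL) {
  stopifnot(length(time) == length(conc), !is.unsorted(time))
  if (is.null(blq)) blq <- rep(FALSE, length(time))
  keep <- !blq & !is.na(conc)
  time <- time[keep]
  conc <- conc[keep]
  if (length(conc) < 3) {
    stop("NCA requires at least 3 quantifiable points, got ", length(conc))
  }
  imax <- which.max(conc)
  auc <- sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  list(cmax = conc[imax], tmax = time[imax], auclast = auc,
       n_points = length(conc))
}

#' Day-1 NCA summary for a PK dataset
#'
#' Runs [nca()] on each subject's Day-1 profile for one drug and summarizes
#' Cmax and AUClast as mean +/- standard error.
#'
#' @param data Event table.
#' @param drug `"budesonide"` or `"formoterol"`.
#' @param tmax_window Upper time bound of the Day-1 profile (h).
#' @return List `per_subject` (data frame) and `summary` (mean and SE of
#'   Cmax and AUClast; subjects with fewer than 3 quantifiable points are
#'   skipped and counted).
#' @export
nca_day1 <- function(data, drug = c("budesonide", "formoterol"),
                     tmax_window = 12) {
  drug <- match.arg(drug)
  dvid <- if (drug == "budesonide") "conc_BUD" else "conc_FMT"
  obs <- data[data$EVID == 0 & data$DVID == dvid & data$TIME <= tmax_window, ]
  res <- list()
  n_skipped <- 0
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    r <- try(nca(o$TIME, o$DV, blq = o$BLQ == 1), silent = TRUE)
    if (inherits(r, "try-error")) {
      n_skipped <- n_skipped + 1
      next
    }
    res[[length(res) + 1]] <- data.frame(ID = id, cmax = r$cmax,
                                         tmax = r$tmax, auclast = r$auclast)
  }
  per <- do.call(rbind, res)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(per_subject = per,
       summary = data.frame(
         metric = c("Cmax", "AUClast"),
         mean = c(mean(per$cmax), mean(per$auclast)),
         se = c(se(per$cmax), se(per$auclast))),
       n_skipped = n_skipped)
}
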