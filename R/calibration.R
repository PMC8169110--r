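#' Fit result container
#'
#' Every calibration stage returns its estimates wrapped in a `fit_result`
#' holding the residual sum of squares, an optional Pearson fit-quality
#' statistic, and a convergence flag.
#'
#' @param stage Stage label (e.g. `"growth_rate"`).
#' @param estimates Named list of estimated parameters.
#' @param rss Residual sum of squares (>= 0).
#' @param R Pearson correlation between model and data (in `[-1, 1]`), or
#'   `NA` if not computed.
#' @param p Two-sided p-value accompanying `R`.
#' @param converged Logical convergence flag.
#' @param message Optional diagnostic message.
#' @param details Optional list of stage-specific diagnostics.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(stage, estimates, rss, R = NA_real_, p = NA_real_,
                       converged = TRUE, message = "", details = list()) {
  stopifnot(is.character(stage), rss >= 0,
            is.na(R) || (R >= -1 && R <= 1))
  structure(list(stage = stage, estimates = estimates, rss = rss,
                 R = R, p = p, converged = converged, message = message,
                 details = details),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit stage '%s': RSS = %.4g%s%s\n", x$stage, x$rss,
              if (!is.na(x$R)) sprintf(", R = %.4f", x$R) else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- unlist(x$estimates)
  for (nm in names(est)) cat(sprintf("  %-12s %.6g\n", nm, est[nm]))
  if (nzchar(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A [fit_result()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
fit_result_json <- function(fit, path = NULL) {
  x <- list(stage = fit$stage, estimates = fit$estimates, rss = fit$rss,
            R = fit$R, p = fit$p, converged = fit$converged,
            message = fit$message)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                             null = "null"))
}

calibration_means <- function(cohort, arm, stage) {
  df <- as.data.frame(cohort)
  if (!arm %in% df$arm)
    stop("calibration stage '", stage, "' requires the '", arm,
         "' arm, which is absent from the cohort data")
  arm_means(cohort, arm)
}

fit_weights <- function(means, weights) {
  if (weights == "inverse_variance") {
    w <- 1 / means$sd_mm3^2
    if (any(!is.finite(w)))
      stop("inverse-variance weighting requires positive per-day SDs")
    sqrt(w)
  } else {
    rep(1, nrow(means))
  }
}

#' Stage 1: fit the tumor growth rate constant
#'
#' Least-squares fit of the closed-form logistic solution to the per-day
#' mean volumes of the GCV-only control arm over the late observation
#' window (both kill terms vanish there, so growth is pure logistic). The
#' curve is anchored at the earliest day in the window and parameterised by
#' `(sigma, V_anchor)`; starting values come from the exact logit-linear
#' form `log(V / (K - V)) = const + sigma * t`.
#'
#' @param cohort A [cohort_measurements()] data frame.
#' @param K Carrying capacity (mm^3), held fixed.
#' @param arm Control arm label.
#' @param day_range Inclusive day window used for the fit (default 15-21).
#' @param weights `"none"` (ordinary least squares on day means, default)
#'   or `"inverse_variance"` (weight by 1/SD^2).
#' @return A list with elements `sigma` and `fit` (a [fit_result()]).
#' @export
fit_growth_rate <- function(cohort, K = 1e4, arm = "control_gcv_only",
                            day_range = c(15, 21),
                            weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  means <- calibration_means(cohort, arm, "growth_rate")
  means <- means[means$day >= day_range[1] & means$day <= day_range[2], ]
  if (nrow(means) < 2L)
    stop("calibration stage 'growth_rate' needs >= 2 control time points ",
         "in [", day_range[1], ", ", day_range[2], "] days")
  t1 <- min(means$day)
  w <- fit_weights(means, weights)
  # exact logit-linear start; noisy means can exceed K near saturation, so
  # clamp into (0, K) for the transform only
  vc <- pmin(pmax(means$mean_mm3, K * 1e-9), K * (1 - 1e-9))
  u <- log(vc / (K - vc))
  ls <- stats::lm(u ~ means$day)
  sigma0 <- max(1e-4, min(5, unname(stats::coef(ls)[2])))
  v1_0 <- vc[means$day == t1][1]
  model_v <- function(par, t) {
    # logistic anchored at (t1, V1)
    K / (1 + (K / par[2] - 1) * exp(-par[1] * (t - t1)))
  }
  res_fn <- function(par) w * (model_v(par, means$day) - means$mean_mm3)
  fit <- minpack.lm::nls.lm(
    par = c(sigma = sigma0, V1 = v1_0), fn = res_fn,
    lower = c(1e-6, 1e-6), upper = c(5, K * (1 - 1e-12)),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 200))
  sigma <- unname(fit$par[1])
  rss <- sum(fit$fvec^2)
  list(sigma = sigma,
       fit = fit_result("growth_rate",
                        list(sigma = sigma, V_anchor = unname(fit$par[2]),
                             anchor_day = t1),
                        rss, converged = fit$info %in% 1:4,
                        message = fit$message))
}

#' Stage 2: extrapolate the initial tumor volume
#'
#' Runs the logistic closed form backward from the earliest fitted point to
#' implantation time t = 0:
#' `V0 = K * V1 / (V1 + (K - V1) * exp(sigma * t1))`.
#' By default the anchor `(t1, V1)` is the earliest observed control mean;
#' supplying the fitted anchor from [fit_growth_rate()] instead makes the
#' extrapolation robust to observation noise near the carrying capacity.
#'
#' @param sigma Fitted growth rate constant (day^-1).
#' @param cohort A [cohort_measurements()] data frame.
#' @param K Carrying capacity (mm^3).
#' @param arm Control arm label.
#' @param anchor Optional list with `day` and `volume` overriding the
#'   earliest observed mean (e.g. `V_anchor`/`anchor_day` from the
#'   growth-rate fit).
#' @return `V0` in mm^3.
#' @export
extrapolate_initial_volume <- function(sigma, cohort, K = 1e4,
                                       arm = "control_gcv_only",
                                       anchor = NULL) {
  if (is.null(anchor)) {
    means <- calibration_means(cohort, arm, "initial_volume")
    t1 <- min(means$day)
    V1 <- means$mean_mm3[means$day == t1][1]
  } else {
    t1 <- anchor$day; V1 <- anchor$volume
  }
  if (V1 >= K)
    stop("anchor volume is at or above the carrying capacity")
  K * V1 / (V1 + (K - V1) * exp(sigma * t1))
}

#' Stage 3: fit the GCV plasma pharmacokinetics
#'
#' Least-squares Bateman-curve fit to a plasma concentration time series
#' after a single ip dose. The absorption/excretion exchange ambiguity of
#' the Bateman function is resolved by the constraint `ka > kex`
#' (absorption faster than elimination, the flip-over convention). When
#' `c0_ip` is `NULL` the curve amplitude is fitted as a third parameter,
#' which absorbs the unknown plasma volume of distribution.
#'
#' @param pk_data Data frame with columns `time` (days) and `concentration`.
#' @param c0_ip Known initial peritoneal concentration, or `NULL` to fit the
#'   amplitude.
#' @return A list with `ka_gcv`, `kex_gcv`, `c0_ip`, and `fit`.
#' @export
fit_gcv_pk <- function(pk_data, c0_ip = NULL) {
  stopifnot(is.data.frame(pk_data),
            all(c("time", "concentration") %in% names(pk_data)))
  pk <- pk_data[order(pk_data$time), ]
  pos <- pk[pk$time > 0, ]
  if (nrow(pos) < 4L)
    stop("calibration stage 'gcv_pk' needs >= 4 post-dose samples")
  imax <- which.max(pos$concentration)
  if (imax == 1L || imax == nrow(pos))
    warning("GCV PK samples do not bracket a concentration peak; ",
            "absorption and excretion rates may be poorly identified")
  # starts: terminal slope for kex, peak position for ka
  tail_n <- max(3L, ceiling(nrow(pos) / 3))
  tail_i <- seq(nrow(pos) - tail_n + 1L, nrow(pos))
  cc <- pmax(pos$concentration, 1e-12 * max(pos$concentration))
  kex0 <- max(0.1, -unname(stats::coef(
    stats::lm(log(cc[tail_i]) ~ pos$time[tail_i]))[2]))
  ka0 <- max(3 * kex0, 1 / max(pos$time[imax], 1e-3))
  amp0 <- if (is.null(c0_ip)) {
    max(pos$concentration) / max(ip_bateman_concentration(
      bateman_peak_time(ka0, kex0), 1, ka0, kex0), 1e-12)
  } else c0_ip
  # parameterise ka = kex + delta (delta > 0) to enforce ka > kex
  pred <- function(par) {
    kex <- exp(par[1]); ka <- kex + exp(par[2])
    a <- if (is.null(c0_ip)) exp(par[3]) else c0_ip
    vapply(pos$time, ip_bateman_concentration, numeric(1),
           c0_ip = a, ka = ka, kex = kex)
  }
  res_fn <- function(par) pred(par) - pos$concentration
  par0 <- c(log_kex = log(kex0), log_delta = log(max(ka0 - kex0, 1e-3)))
  if (is.null(c0_ip)) par0 <- c(par0, log_amp = log(amp0))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = res_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500))
  kex <- exp(unname(fit$par[1]))
  ka <- kex + exp(unname(fit$par[2]))
  amp <- if (is.null(c0_ip)) exp(unname(fit$par[3])) else c0_ip
  rss <- sum(fit$fvec^2)
  list(ka_gcv = ka, kex_gcv = kex, c0_ip = amp,
       fit = fit_result("gcv_pk",
                        list(ka_gcv = ka, kex_gcv = kex, c0_ip = amp),
                        rss, converged = fit$info %in% 1:4,
                        message = fit$message))
}

sim_obs_days <- function(params, schedule, days, peptide_mode,
                         active_S, active_N, rtol = 1e-8) {
  tf <- max(c(days, schedule$events$time,
              if (schedule$infusion_mu > 0) schedule$infusion_start))
  times <- sort(unique(c(0, days, tf)))
  traj <- simulate_system(params, schedule, times,
                          peptide_mode = peptide_mode,
                          active_S = active_S, active_N = active_N,
                          rtol = rtol, atol = rtol * 1e-2)
  traj$V[match(days, traj$time)]
}

#' Stage 4: fit the GCV kill proportionality constant
#'
#' With the growth parameters fixed and the peptide kill term switched off,
#' fits `lambda` by least squares against the untargeted-vector + GCV arm
#' means over the 0-21 day window, integrating the full dosed system at
#' each objective evaluation.
#'
#' @param cohort A [cohort_measurements()] data frame.
#' @param sigma,V0 Growth parameters from the earlier stages.
#' @param gcv_pk List with `ka_gcv` and `kex_gcv` (from [fit_gcv_pk()]).
#' @param K Carrying capacity (mm^3).
#' @param arm Untargeted-vector arm label.
#' @param schedule GCV dosing schedule (default: daily ip doses, days
#'   12-21, no peptide bolus).
#' @param upper Upper bound for `lambda`.
#' @inheritParams fit_growth_rate
#' @return A list with `lam` and `fit`.
#' @export
fit_gcv_death <- function(cohort, sigma, V0, gcv_pk, K = 1e4,
                          arm = "fd_aavp_gcv",
                          schedule = gene_therapy_schedule(include_peptide = FALSE),
                          upper = 1e3,
                          weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  means <- calibration_means(cohort, arm, "gcv_death")
  means <- means[means$day <= 21, ]
  days <- means$day
  w <- fit_weights(means, weights)
  base <- model_parameters(sigma = sigma, K = K, V0 = V0, D_pep = 0,
                           Kd = 1, lam = 0, kex_pep = 1, kex_pep_sol = 1,
                           ka_gcv = gcv_pk$ka_gcv, kex_gcv = gcv_pk$kex_gcv)
  res_fn <- function(par) {
    p <- update_parameters(base, lam = par[1])
    w * (sim_obs_days(p, schedule, days, "aavp", FALSE, TRUE) -
           means$mean_mm3)
  }
  # rough start: terminal log-deficit relative to the untreated curve,
  # divided by the cumulative GCV exposure
  v_un <- logistic_solution(days, V0, sigma, K)
  gcv_amt <- schedule$events$amount[schedule$events$compartment ==
                                      "gcv_peritoneal"]
  auc1 <- mean(if (length(gcv_amt) > 0) gcv_amt else 0.008) /
    gcv_pk$kex_gcv  # per-dose plasma AUC
  n_doses <- vapply(days, function(d)
    sum(schedule$events$time <= d), numeric(1))
  defic <- log(pmax(v_un / pmax(means$mean_mm3, 1e-9), 1))
  lam0 <- stats::median(defic[n_doses > 0] / (auc1 * n_doses[n_doses > 0]))
  lam0 <- min(max(lam0, 1e-3, na.rm = TRUE), upper, na.rm = TRUE)
  fit <- minpack.lm::nls.lm(
    par = c(lam = lam0), fn = res_fn, lower = 0, upper = upper,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 200))
  lam <- unname(fit$par[1])
  msg <- fit$message
  if (lam >= upper * (1 - 1e-6)) {
    warning("lambda driven to its upper bound; fit may not have converged")
    msg <- paste(msg, "(at upper bound)")
  }
  list(lam = lam,
       fit = fit_result("gcv_death", list(lam = lam), sum(fit$fvec^2),
                        converged = fit$info %in% 1:4, message = msg))
}

#' Stage 5: fit the peptide kill parameters
#'
#' Joint 3-parameter least squares for `(D_pep, Kd, kex_pep)` on the
#' targeted-vector + GCV arm, with all previously estimated parameters held
#' fixed. The objective integrates the full dosed system (both kill terms
#' active). Because the three parameters can trade off along the observed
#' kill time course, the fit uses Latin-hypercube multi-start in log space
#' and reports a practical-identifiability flag when the fitted `Kd` lies
#' far above the peak plasma peptide concentration (occupancy then depends
#' only on `D_pep / Kd`).
#'
#' @inheritParams fit_gcv_death
#' @param lam Fitted GCV kill constant.
#' @param arm Targeted-vector arm label.
#' @param schedule Full gene-therapy schedule (peptide bolus + GCV doses).
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Seed for the start design.
#' @return A list with `D_pep`, `Kd`, `kex_pep`, and `fit`.
#' @export
fit_peptide_params <- function(cohort, sigma, V0, lam, gcv_pk, K = 1e4,
                               arm = "csstresac_aavp_gcv",
                               schedule = gene_therapy_schedule(),
                               n_starts = 8, seed = 20210601,
                               weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  means <- calibration_means(cohort, arm, "peptide_params")
  means <- means[means$day <= 21, ]
  days <- means$day
  w <- fit_weights(means, weights)
  base <- model_parameters(sigma = sigma, K = K, V0 = V0, D_pep = 0.01,
                           Kd = 1, lam = lam, kex_pep = 1, kex_pep_sol = 1,
                           ka_gcv = gcv_pk$ka_gcv, kex_gcv = gcv_pk$kex_gcv)
  res_fn <- function(par) {
    p <- update_parameters(base, D_pep = exp(par[1]), Kd = exp(par[2]),
                           kex_pep = exp(par[3]))
    w * (sim_obs_days(p, schedule, days, "aavp", TRUE, TRUE) -
           means$mean_mm3)
  }
  # log-space Latin-hypercube starts: D_pep 1e-4..10, Kd 1e-2..1e2,
  # kex_pep 1e-2..1e2
  set.seed(seed)
  lo <- log(c(1e-4, 1e-2, 1e-2)); hi <- log(c(10, 1e2, 1e2))
  X <- lhs::randomLHS(n_starts, 3)
  starts <- t(lo + t(X) * (hi - lo))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = starts[i, ], fn = res_fn, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                           maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)))
      best <- f
  }
  if (is.null(best)) stop("all peptide-parameter starts failed")
  est <- exp(unname(best$par))
  peak_c <- if (nrow(schedule$events) > 0)
    max(schedule$events$amount[schedule$events$compartment ==
                                 "peptide_plasma"], 0) else 0
  flag <- peak_c > 0 && est[2] > 50 * peak_c
  list(D_pep = est[1], Kd = est[2], kex_pep = est[3],
       fit = fit_result("peptide_params",
                        list(D_pep = est[1], Kd = est[2],
                             kex_pep = est[3]),
                        sum(best$fvec^2), converged = best$info %in% 1:4,
                        message = if (flag)
                          "Kd far above peak concentration: only D_pep/Kd identified"
                        else best$message,
                        details = list(non_identifiable_plateau = flag)))
}

#' Stage 6: refit the soluble-peptide excretion rate
#'
#' The vector-displayed and soluble forms of the peptide clear at very
#' different rates. With `D_pep` and `Kd` fixed from the gene-therapy
#' calibration, this stage refits the excretion rate constant on the
#' soluble-peptide arm (no GCV, so the `lambda` term is absent).
#'
#' @inheritParams fit_peptide_params
#' @param D_pep,Kd Peptide kill parameters, held fixed.
#' @param arm Soluble-peptide arm label.
#' @param schedule Soluble bolus schedule (default: one 0.8 mM iv bolus on
#'   day 5).
#' @param bounds Search interval for `kex_pep_sol` (day^-1).
#' @return A list with `kex_pep_sol` and `fit`.
#' @export
refit_soluble_excretion <- function(cohort, sigma, V0, D_pep, Kd, K = 1e4,
                                    arm = "soluble_csstresac",
                                    schedule = soluble_bolus_schedule(),
                                    bounds = c(1e-2, 1e3),
                                    weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  means <- calibration_means(cohort, arm, "soluble_excretion")
  means <- means[means$day <= 21, ]
  days <- means$day
  w <- fit_weights(means, weights)
  base <- model_parameters(sigma = sigma, K = K, V0 = V0, D_pep = D_pep,
                           Kd = Kd, lam = 0, kex_pep = 1, kex_pep_sol = 1,
                           ka_gcv = 1, kex_gcv = 1)
  res_fn <- function(par) {
    p <- update_parameters(base, kex_pep_sol = exp(par[1]))
    w * (sim_obs_days(p, schedule, days, "soluble", TRUE, FALSE,
                      rtol = 1e-10) - means$mean_mm3)
  }
  # epsfcn keeps finite-difference steps above the ODE-solver noise floor:
  # the soluble-arm volumes respond only weakly to kex, so the default
  # sqrt(machine-eps) step would differentiate integrator round-off
  fit <- minpack.lm::nls.lm(
    par = c(log_kex = log(20)), fn = res_fn,
    lower = log(bounds[1]), upper = log(bounds[2]),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         epsfcn = 1e-6, maxiter = 500))
  kex <- exp(unname(fit$par[1]))
  msg <- fit$message
  if (kex >= bounds[2] * (1 - 1e-6)) {
    warning("kex_pep_sol at its upper bound: the soluble arm is ",
            "indistinguishable from an untreated arm")
    msg <- paste(msg, "(at upper bound)")
  }
  list(kex_pep_sol = kex,
       fit = fit_result("soluble_excretion", list(kex_pep_sol = kex),
                        sum(fit$fvec^2), converged = fit$info %in% 1:4,
                        message = msg))
}

#' Pearson fit-quality statistic
#'
#' Pearson correlation (with two-sided p-value) between model-predicted
#' volumes and observed per-day arm means at the observation days. Model
#' values are linearly interpolated from the trajectory grid. Passing a
#' named list of trajectories (one per arm) pools the matched pairs across
#' arms, which is the statistic quoted for the overall model-data
#' agreement.
#'
#' @param model_traj A `trajectory_series` from [simulate_system()], or a
#'   named list of them keyed by arm label.
#' @param cohort A [cohort_measurements()] data frame.
#' @param arm Arm whose means are compared (ignored when `model_traj` is a
#'   named list).
#' @return A list with `R`, `p`, and `n` (number of matched pairs).
#' @export
fit_quality <- function(model_traj, cohort, arm = NULL) {
  if (is.data.frame(model_traj)) {
    if (is.null(arm)) stop("arm is required for a single trajectory")
    model_traj <- stats::setNames(list(model_traj), arm)
  }
  pred <- numeric(0); obs <- numeric(0)
  for (a in names(model_traj)) {
    tr <- model_traj[[a]]
    means <- calibration_means(cohort, a, "fit_quality")
    means <- means[means$day >= min(tr$time) & means$day <= max(tr$time), ]
    pred <- c(pred, stats::approx(tr$time, tr$V, xout = means$day)$y)
    obs <- c(obs, means$mean_mm3)
  }
  if (length(obs) < 3L)
    stop("fit_quality needs >= 3 matched (model, observed-mean) pairs")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("Pearson correlation undefined: zero variance in model ",
         "predictions or observed means")
  ct <- stats::cor.test(pred, obs, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(obs))
}

#' Run the full sequential calibration
#'
#' Executes the six calibration stages in their required order: growth rate
#' on the GCV-only control, initial-volume extrapolation, GCV plasma PK
#' (when `pk_data` is supplied), GCV kill constant on the untargeted-vector
#' arm, the peptide kill triple on the targeted-vector arm, and the
#' soluble-peptide excretion rate (when that arm is present). Each stage
#' consumes only previously estimated parameters.
#'
#' @param cohort A [cohort_measurements()] data frame with the arms named
#'   in [cohort_arms()].
#' @param pk_data GCV plasma PK series for [fit_gcv_pk()], or `NULL` to use
#'   `gcv_pk` as given.
#' @param gcv_pk List with `ka_gcv`/`kex_gcv` used when `pk_data` is `NULL`.
#' @param K Carrying capacity (mm^3), held fixed throughout.
#' @param n_starts,seed Multi-start settings for [fit_peptide_params()].
#' @inheritParams fit_growth_rate
#' @return A list with `params` (a full [model_parameters()] set), `stages`
#'   (per-stage [fit_result()]s), and `quality` (Pearson R of the
#'   targeted-arm fit).
#' @export
sequential_calibration <- function(cohort, pk_data = NULL, gcv_pk = NULL,
                                   K = 1e4, n_starts = 8, seed = 20210601,
                                   weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  stages <- list()
  g <- fit_growth_rate(cohort, K = K, weights = weights)
  stages$growth_rate <- g$fit
  V0 <- extrapolate_initial_volume(
    g$sigma, cohort, K = K,
    anchor = list(day = g$fit$estimates$anchor_day,
                  volume = g$fit$estimates$V_anchor))
  stages$initial_volume <- fit_result("initial_volume", list(V0 = V0), 0)
  if (!is.null(pk_data)) {
    pk <- fit_gcv_pk(pk_data)
    stages$gcv_pk <- pk$fit
    gcv_pk <- pk
  } else if (is.null(gcv_pk)) {
    stop("stage ordering error: 'gcv_death' needs GCV PK parameters; ",
         "supply pk_data or gcv_pk")
  }
  gd <- fit_gcv_death(cohort, g$sigma, V0, gcv_pk, K = K,
                      weights = weights)
  stages$gcv_death <- gd$fit
  pp <- fit_peptide_params(cohort, g$sigma, V0, gd$lam, gcv_pk, K = K,
                           n_starts = n_starts, seed = seed,
                           weights = weights)
  stages$peptide_params <- pp$fit
  kex_sol <- NA_real_
  if ("soluble_csstresac" %in% as.data.frame(cohort)$arm) {
    se <- refit_soluble_excretion(cohort, g$sigma, V0, pp$D_pep, pp$Kd,
                                  K = K, weights = weights)
    stages$soluble_excretion <- se$fit
    kex_sol <- se$kex_pep_sol
  }
  params <- model_parameters(
    sigma = g$sigma, K = K, V0 = V0, D_pep = pp$D_pep, Kd = pp$Kd,
    lam = gd$lam, kex_pep = pp$kex_pep,
    kex_pep_sol = if (is.na(kex_sol)) 38 else kex_sol,
    ka_gcv = gcv_pk$ka_gcv, kex_gcv = gcv_pk$kex_gcv)
  obs_days <- sort(unique(as.data.frame(cohort)$day))
  times <- sort(unique(c(0, obs_days, 21)))
  fit_arms <- intersect(cohort_arms(), unique(as.data.frame(cohort)$arm))
  trajs <- stats::setNames(
    lapply(fit_arms, function(a) simulate_treatment_arm(params, a, times)),
    fit_arms)
  quality <- fit_quality(trajs, cohort)
  list(params = params, stages = stages, quality = quality)
}
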