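#' Observation noise models
#'
#' Caliper measurements of tumor volume show roughly proportional scatter,
#' so the default is multiplicative lognormal noise with a 10% coefficient
#' of variation, parameterised to be mean-unbiased
#' (`E[noise] = 1`). Additive Gaussian noise (truncated at zero) and
#' noise-free generation are also available.
#'
#' @param kind `"none"`, `"multiplicative_lognormal"`, or
#'   `"additive_gaussian"`.
#' @param scale Coefficient of variation (multiplicative) or SD in mm^3
#'   (additive); must be >= 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal", "none",
                                 "additive_gaussian"),
                        scale = 0.1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0)
  structure(list(kind = kind, scale = scale), class = "noise_model")
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
    none = x,
    multiplicative_lognormal = {
      if (noise$scale == 0) return(x)
      s <- sqrt(log(1 + noise$scale^2))
      x * stats::rlnorm(length(x), meanlog = -s^2 / 2, sdlog = s)
    },
    additive_gaussian =
      pmax(x + stats::rnorm(length(x), sd = noise$scale), 0))
}

#' Generate a synthetic measurement cohort
#'
#' Simulates the deterministic model trajectory for each requested arm under
#' its standard dosing schedule (see [simulate_treatment_arm()]) and draws
#' per-subject volumes at the observation days by perturbing the trajectory
#' with observation noise. The defaults emulate the modelled preclinical
#' design: 10 subjects per arm measured one week after treatment initiation
#' and every other day afterwards (days 15, 17, 19, 21).
#'
#' @param params True [model_parameters()] used for generation.
#' @param arms Arm labels to generate (subset of [cohort_arms()]).
#' @param n_subjects Subjects per arm (>= 1).
#' @param days Observation day grid (non-empty).
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A [cohort_measurements()] data frame.
#' @export
#' @examples
#' coh <- generate_cohort(default_parameters(),
#'                        arms = c("control_gcv_only", "fd_aavp_gcv"),
#'                        n_subjects = 3, noise = noise_model("none"))
#' arm_means(coh)
generate_cohort <- function(params, arms = cohort_arms(), n_subjects = 10,
                            days = c(15, 17, 19, 21),
                            noise = noise_model(), seed = 20210601) {
  stopifnot(n_subjects >= 1)
  if (length(days) == 0) stop("empty observation day grid")
  unknown <- setdiff(arms, cohort_arms())
  if (length(unknown) > 0)
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "))
  days <- sort(unique(days))
  set.seed(seed)
  out <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    arm <- arms[i]
    tf <- max(days, 21)
    traj <- simulate_treatment_arm(params, arm,
                                   sort(unique(c(0, days, tf))))
    v <- traj$V[match(days, traj$time)]
    rows <- data.frame(
      arm = arm,
      subject_id = rep(sprintf("%s_%02d", arm, seq_len(n_subjects)),
                       each = length(days)),
      day = rep(days, times = n_subjects),
      volume_mm3 = apply_noise(rep(v, times = n_subjects), noise),
      stringsAsFactors = FALSE)
    out[[i]] <- rows
  }
  cohort_measurements(do.call(rbind, out))
}

#' Generate synthetic GCV plasma PK samples
#'
#' Bateman-curve concentrations after a single ip dose, sampled at the
#' given times with optional noise; a stand-in for a digitized plasma
#' kinetics curve in the [fit_gcv_pk()] round trip.
#'
#' @param ka,kex Absorption and excretion rate constants (day^-1, > 0).
#' @param c0_ip Initial peritoneal concentration (mg/mm^3).
#' @param sample_times Sampling times (days); default 8 log-spaced points
#'   over 12 hours.
#' @param noise A [noise_model()].
#' @param seed Integer seed (used only when noise is stochastic).
#' @return Data frame with columns `time` and `concentration`.
#' @export
generate_gcv_pk_samples <- function(ka, kex, c0_ip = 0.008,
                                    sample_times = exp(seq(log(0.01),
                                                           log(0.5),
                                                           length.out = 8)),
                                    noise = noise_model("none"),
                                    seed = 20210601) {
  stopifnot(ka > 0, kex > 0)
  set.seed(seed)
  conc <- vapply(sample_times, ip_bateman_concentration, numeric(1),
                 c0_ip = c0_ip, ka = ka, kex = kex)
  data.frame(time = sample_times, concentration = apply_noise(conc, noise))
}
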