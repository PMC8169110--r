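#' One-compartment pharmacokinetic closed forms
#'
#' Exact solutions of the one-compartment pharmacokinetic sub-models, used
#' both as integration oracles and inside the calibration routines.
#'
#' `iv_bolus_concentration()` solves `dC/dt = -kex * C`, `C(0) = C0`
#' (first-order renal clearance after an iv bolus).
#'
#' @param t Time since dose (days, >= 0); vectorized.
#' @param C0 Initial plasma concentration.
#' @param kex Excretion rate constant (day^-1).
#' @return Concentration at `t`, same units as `C0`.
#' @export
#' @examples
#' iv_bolus_concentration(log(2) / 38, 0.8, 38)  # half of 0.8
iv_bolus_concentration <- function(t, C0, kex) {
  stopifnot(is.numeric(t), is.numeric(C0), length(C0) == 1L, C0 >= 0,
            is.numeric(kex), length(kex) == 1L, kex >= 0)
  if (any(t < 0)) stop("t must be >= 0")
  C0 * exp(-kex * t)
}

#' @rdname iv_bolus_concentration
#'
#' @details
#' `ip_bateman_concentration()` is the Bateman function: plasma
#' concentration after an intraperitoneal dose with first-order absorption
#' (`ka`) and first-order excretion (`kex`),
#' `C(t) = ka * C0IP / (ka - kex) * (exp(-kex t) - exp(-ka t))`.
#' At `ka == kex` (within `1e-9` relative) the removable singularity is
#' evaluated by its limit `ka * C0IP * t * exp(-ka t)`.
#'
#' @param c0_ip Initial peritoneal concentration (mg/mm^3).
#' @param ka Absorption rate constant (day^-1, > 0).
#' @export
ip_bateman_concentration <- function(t, c0_ip, ka, kex) {
  stopifnot(is.numeric(t), is.numeric(c0_ip), length(c0_ip) == 1L,
            c0_ip >= 0, is.numeric(ka), length(ka) == 1L, ka > 0,
            is.numeric(kex), length(kex) == 1L, kex > 0)
  if (any(t < 0)) stop("t must be >= 0")
  if (abs(ka - kex) < 1e-9 * ka) {
    ka * c0_ip * t * exp(-ka * t)
  } else {
    ka * c0_ip / (ka - kex) * (exp(-kex * t) - exp(-ka * t))
  }
}

#' @rdname iv_bolus_concentration
#' @details `bateman_peak_time()` returns the time of the Bateman maximum,
#'   `ln(ka/kex) / (ka - kex)` (or `1/ka` in the `ka == kex` limit).
#' @export
bateman_peak_time <- function(ka, kex) {
  stopifnot(ka > 0, kex > 0)
  if (abs(ka - kex) < 1e-9 * ka) 1 / ka else log(ka / kex) / (ka - kex)
}

#' Dose-to-concentration conversion for intraperitoneal administration
#'
#' Converts a weight-normalised ip dose (mg/kg) into the initial peritoneal
#' concentration increment used by the model, assuming the peritoneal fluid
#' volume scales with body weight. With the default mouse context (20 g,
#' 10 ml/kg) an 80 mg/kg dose gives 0.008 mg/mm^3 (1 ml = 1000 mm^3).
#'
#' @param dose Administered dose (mg/kg, >= 0).
#' @param ctx A [dose_conversion_context()].
#' @return Peritoneal concentration increment (mg/mm^3).
#' @export
#' @examples
#' dose_to_peritoneal_concentration(80)  # 0.008
dose_to_peritoneal_concentration <- function(dose,
                                             ctx = dose_conversion_context()) {
  stopifnot(is.numeric(dose), dose >= 0)
  mass_mg <- dose * ctx$body_weight
  volume_mm3 <- ctx$peritoneal_volume_per_kg * ctx$body_weight * 1000
  mass_mg / volume_mm3
}

#' @rdname dose_to_peritoneal_concentration
#' @param body_weight Body weight in kg (default 0.02, a 20 g mouse).
#' @param peritoneal_volume_per_kg Peritoneal fluid volume in ml per kg body
#'   weight (default 10).
#' @export
dose_conversion_context <- function(body_weight = 0.02,
                                    peritoneal_volume_per_kg = 10) {
  if (body_weight <= 0 || peritoneal_volume_per_kg <= 0)
    stop("dose conversion context fields must be > 0")
  list(body_weight = body_weight,
       peritoneal_volume_per_kg = peritoneal_volume_per_kg)
}

#' Elimination half-life in minutes
#'
#' `t_1/2 = ln(2) / kex`, converted from days to minutes (1 day = 1440 min).
#' For the soluble peptide's fitted excretion rate of 38 day^-1 this is
#' about 26 minutes.
#'
#' @param kex Excretion rate constant (day^-1, > 0).
#' @return Half-life in minutes.
#' @export
#' @examples
#' half_life(38)  # ~26.3 min
half_life <- function(kex) {
  stopifnot(is.numeric(kex), length(kex) == 1L)
  if (kex <= 0) stop("kex must be > 0")
  log(2) / kex * 1440
}

#' Steady-state concentration under constant-rate infusion
#'
#' Under `dC/dt = mu * kex - kex * C` the fixed point is `mu`: the infusion
#' constant is parameterised directly as the asymptotic plasma
#' concentration.
#'
#' @param mu Asymptotic infusion concentration (>= 0).
#' @param kex Excretion rate constant (day^-1, > 0).
#' @return The steady-state concentration (equal to `mu`).
#' @export
steady_state_infusion_concentration <- function(mu, kex) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(kex), length(kex) == 1L)
  if (kex <= 0) stop("kex must be > 0")
  mu
}
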