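#' Experimental arm labels
#'
#' The six cohort arms of the modelled preclinical programme:
#' \describe{
#'   \item{`vehicle`}{untreated control.}
#'   \item{`control_peptide`}{unrelated peptide; no modelled effect.}
#'   \item{`control_gcv_only`}{daily ip GCV without any vector, so no
#'     thymidine kinase is present and GCV has no kill effect; pure logistic
#'     growth. Used to fit the growth rate.}
#'   \item{`fd_aavp_gcv`}{untargeted vector plus GCV: the GCV kill term `N`
#'     is active, the peptide kill term `S` is not.}
#'   \item{`csstresac_aavp_gcv`}{targeted vector plus GCV: both kill terms
#'     active; the vector bolus also loads the peptide compartment.}
#'   \item{`soluble_csstresac`}{soluble peptide bolus, no GCV: `S` active
#'     with the soluble excretion rate.}
#' }
#' @return Character vector of arm labels.
#' @export
cohort_arms <- function() {
  c("vehicle", "control_peptide", "control_gcv_only",
    "fd_aavp_gcv", "csstresac_aavp_gcv", "soluble_csstresac")
}

#' Deterministic model trajectory for one experimental arm
#'
#' Maps an arm label to its dosing schedule and active kill terms and
#' integrates the system. The GCV kill applies only in arms that received a
#' vector (thymidine kinase delivered); the peptide kill only in the
#' targeted-vector and soluble-peptide arms.
#'
#' @param params A [model_parameters()] object.
#' @param arm One of [cohort_arms()].
#' @param times Output grid (days).
#' @param schedule Optional [dose_schedule()] overriding the arm default.
#' @param ... Passed to [simulate_system()] (e.g. solver tolerances).
#' @return A `trajectory_series`.
#' @export
simulate_treatment_arm <- function(params, arm, times = seq(0, 21, by = 0.1),
                                   schedule = NULL, ...) {
  if (!arm %in% cohort_arms())
    stop("unknown arm label: '", arm, "' (see cohort_arms())")
  cfg <- switch(arm,
    vehicle = ,
    control_peptide = list(
      schedule = dose_schedule(), mode = "soluble", S = FALSE, N = FALSE),
    control_gcv_only = list(
      schedule = gene_therapy_schedule(include_peptide = FALSE),
      mode = "aavp", S = FALSE, N = FALSE),
    fd_aavp_gcv = list(
      schedule = gene_therapy_schedule(include_peptide = FALSE),
      mode = "aavp", S = FALSE, N = TRUE),
    csstresac_aavp_gcv = list(
      schedule = gene_therapy_schedule(),
      mode = "aavp", S = TRUE, N = TRUE),
    soluble_csstresac = list(
      schedule = soluble_bolus_schedule(),
      mode = "soluble", S = TRUE, N = FALSE))
  if (!is.null(schedule)) cfg$schedule <- schedule
  simulate_system(params, cfg$schedule, times, peptide_mode = cfg$mode,
                  active_S = cfg$S, active_N = cfg$N, ...)
}
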