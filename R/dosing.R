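#' Dose events and schedules
#'
#' A dose event is an instantaneous increment of a compartment
#' concentration at a given time (impulsive dosing): the integrator runs up
#' to the event time, adds `amount` to the named compartment, and restarts.
#' A schedule bundles an ordered list of events with an optional
#' constant-rate infusion of the soluble peptide.
#'
#' @param time Day of administration (>= 0).
#' @param compartment `"peptide_plasma"` (iv peptide/vector bolus, mM) or
#'   `"gcv_peritoneal"` (ip GCV dose, mg/mm^3).
#' @param amount Concentration increment in the compartment's units (>= 0).
#' @return `dose_event()`: a one-row data frame with columns `time`,
#'   `compartment`, `amount`.
#' @export
#' @examples
#' dose_event(5, "peptide_plasma", 0.8)
dose_event <- function(time,
                       compartment = c("peptide_plasma", "gcv_peritoneal"),
                       amount) {
  compartment <- match.arg(compartment)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0,
            is.numeric(amount), length(amount) == 1L, amount >= 0)
  data.frame(time = time, compartment = compartment, amount = amount,
             stringsAsFactors = FALSE)
}

#' @rdname dose_event
#' @param events A data frame of dose events (rows as returned by
#'   [dose_event()]), or `NULL` for none. Sorted by time on construction.
#' @param infusion_mu Asymptotic plasma concentration of the infused soluble
#'   peptide (same units as the peptide compartment); 0 disables infusion.
#'   The infusion rate is `infusion_mu * kex` so that the peptide
#'   compartment relaxes exactly to `infusion_mu`.
#' @param infusion_start Day at which the infusion switches on (default 5).
#' @return `dose_schedule()`: an object of class `dose_schedule`.
#' @export
dose_schedule <- function(events = NULL, infusion_mu = 0, infusion_start = 5) {
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), compartment = character(0),
                         amount = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(events),
            all(c("time", "compartment", "amount") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$time < 0) || any(events$amount < 0))
      stop("dose event times and amounts must be >= 0")
    bad <- setdiff(unique(events$compartment),
                   c("peptide_plasma", "gcv_peritoneal"))
    if (length(bad) > 0)
      stop("unknown dose compartment(s): ", paste(bad, collapse = ", "))
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  stopifnot(is.numeric(infusion_mu), length(infusion_mu) == 1L,
            infusion_mu >= 0,
            is.numeric(infusion_start), length(infusion_start) == 1L)
  structure(list(events = events, infusion_mu = infusion_mu,
                 infusion_start = infusion_start),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat("Dose schedule:", nrow(x$events), "impulsive event(s)")
  if (x$infusion_mu > 0)
    cat(sprintf("; infusion mu = %g from day %g", x$infusion_mu,
                x$infusion_start))
  cat("\n")
  if (nrow(x$events) > 0) print(x$events, ...)
  invisible(x)
}

#' Standard dosing schedules
#'
#' `gene_therapy_schedule()` reproduces the preclinical suicide-gene-therapy
#' regimen: a single iv vector bolus (0.8 mM peptide-equivalent) on day 5
#' after tumor implantation, followed by daily ip GCV doses (0.008 mg/mm^3,
#' i.e. 80 mg/kg in a 20 g mouse) on days 12 through 21 inclusive.
#' `soluble_bolus_schedule()` is a single iv bolus of the soluble peptide.
#' `infusion_schedule()` is a constant-rate soluble-peptide infusion.
#'
#' @param peptide_day Day of the iv peptide/vector bolus.
#' @param peptide_amount Bolus size in peptide concentration units (mM).
#' @param gcv_days Integer days of ip GCV administration.
#' @param gcv_amount Per-dose peritoneal concentration increment (mg/mm^3).
#' @param include_peptide,include_gcv Logical switches to drop either arm of
#'   the regimen (e.g. the GCV-only control receives no vector bolus).
#' @return A `dose_schedule`.
#' @export
gene_therapy_schedule <- function(peptide_day = 5, peptide_amount = 0.8,
                                  gcv_days = 12:21, gcv_amount = 0.008,
                                  include_peptide = TRUE, include_gcv = TRUE) {
  ev <- list()
  if (include_peptide)
    ev <- c(ev, list(dose_event(peptide_day, "peptide_plasma",
                                peptide_amount)))
  if (include_gcv)
    ev <- c(ev, lapply(gcv_days, dose_event, compartment = "gcv_peritoneal",
                       amount = gcv_amount))
  events <- if (length(ev) > 0) do.call(rbind, ev) else NULL
  dose_schedule(events)
}

#' @rdname gene_therapy_schedule
#' @export
soluble_bolus_schedule <- function(peptide_day = 5, peptide_amount = 0.8) {
  dose_schedule(dose_event(peptide_day, "peptide_plasma", peptide_amount))
}

#' @rdname gene_therapy_schedule
#' @param mu Asymptotic infusion concentration.
#' @param start Day the infusion switches on.
#' @export
infusion_schedule <- function(mu = 0.75, start = 5) {
  dose_schedule(NULL, infusion_mu = mu, infusion_start = start)
}
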