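#' Tumor growth and drug-induced death rate terms
#'
#' The tumor volume obeys `dV/dt = G - S - N`: logistic proliferation `G`
#' opposed by a Michaelis-Menten peptide kill term `S` and a kill term `N`
#' linear in plasma GCV. By default the kill terms are per-volume rates
#' multiplied by `V` (`death_scaling = "proportional"`), which keeps every
#' term in mm^3/day and makes `V = 0` absorbing; the literal volume-free
#' reading is available via `death_scaling = "absolute"`.
#'
#' `logistic_growth_rate()` returns `G = sigma * V * (1 - V / K)`.
#'
#' @param V Tumor volume (mm^3, >= 0); vectorized.
#' @param sigma Growth rate constant (day^-1, >= 0).
#' @param K Carrying capacity (mm^3, > 0). `V = K` is a valid equilibrium
#'   input, not an error.
#' @return Rate in mm^3/day.
#' @export
#' @examples
#' logistic_growth_rate(5000, 1, 1e4)  # K/4 = 2500
logistic_growth_rate <- function(V, sigma, K) {
  stopifnot(is.numeric(V), is.numeric(sigma), length(sigma) == 1L,
            sigma >= 0, is.numeric(K), length(K) == 1L)
  if (K <= 0) stop("carrying capacity K must be > 0")
  if (any(V < 0)) stop("tumor volume V must be >= 0")
  sigma * V * (1 - V / K)
}

#' @rdname logistic_growth_rate
#' @details `peptide_death_rate()` returns
#'   `S = V * D_pep * c_pep / (c_pep + Kd)` (proportional scaling): a
#'   saturable receptor-occupancy kill with half-maximal effect at
#'   `c_pep = Kd` and asymptote `D_pep`.
#' @param c_pep Plasma peptide concentration (mM, >= 0); vectorized.
#' @param D_pep Asymptotic kill rate (day^-1, >= 0).
#' @param Kd Dissociation constant (mM, > 0).
#' @param death_scaling `"proportional"` (default, kill scales with `V`) or
#'   `"absolute"` (volume-free literal form).
#' @export
peptide_death_rate <- function(V, c_pep, D_pep, Kd,
                               death_scaling = c("proportional", "absolute")) {
  death_scaling <- match.arg(death_scaling)
  stopifnot(is.numeric(V), is.numeric(c_pep), is.numeric(D_pep),
            length(D_pep) == 1L, D_pep >= 0, is.numeric(Kd),
            length(Kd) == 1L)
  if (Kd <= 0) stop("dissociation constant Kd must be > 0")
  if (any(V < 0) || any(c_pep < 0)) stop("V and c_pep must be >= 0")
  occ <- c_pep / (c_pep + Kd)
  if (death_scaling == "proportional") V * D_pep * occ else D_pep * occ
}

#' @rdname logistic_growth_rate
#' @details `gcv_death_rate()` returns `N = V * lam * c_gcv` (proportional
#'   scaling): GCV phosphorylated by the delivered thymidine kinase kills in
#'   proportion to its plasma concentration.
#' @param c_gcv Plasma GCV concentration (mg/mm^3, >= 0); vectorized.
#' @param lam Kill proportionality constant (day^-1 per mg/mm^3, >= 0).
#' @export
gcv_death_rate <- function(V, c_gcv, lam,
                           death_scaling = c("proportional", "absolute")) {
  death_scaling <- match.arg(death_scaling)
  stopifnot(is.numeric(V), is.numeric(c_gcv), is.numeric(lam),
            length(lam) == 1L, lam >= 0)
  if (any(V < 0) || any(c_gcv < 0)) stop("V and c_gcv must be >= 0")
  if (death_scaling == "proportional") V * lam * c_gcv else lam * c_gcv
}

#' Closed-form logistic growth solution
#'
#' `V(t) = K / (1 + (K/V0 - 1) * exp(-sigma * t))`, the exact solution of
#' the untreated model. Evaluated in the numerically stable decaying form.
#'
#' @param t Time (days); vectorized.
#' @param V0 Initial volume (mm^3, `0 <= V0 <= K`).
#' @param sigma Growth rate constant (day^-1).
#' @param K Carrying capacity (mm^3, > 0).
#' @return Volume at `t` (mm^3).
#' @export
logistic_solution <- function(t, V0, sigma, K) {
  stopifnot(K > 0, V0 >= 0, V0 <= K)
  if (V0 == 0) return(rep(0, length(t)))
  K / (1 + (K / V0 - 1) * exp(-sigma * t))
}

state_names <- function() c("V", "c_pep_p", "c_gcv_p", "c_gcv_ip")

#' Right-hand side of the coupled dosed system
#'
#' Time-derivatives of the full state
#' `(V, c_pep_p, c_gcv_p, c_gcv_ip)`:
#' \itemize{
#'   \item `dV/dt = G - S - N` (see [logistic_growth_rate()]);
#'   \item `dc_pep_p/dt = I(t) - kex * c_pep_p`, with infusion rate
#'     `I(t) = 0` for `t <= infusion_start` and `mu * kex` afterwards, and
#'     `kex` selected by `peptide_mode` (`kex_pep` for the vector-displayed
#'     peptide, `kex_pep_sol` for the soluble peptide);
#'   \item `dc_gcv_p/dt = ka_gcv * c_gcv_ip - kex_gcv * c_gcv_p`;
#'   \item `dc_gcv_ip/dt = -ka_gcv * c_gcv_ip`.
#' }
#' Impulsive doses are not part of the vector field; they are applied as
#' state jumps by [simulate_system()].
#'
#' @param state Named numeric vector with entries `V`, `c_pep_p`, `c_gcv_p`,
#'   `c_gcv_ip`, and optionally `t` (time; defaults to 0).
#' @param params A [model_parameters()] object.
#' @param schedule A [dose_schedule()] (only the infusion fields are used).
#' @param peptide_mode `"aavp"` (vector-displayed) or `"soluble"`.
#' @param death_scaling See [logistic_growth_rate()].
#' @param active_S,active_N Logical switches for the peptide and GCV kill
#'   terms (e.g. arms in which no thymidine kinase was delivered have
#'   `active_N = FALSE`).
#' @return Named numeric vector of derivatives.
#' @export
system_rhs <- function(state, params, schedule = dose_schedule(),
                       peptide_mode = c("aavp", "soluble"),
                       death_scaling = c("proportional", "absolute"),
                       active_S = TRUE, active_N = TRUE) {
  peptide_mode <- match.arg(peptide_mode)
  death_scaling <- match.arg(death_scaling)
  stopifnot(all(state_names() %in% names(state)))
  t <- if ("t" %in% names(state)) unname(state[["t"]]) else 0
  y <- state[state_names()]
  d <- rhs_core(t, unname(y),
                rhs_parms(params, schedule, peptide_mode, death_scaling,
                          active_S, active_N))[[1]]
  names(d) <- state_names()
  d
}

rhs_parms <- function(params, schedule, peptide_mode, death_scaling,
                      active_S, active_N) {
  list(sigma = params$sigma, K = params$K, D_pep = params$D_pep,
       Kd = params$Kd, lam = params$lam,
       kex_eff = if (peptide_mode == "soluble") params$kex_pep_sol
                 else params$kex_pep,
       ka_gcv = params$ka_gcv, kex_gcv = params$kex_gcv,
       infusion_mu = schedule$infusion_mu,
       infusion_start = schedule$infusion_start,
       proportional = (death_scaling == "proportional"),
       s_on = as.numeric(active_S), n_on = as.numeric(active_N))
}

rhs_core <- function(t, y, p) {
  V <- y[1]; cp <- y[2]; cgp <- y[3]; cgi <- y[4]
  G <- p$sigma * V * (1 - V / p$K)
  occ <- cp / (cp + p$Kd)
  if (p$proportional) {
    S <- V * p$D_pep * occ * p$s_on
    N <- V * p$lam * cgp * p$n_on
  } else {
    S <- p$D_pep * occ * p$s_on
    N <- p$lam * cgp * p$n_on
  }
  I <- if (p$infusion_mu > 0 && t > p$infusion_start)
    p$infusion_mu * p$kex_eff else 0
  list(c(G - S - N,
         I - p$kex_eff * cp,
         p$ka_gcv * cgi - p$kex_gcv * cgp,
         -p$ka_gcv * cgi))
}

#' Integrate the dosed tumor growth / treatment system
#'
#' Adaptive stiff-capable integration (`deSolve::lsoda`) of the coupled
#' system, with impulsive doses realised exactly: the trajectory is
#' integrated up to each dose time, the dose amount is added to the target
#' compartment, and integration restarts. The infusion switch-on time is
#' likewise an integration breakpoint. Rows at dose times report the
#' post-dose state.
#'
#' @inheritParams system_rhs
#' @param schedule A [dose_schedule()]; impulsive events outside
#'   `range(times)` are an error.
#' @param times Strictly increasing output grid (days); default 0 to 21 in
#'   steps of 0.1.
#' @param init Optional named initial state (defaults to
#'   `V = params$V0` and all concentrations 0).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data frame of class `trajectory_series` with columns `time`,
#'   `V`, `c_pep_p`, `c_gcv_p`, `c_gcv_ip`.
#' @export
#' @examples
#' p <- default_parameters()
#' traj <- simulate_system(p, gene_therapy_schedule(), seq(0, 21, 0.5))
#' tail(traj, 3)
simulate_system <- function(params, schedule = dose_schedule(),
                            times = seq(0, 21, by = 0.1), init = NULL,
                            peptide_mode = c("aavp", "soluble"),
                            death_scaling = c("proportional", "absolute"),
                            active_S = TRUE, active_N = TRUE,
                            rtol = 1e-8, atol = 1e-10) {
  peptide_mode <- match.arg(peptide_mode)
  death_scaling <- match.arg(death_scaling)
  validate_parameters(params)
  stopifnot(inherits(schedule, "dose_schedule"), is.numeric(times),
            length(times) >= 2L, all(diff(times) > 0))
  y <- c(V = params$V0, c_pep_p = 0, c_gcv_p = 0, c_gcv_ip = 0)
  if (!is.null(init)) {
    stopifnot(all(names(init) %in% state_names()))
    y[names(init)] <- init
    if (any(y < 0)) stop("initial state must be non-negative")
  }
  t0 <- times[1]; tf <- times[length(times)]
  ev <- schedule$events
  if (nrow(ev) > 0 && (any(ev$time < t0) || any(ev$time > tf)))
    stop("dose events must lie within range(times)")
  breaks <- sort(unique(ev$time))
  if (schedule$infusion_mu > 0 &&
      schedule$infusion_start > t0 && schedule$infusion_start < tf)
    breaks <- sort(unique(c(breaks, schedule$infusion_start)))
  # apply any dose falling exactly on the start of the grid
  y <- apply_doses(y, ev[ev$time == t0, , drop = FALSE])
  breaks <- breaks[breaks > t0 & breaks <= tf]
  grid <- sort(unique(c(times, breaks)))
  parms <- rhs_parms(params, schedule, peptide_mode, death_scaling,
                     active_S, active_N)
  bounds <- c(t0, breaks, if (length(breaks) == 0 || max(breaks) < tf) tf)
  bounds <- sort(unique(bounds))
  out <- matrix(NA_real_, nrow = length(grid), ncol = 4,
                dimnames = list(NULL, state_names()))
  out[1, ] <- y
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    seg <- grid[grid >= a & grid <= b]
    if (length(seg) < 2L) seg <- c(a, b)
    sol <- deSolve::lsoda(y, seg, function(t, y, p) rhs_core(t, y, p),
                          parms, rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    keep <- grid > a & grid < b
    if (any(keep))
      out[keep, ] <- sol[match(grid[keep], sol[, 1]), -1, drop = FALSE]
    # post-dose state at the segment end
    y <- apply_doses(y, ev[ev$time == b, , drop = FALSE])
    out[grid == b, ] <- rep(y, each = sum(grid == b))
  }
  # clamp integrator round-off below zero
  out[out < 0 & out > -1e-9] <- 0
  res <- data.frame(time = grid, out)
  res <- res[res$time %in% times, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("trajectory_series", "data.frame"),
            peptide_mode = peptide_mode, death_scaling = death_scaling)
}

apply_doses <- function(y, events) {
  if (nrow(events) == 0) return(y)
  comp_map <- c(peptide_plasma = "c_pep_p", gcv_peritoneal = "c_gcv_ip")
  for (j in seq_len(nrow(events))) {
    tgt <- comp_map[[events$compartment[j]]]
    y[tgt] <- y[tgt] + events$amount[j]
  }
  y
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] days; final V = %.1f mm^3\n",
              nrow(x), x$time[1], x$time[nrow(x)], x$V[nrow(x)]))
  NextMethod()
}
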