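# shared fixtures: reference parameter set and random draws for
# property-style tests

ref_params <- function(...) {
  p <- model_parameters(sigma = 0.2, K = 1e4, V0 = 200, D_pep = 0.016,
                        Kd = 0.75, lam = 60, kex_pep = 0.2,
                        kex_pep_sol = 38, ka_gcv = 12, kex_gcv = 3)
  if (length(list(...)) > 0) p <- update_parameters(p, ...)
  p
}

# random but physically plausible parameter draw (call under a set seed)
random_params <- function() {
  model_parameters(
    sigma = runif(1, 0.05, 1.5), K = 1e4, V0 = runif(1, 50, 2000),
    D_pep = runif(1, 0, 2), Kd = 10^runif(1, -2, 1),
    lam = runif(1, 0, 200), kex_pep = 10^runif(1, -1, 1),
    kex_pep_sol = runif(1, 5, 60), ka_gcv = runif(1, 5, 30),
    kex_gcv = runif(1, 0.5, 5))
}

# independent two-compartment GCV PK oracle: integrate the absorption /
# elimination ODEs directly (no closed form, no package rhs)
gcv_pk_ode_oracle <- function(times, c0_ip, ka, kex) {
  f <- function(t, y, parms)
    list(c(ka * y[2] - kex * y[1], -ka * y[2]))
  out <- deSolve::lsoda(c(cp = 0, cip = c0_ip), times, f, NULL,
                        rtol = 1e-11, atol = 1e-13)
  out[, "cp"]
}
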