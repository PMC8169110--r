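test_that("logistic growth rate matches its closed form and edge cases", {
  expect_equal(logistic_growth_rate(0, 0.5, 1e4), 0)
  expect_equal(logistic_growth_rate(1e4, 0.5, 1e4), 0)
  expect_equal(logistic_growth_rate(5000, 1, 1e4), 2500)
  expect_error(logistic_growth_rate(-1, 0.5, 1e4), "V must be")
  expect_error(logistic_growth_rate(10, 0.5, 0), "K must be")
})

test_that("peptide kill term is saturable with half-max at Kd", {
  expect_equal(peptide_death_rate(100, 0, 2, 0.5), 0)
  expect_equal(peptide_death_rate(1, 0.5, 2, 0.5), 1)  # D_pep / 2
  # asymptote: c_pep far above Kd approaches D_pep
  expect_equal(peptide_death_rate(1, 1e9, 2, 0.5), 2, tolerance = 1e-8)
  # absolute scaling drops the volume factor
  expect_equal(peptide_death_rate(100, 0.5, 2, 0.5, "absolute"), 1)
  expect_error(peptide_death_rate(1, 1, 2, 0), "Kd must be")
})

test_that("GCV kill term is linear in plasma concentration", {
  expect_equal(gcv_death_rate(50, 0, 3), 0)
  expect_equal(gcv_death_rate(50, 0.008, 0), 0)
  expect_equal(gcv_death_rate(1, 0.008, 2), 0.016)
  expect_equal(gcv_death_rate(10, 0.008, 2), 0.16)
  expect_error(gcv_death_rate(1, -0.1, 2), "must be >= 0")
})

test_that("system rhs reduces to pure logistic without drug and is absorbing at V = 0", {
  p <- ref_params()
  s <- c(V = 500, c_pep_p = 0, c_gcv_p = 0, c_gcv_ip = 0)
  d <- system_rhs(s, p)
  expect_equal(unname(d["V"]), logistic_growth_rate(500, p$sigma, p$K))
  expect_equal(unname(d[c("c_pep_p", "c_gcv_p", "c_gcv_ip")]), c(0, 0, 0))
  s0 <- c(V = 0, c_pep_p = 0.4, c_gcv_p = 0.004, c_gcv_ip = 0.002)
  expect_equal(unname(system_rhs(s0, p)["V"]), 0)
})

test_that("rhs concentration derivatives match finite differences of the PK closed forms", {
  p <- ref_params()
  # bolus-only run: peptide bolus at t = 0 and one ip GCV dose at t = 0
  h <- 1e-6
  for (t in c(0.05, 0.2, 1, 3)) {
    cp <- iv_bolus_concentration(t, 0.8, p$kex_pep)
    cgp <- ip_bateman_concentration(t, 0.008, p$ka_gcv, p$kex_gcv)
    cgi <- 0.008 * exp(-p$ka_gcv * t)
    st <- c(t = t, V = 400, c_pep_p = cp, c_gcv_p = cgp, c_gcv_ip = cgi)
    d <- system_rhs(st, p)
    fd_cp <- (iv_bolus_concentration(t + h, 0.8, p$kex_pep) -
                iv_bolus_concentration(t - h, 0.8, p$kex_pep)) / (2 * h)
    fd_cgp <- (ip_bateman_concentration(t + h, 0.008, p$ka_gcv, p$kex_gcv) -
                 ip_bateman_concentration(t - h, 0.008, p$ka_gcv,
                                          p$kex_gcv)) / (2 * h)
    fd_cgi <- (0.008 * exp(-p$ka_gcv * (t + h)) -
                 0.008 * exp(-p$ka_gcv * (t - h))) / (2 * h)
    expect_equal(unname(d["c_pep_p"]), fd_cp, tolerance = 1e-6)
    expect_equal(unname(d["c_gcv_p"]), fd_cgp, tolerance = 1e-6)
    expect_equal(unname(d["c_gcv_ip"]), fd_cgi, tolerance = 1e-6)
  }
})

test_that("dV/dt is monotone non-increasing in each drug concentration at fixed V", {
  p <- ref_params()
  cps <- seq(0, 5, length.out = 20)
  dv <- vapply(cps, function(cc) {
    system_rhs(c(V = 1000, c_pep_p = cc, c_gcv_p = 0, c_gcv_ip = 0),
               p)[["V"]]
  }, numeric(1))
  expect_true(all(diff(dv) <= 0))
  cgs <- seq(0, 0.02, length.out = 20)
  dv <- vapply(cgs, function(cc) {
    system_rhs(c(V = 1000, c_pep_p = 0, c_gcv_p = cc, c_gcv_ip = 0),
               p)[["V"]]
  }, numeric(1))
  expect_true(all(diff(dv) <= 0))
})

test_that("untreated integration matches the logistic closed form to 1e-6 relative", {
  p <- ref_params(D_pep = 0, lam = 0)
  times <- seq(0, 30, by = 0.5)
  tr <- simulate_system(p, dose_schedule(), times)
  expect_equal(tr$V, logistic_solution(times, p$V0, p$sigma, p$K),
               tolerance = 1e-6)
})

test_that("integrated trajectories stay non-negative and below K under random draws", {
  set.seed(42)
  for (i in 1:8) {
    p <- random_params()
    tr <- simulate_system(p, gene_therapy_schedule(), seq(0, 25, 0.25))
    expect_true(all(tr$V >= 0))
    expect_true(all(tr$V <= p$K * (1 + 1e-8)))
    expect_true(all(tr$c_pep_p >= 0))
    expect_true(all(tr$c_gcv_p >= 0))
    expect_true(all(tr$c_gcv_ip >= 0))
  }
})

test_that("impulsive doses appear as exact jumps and peritoneal GCV decays between them", {
  p <- ref_params()
  tr <- simulate_system(p, gene_therapy_schedule(), seq(0, 21, 0.1))
  # post-dose value at day 12 carries the full increment
  v12 <- tr$c_gcv_ip[tr$time == 12]
  expect_gt(v12, 0.008 * 0.999)
  # strictly non-increasing between consecutive dose days
  between <- tr$time > 12 & tr$time < 13
  expect_true(all(diff(tr$c_gcv_ip[between]) <= 0))
  # peptide compartment jumps by I1 = 0.8 at day 5
  i5 <- which(tr$time == 5)
  expect_equal(tr$c_pep_p[i5], tr$c_pep_p[i5 - 1] * 1 + 0.8,
               tolerance = 1e-6)
})

test_that("dose schedule construction validates its inputs", {
  expect_error(dose_event(-1, "peptide_plasma", 0.8))
  expect_error(dose_event(5, "muscle", 0.8))
  ev <- rbind(dose_event(12, "gcv_peritoneal", 0.008),
              dose_event(5, "peptide_plasma", 0.8))
  sch <- dose_schedule(ev)
  expect_equal(sch$events$time, c(5, 12))  # sorted on construction
  expect_error(dose_schedule(ev, infusion_mu = -1))
})
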