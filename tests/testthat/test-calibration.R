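test_that("growth-rate fit recovers sigma from noise-free control data", {
  p <- ref_params(sigma = 0.45, V0 = 250)
  coh <- generate_cohort(p, arms = "control_gcv_only", n_subjects = 3,
                         noise = noise_model("none"))
  g <- fit_growth_rate(coh)
  expect_equal(g$sigma, p$sigma, tolerance = 1e-4)
  expect_true(g$fit$converged)
  expect_lt(g$fit$rss, 1e-4)
})

test_that("flat volumes give sigma near zero and a missing arm names the stage", {
  flat <- cohort_measurements(data.frame(
    arm = "control_gcv_only", subject_id = "s1",
    day = c(15, 17, 19, 21), volume_mm3 = rep(500, 4)))
  expect_lt(fit_growth_rate(flat)$sigma, 1e-3)
  wrong <- cohort_measurements(data.frame(
    arm = "fd_aavp_gcv", subject_id = "s1",
    day = c(15, 17, 19, 21), volume_mm3 = c(500, 600, 700, 800)))
  expect_error(fit_growth_rate(wrong), "growth_rate.*control_gcv_only")
})

test_that("initial volume extrapolates backward through the logistic closed form", {
  p <- ref_params(sigma = 0.45, V0 = 250)
  coh <- generate_cohort(p, arms = "control_gcv_only", n_subjects = 2,
                         noise = noise_model("none"))
  v0 <- extrapolate_initial_volume(p$sigma, coh)
  expect_equal(v0, 250, tolerance = 1e-3)
  # identity when the earliest observation is at t = 0
  at0 <- cohort_measurements(data.frame(
    arm = "control_gcv_only", subject_id = "s1", day = c(0, 15, 21),
    volume_mm3 = logistic_solution(c(0, 15, 21), 250, 0.45, 1e4)))
  expect_equal(extrapolate_initial_volume(0.45, at0), 250,
               tolerance = 1e-10)
  # sigma = 0: no growth, V0 equals the earliest observation
  expect_equal(extrapolate_initial_volume(0, at0), 250)
})

test_that("Bateman fit round-trips noise-free GCV PK parameters", {
  pk <- generate_gcv_pk_samples(12, 3, 0.008)
  f <- fit_gcv_pk(pk)
  expect_equal(f$ka_gcv, 12, tolerance = 1e-3)
  expect_equal(f$kex_gcv, 3, tolerance = 1e-3)
  expect_equal(f$c0_ip, 0.008, tolerance = 1e-3)
  # with the amplitude pinned to the known dose
  f2 <- fit_gcv_pk(pk, c0_ip = 0.008)
  expect_equal(f2$ka_gcv, 12, tolerance = 1e-3)
  expect_equal(f2$kex_gcv, 3, tolerance = 1e-3)
})

test_that("Bateman exchange ambiguity resolves to ka > kex with an identical curve", {
  pk <- generate_gcv_pk_samples(3, 12, 0.008)  # flipped labels
  f <- fit_gcv_pk(pk)
  expect_gt(f$ka_gcv, f$kex_gcv)
  expect_equal(f$ka_gcv, 12, tolerance = 1e-3)
  expect_equal(f$kex_gcv, 3, tolerance = 1e-3)
  refit_curve <- vapply(pk$time, ip_bateman_concentration, numeric(1),
                        f$c0_ip, f$ka_gcv, f$kex_gcv)
  expect_equal(refit_curve, pk$concentration, tolerance = 1e-6)
})

test_that("Bateman fit under 5% noise has median relative error below 10%", {
  errs <- t(vapply(1:200, function(s) {
    pk <- generate_gcv_pk_samples(12, 3, 0.008, seed = s,
                                  noise = noise_model(scale = 0.05))
    f <- suppressWarnings(fit_gcv_pk(pk, c0_ip = 0.008))
    c(abs(f$ka_gcv - 12) / 12, abs(f$kex_gcv - 3) / 3)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})

test_that("non-unimodal PK samples warn rather than fail", {
  pk <- data.frame(time = c(0.2, 0.4, 0.6, 0.8),
                   concentration = c(0.004, 0.003, 0.002, 0.001))
  expect_warning(fit_gcv_pk(pk), "peak")
  expect_error(fit_gcv_pk(pk[1:3, ]), "4 post-dose samples")
})

test_that("GCV kill constant is recovered at zero noise and vanishes for identical arms", {
  p <- ref_params(lam = 3)
  coh <- generate_cohort(p, arms = c("control_gcv_only", "fd_aavp_gcv"),
                         n_subjects = 2, noise = noise_model("none"))
  gd <- fit_gcv_death(coh, p$sigma, p$V0,
                      list(ka_gcv = p$ka_gcv, kex_gcv = p$kex_gcv))
  expect_equal(gd$lam, 3, tolerance = 1e-3)
  # untreated-looking arm: relabel the control data as the fd arm
  ctl <- as.data.frame(coh)[as.data.frame(coh)$arm == "control_gcv_only", ]
  ctl$arm <- "fd_aavp_gcv"
  gd0 <- fit_gcv_death(cohort_measurements(ctl), p$sigma, p$V0,
                       list(ka_gcv = p$ka_gcv, kex_gcv = p$kex_gcv))
  expect_lt(gd0$lam, 1e-3)
})

test_that("peptide triple fit reproduces the treated-arm curve at zero noise", {
  p <- ref_params()
  coh <- generate_cohort(p, arms = "csstresac_aavp_gcv", n_subjects = 2,
                         noise = noise_model("none"))
  pp <- fit_peptide_params(coh, p$sigma, p$V0, p$lam,
                           list(ka_gcv = p$ka_gcv, kex_gcv = p$kex_gcv))
  fitted <- update_parameters(p, D_pep = pp$D_pep, Kd = pp$Kd,
                              kex_pep = pp$kex_pep)
  days <- c(0, 15, 17, 19, 21)
  v_true <- simulate_treatment_arm(p, "csstresac_aavp_gcv", days)$V
  v_fit <- simulate_treatment_arm(fitted, "csstresac_aavp_gcv", days)$V
  expect_lt(sqrt(mean((v_true - v_fit)^2)), 1)
})

test_that("a treated arm with no peptide effect yields D_pep near zero", {
  p <- ref_params(D_pep = 1e-9)
  coh <- generate_cohort(p, arms = "csstresac_aavp_gcv", n_subjects = 2,
                         noise = noise_model("none"))
  pp <- fit_peptide_params(coh, p$sigma, p$V0, p$lam,
                           list(ka_gcv = p$ka_gcv, kex_gcv = p$kex_gcv))
  # fitted kill at the bolus concentration is negligible
  expect_lt(pp$D_pep * 0.8 / (0.8 + pp$Kd), 1e-3)
})

test_that("Kd profile likelihood brackets the generating value", {
  p <- ref_params()
  coh <- generate_cohort(p, arms = "csstresac_aavp_gcv", n_subjects = 2,
                         noise = noise_model("none"))
  m <- arm_means(coh, "csstresac_aavp_gcv")
  sch <- gene_therapy_schedule()
  profile_rss <- vapply(c(0.25, 0.75, 2.25), function(kd) {
    res_fn <- function(par) {
      pr <- update_parameters(p, D_pep = exp(par[1]), Kd = kd,
                              kex_pep = exp(par[2]))
      tr <- simulate_treatment_arm(pr, "csstresac_aavp_gcv",
                                   c(0, m$day))
      tr$V[match(m$day, tr$time)] - m$mean_mm3
    }
    f <- minpack.lm::nls.lm(
      par = c(log(0.05), log(0.5)), fn = res_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                           maxiter = 200))
    sum(f$fvec^2)
  }, numeric(1))
  expect_lt(profile_rss[2], profile_rss[1])
  expect_lt(profile_rss[2], profile_rss[3])
})

test_that("soluble excretion rate round-trips and implies the ~26 min half-life", {
  p <- ref_params()
  coh <- generate_cohort(p, arms = "soluble_csstresac", n_subjects = 2,
                         noise = noise_model("none"))
  se <- refit_soluble_excretion(coh, p$sigma, p$V0, p$D_pep, p$Kd)
  expect_equal(se$kex_pep_sol, 38, tolerance = 0.05)
  expect_equal(half_life(se$kex_pep_sol), 26, tolerance = 0.05)
})

test_that("a soluble arm indistinguishable from vehicle drives kex to its upper bound", {
  p <- ref_params(D_pep = 1e-12)  # generator: effectively untreated
  coh <- generate_cohort(p, arms = "soluble_csstresac", n_subjects = 2,
                         noise = noise_model("none"))
  expect_warning(
    se <- refit_soluble_excretion(coh, p$sigma, p$V0, D_pep = 0.036,
                                  Kd = 0.75),
    "upper bound")
  expect_gt(se$kex_pep_sol, 900)
})

test_that("Pearson fit quality matches the textbook formula and flags degeneracies", {
  x <- c(150, 320, 610, 980)
  y <- c(180, 300, 700, 900)
  traj <- data.frame(time = c(10, 12, 14, 16), V = x)
  coh <- cohort_measurements(data.frame(
    arm = "csstresac_aavp_gcv", subject_id = "s1",
    day = c(10, 12, 14, 16), volume_mm3 = y))
  q <- fit_quality(traj, coh, "csstresac_aavp_gcv")
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(q$R, r_hand)
  # perfect agreement and perfect anti-correlation
  coh_eq <- cohort_measurements(data.frame(
    arm = "a", subject_id = "s1", day = traj$time, volume_mm3 = x))
  expect_equal(fit_quality(traj, coh_eq, "a")$R, 1)
  coh_neg <- cohort_measurements(data.frame(
    arm = "a", subject_id = "s1", day = traj$time, volume_mm3 = 2000 - x))
  expect_equal(fit_quality(traj, coh_neg, "a")$R, -1)
  coh_const <- cohort_measurements(data.frame(
    arm = "a", subject_id = "s1", day = traj$time, volume_mm3 = rep(5, 4)))
  expect_error(fit_quality(traj, coh_const, "a"), "zero variance")
  expect_error(fit_quality(traj, coh_eq[1:2, ], "a"), ">= 3 matched")
})

test_that("stage ordering is enforced by the sequential driver", {
  p <- ref_params()
  coh <- generate_cohort(p, arms = "control_gcv_only", n_subjects = 2,
                         noise = noise_model("none"))
  expect_error(sequential_calibration(coh), "stage ordering.*gcv_death|GCV PK")
})

test_that("cohort CSV round-trips and malformed input is rejected", {
  p <- ref_params()
  coh <- generate_cohort(p, arms = c("vehicle", "control_gcv_only"),
                         n_subjects = 2, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("arm,subject,day", "a,1,2"), bad)
  expect_error(read_cohort(bad), "lacks column")
  dup <- data.frame(arm = "a", subject_id = "s", day = c(1, 1),
                    volume_mm3 = c(10, 11))
  expect_error(cohort_measurements(dup), "duplicate")
})
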