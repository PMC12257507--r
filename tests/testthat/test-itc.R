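albumin <- itc_scenario("albumin")
insulin <- itc_scenario("insulin")

test_that("forward isotherm obeys its analytic limits", {
  # zero enthalpy -> exactly zero heats
  p0 <- binding_parameters(N = 0.25, K = 1e4, dH = 0)
  expect_true(all(one_site_heats(p0, albumin$schedule)$raw_heat == 0))

  # very large K, first injections: all titrant binds, normalized -> dH
  tight <- binding_parameters(N = 0.25, K = 1e9, dH = -100)
  tg <- one_site_heats(tight, albumin$schedule)
  expect_equal(tg$normalized[1], -100, tolerance = 1e-4)
  expect_equal(tg$normalized[2], -100, tolerance = 1e-4)

  # strong titrant excess: normalized heat -> 0 and cumulative raw heat
  # approaches the saturation capacity N * M0 * V0 * dH
  long <- titration_schedule(injection_volumes = 10e-6, n_injections = 90,
                             cell_volume = 1.42e-3, syringe_conc = 2.88,
                             cell_conc0 = 1.5)
  tgl <- one_site_heats(albumin$params, long)
  # deep in titrant excess the per-gram heat is a small fraction of dH
  # (the residue is the slow displacement-driven drift, not binding)
  expect_lt(abs(tgl$normalized[90]), 0.01 * abs(albumin$params$dH))
  cap <- albumin$params$N * 1.5 * 1.42e-3 * albumin$params$dH
  vtot <- sum(long$injection_volumes)
  expect_equal(sum(tgl$raw_heat), cap,
               tolerance = vtot / (2 * long$cell_volume))

  expect_error(binding_parameters(N = -1, K = 1e4, dH = -10), "N")
  expect_error(binding_parameters(N = 0.2, K = 0, dH = -10), "K")
})

test_that("closed-form heats agree with a numerical equilibrium oracle", {
  for (scen in list(albumin, insulin)) {
    Q_oracle <- oracle_cumulative_heats(scen$params, scen$schedule)
    tg <- one_site_heats(scen$params, scen$schedule)
    dV <- scen$schedule$injection_volumes
    V0 <- scen$schedule$cell_volume
    Qprev <- c(0, Q_oracle[-length(Q_oracle)])
    dQ_oracle <- Q_oracle - Qprev + (dV / V0) * (Q_oracle + Qprev) / 2
    expect_equal(tg$raw_heat, dQ_oracle, tolerance = 1e-8)
  }
})

test_that("blank subtraction is linear and renormalizes", {
  tg <- one_site_heats(albumin$params, albumin$schedule)
  zeros <- new_thermogram(rep(0, 28), albumin$schedule)
  expect_equal(subtract_blank(tg, zeros)$raw_heat, tg$raw_heat)
  expect_true(all(subtract_blank(tg, tg)$raw_heat == 0))

  set.seed(17)
  for (i in 1:5) {
    a <- new_thermogram(rnorm(28), albumin$schedule)
    b <- new_thermogram(rnorm(28), albumin$schedule)
    ab <- new_thermogram(a$raw_heat + b$raw_heat, albumin$schedule)
    back <- subtract_blank(ab, b)
    expect_equal(back$raw_heat, a$raw_heat, tolerance = 1e-12)
    expect_equal(back$normalized,
                 back$raw_heat / (2.88 * albumin$schedule$injection_volumes))
  }
  short <- titration_schedule(injection_volumes = 10e-6, n_injections = 5,
                              syringe_conc = 2.88, cell_conc0 = 1.5)
  expect_error(subtract_blank(tg, new_thermogram(rep(0, 5), short)),
               "mismatch")
})

test_that("normalized heats are monotone toward zero past the equivalence point", {
  y <- one_site_heats(albumin$params, albumin$schedule)$normalized
  i_eq <- which.max(diff(y))  # steepest rise of an exothermic series
  tail <- y[(i_eq + 1):length(y)]
  expect_true(all(diff(tail) >= -1e-9))
})

test_that("noiseless fits recover generating parameters to 4 significant figures", {
  for (scen in list(albumin, insulin)) {
    fit <- fit_one_site(one_site_heats(scen$params, scen$schedule))
    expect_true(fit$converged)
    expect_equal(fit$N, scen$params$N, tolerance = 1e-4)
    expect_equal(fit$K, scen$params$K, tolerance = 1e-4)
    expect_equal(fit$dH, scen$params$dH, tolerance = 1e-4)
    expect_true(all(is.finite(unlist(fit$se))))
  }
})

test_that("fitting is invariant to jointly rescaling the schedule", {
  # doubling both concentrations and refitting the regenerated dataset
  # returns the same parameters the rescaled model was generated with
  sched2 <- titration_schedule(injection_volumes = 10e-6,
                               n_injections = 28, cell_volume = 1.42e-3,
                               syringe_conc = 2 * 2.88, cell_conc0 = 2 * 1.5)
  fit2 <- fit_one_site(one_site_heats(albumin$params, sched2))
  expect_equal(fit2$N, albumin$params$N, tolerance = 1e-4)
  expect_equal(fit2$K, albumin$params$K, tolerance = 1e-4)
  expect_equal(fit2$dH, albumin$params$dH, tolerance = 1e-4)
})

test_that("recovery on an identifiable titration is accurate and sharpens with less noise", {
  # moderate c-value scenario (K * N * M0 ~ 50): all three parameters are
  # information-rich, so 5% noise keeps every median error under 5%
  sched <- titration_schedule(injection_volumes = 10e-6, n_injections = 28,
                              cell_volume = 1.42e-3, syringe_conc = 2.88,
                              cell_conc0 = 1.5)
  truth <- binding_parameters(N = 0.25, K = 135, dH = -150)
  est <- function(noise, seeds) {
    t(vapply(seeds, function(s) {
      g <- generate_itc(truth, sched, noise_sd = noise, seed = s)
      f <- suppressWarnings(fit_one_site(g$thermogram))
      c(f$N, f$K, f$dH)
    }, numeric(3)))
  }
  e5 <- est(0.05, 1:60)
  med5 <- apply(e5, 2, median)
  rel5 <- abs(med5 / c(0.25, 135, -150) - 1)
  expect_true(all(rel5 < 0.05))

  # at the albumin conditions N and dH stay recoverable to < 5% even
  # though the extreme c-value washes out the K information (see the
  # methods vignette); errors shrink as the noise drops for all three
  alb <- function(noise, seeds) {
    t(vapply(seeds, function(s) {
      g <- generate_itc(albumin$params, albumin$schedule, noise_sd = noise,
                        seed = s)
      f <- suppressWarnings(fit_one_site(g$thermogram))
      c(f$N, f$K, f$dH)
    }, numeric(3)))
  }
  a5 <- alb(0.05, 1:60)
  meda <- apply(a5, 2, median)
  expect_lt(abs(meda[1] / 0.246 - 1), 0.05)
  expect_lt(abs(meda[3] / -163.4 - 1), 0.05)

  a1 <- alb(0.01, 1:60)
  for (j in 1:3) {
    err5 <- median(abs(a5[, j] / unlist(albumin$params[c("N", "K", "dH")])[j] - 1))
    err1 <- median(abs(a1[, j] / unlist(albumin$params[c("N", "K", "dH")])[j] - 1))
    expect_lt(err1, err5)
  }
})

test_that("entropy derivation reproduces the tabulated values and its limits", {
  expect_equal(entropy_from_fit(-163.4, 7.55e4, 310.15), 21.8,
               tolerance = 0.05 / 21.8)
  expect_equal(entropy_from_fit(-9.706, 2.87e4, 310.15), 20.4,
               tolerance = 0.05 / 20.4)
  # K = 1: dS = dH / T exactly
  expect_equal(entropy_from_fit(-100, 1, 300), -100 / 300)
  expect_error(entropy_from_fit(-100, 0), "K")
  # fitted parameters carry a consistent derived entropy
  fit <- fit_one_site(one_site_heats(albumin$params, albumin$schedule))
  expect_equal(fit$dS, entropy_from_fit(fit$dH, fit$K, 310.15))
})

test_that("thermogram CSV round trip preserves heats and schedule", {
  g <- generate_itc(albumin$params, albumin$schedule, noise_sd = 0.01,
                    seed = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_thermogram_csv(g$thermogram, csv)
  back <- read_thermogram_csv(csv, albumin$schedule)
  expect_equal(back$raw_heat, g$thermogram$raw_heat, tolerance = 1e-9)
  expect_equal(back$normalized, g$thermogram$normalized, tolerance = 1e-9)
})
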