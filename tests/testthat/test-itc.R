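lamin_schedule <- function() titration_schedule(15e-6, 100e-6)
dna_schedule <- function() titration_schedule(10e-6, 33e-6)

test_that("zero-enthalpy titrations produce pure offset heats", {
  iso <- simulate_isotherm(lamin_schedule(), kd = 1e-6, dh = 0, n = 0.5,
                           dilution_offset = -0.37)
  expect_equal(iso$heats, rep(-0.37, 29))
  expect_length(iso$molar_ratio, 29)
  expect_true(all(diff(iso$molar_ratio) > 0))
})

test_that("tight binding follows stoichiometric mole bookkeeping", {
  sch <- lamin_schedule()
  dh <- -12
  iso <- simulate_isotherm(sch, kd = 1e-15, dh = dh, n = 0.5,
                           dilution_offset = 0.2)
  # oracle: before saturation every injected mole binds; the heat of
  # injection i is dh * (moles of titrant added to the cell), computed
  # here by independent dilution bookkeeping
  V0 <- 1.4e-3; dV <- 10e-6
  xt <- 0; xt_prev <- 0
  moles_added <- numeric(29)
  for (i in 1:29) {
    xt <- xt * (1 - dV / V0) + 100e-6 * dV / V0
    moles_added[i] <- V0 * (xt - xt_prev + dV / V0 * (xt + xt_prev) / 2)
    xt_prev <- xt
  }
  pre <- 1:8    # well before the n = 0.5 equivalence point (~inj 11)
  expect_equal(iso$heats[pre], dh * moles_added[pre] * 1e9 + 0.2,
               tolerance = 1e-6)
  post <- 25:29 # after saturation only the displacement correction remains
  expect_lt(max(abs(iso$heats[post] - 0.2)), 0.005)
  # crossover sits at molar ratio ~ n
  drop_i <- which.max(diff(iso$heats))   # steepest rise back to baseline
  expect_lt(abs(iso$molar_ratio[drop_i] - 0.5), 0.08)
})

test_that("noiseless lamin and DNA titrations round-trip through the fitter", {
  iso <- simulate_isotherm(lamin_schedule(), kd = 2.7e-6, dh = -10, n = 0.5)
  fit <- fit_isotherm(iso, fix_n = 0.5)
  expect_lt(abs(fit$kd - 2.7e-6) / 2.7e-6, 0.01)
  expect_lt(abs(fit$dh - (-10)) / 10, 0.01)

  iso2 <- simulate_isotherm(dna_schedule(), kd = 16.3e-9, dh = -18.1,
                            n = 0.5)
  fit2 <- fit_isotherm(iso2)            # stoichiometry floated
  expect_lt(abs(fit2$kd - 16.3e-9) / 16.3e-9, 0.01)
  expect_lt(abs(fit2$dh - (-18.1)) / 18.1, 0.01)
  expect_lt(abs(fit2$n - 0.5), 0.01)
})

test_that("round-trip identity holds across the Kd and c-value range", {
  for (kd in c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5)) {
    cell <- 50 * kd               # c-value 50 at n = 1
    sch <- titration_schedule(cell, 10 * cell)
    iso <- simulate_isotherm(sch, kd = kd, dh = -15, n = 1,
                             dilution_offset = 0.1)
    fit <- fit_isotherm(iso)
    expect_lt(abs(fit$kd - kd) / kd, 0.01)
    expect_lt(abs(fit$dh - (-15)) / 15, 0.01)
    expect_lt(abs(fit$dilution_offset - 0.1), 0.01)
    expect_lt(abs(fit$dg - fit$dh - fit$entropic_penalty), 1e-6)
  }
})

test_that("degenerate isotherms raise identifiability errors", {
  iso <- simulate_isotherm(lamin_schedule(), kd = 1e-6, dh = 0, n = 0.5,
                           dilution_offset = 1.0)
  expect_error(fit_isotherm(iso), "unidentifiable|flat")
  short <- simulate_isotherm(titration_schedule(15e-6, 100e-6,
                                                injection_volumes = rep(10, 4)),
                             kd = 1e-6, dh = -10, n = 0.5)
  expect_error(fit_isotherm(short), ">= 5")
  expect_error(titration_schedule(15e-6, 100e-6,
                                  injection_volumes = 1500),
               "schedule error")
})

test_that("low c-value fits warn but still recover", {
  sch <- titration_schedule(15e-6, 100e-6)
  iso <- simulate_isotherm(sch, kd = 9.0e-6, dh = -10, n = 0.5)
  expect_warning(fit <- fit_isotherm(iso, fix_n = 0.5), "c-value")
  expect_lt(abs(fit$kd - 9.0e-6) / 9.0e-6, 0.01)
})

test_that("free energy, entropic penalty and fold changes match closed forms", {
  expect_equal(gibbs_from_kd(1, 288), 0)
  expect_equal(gibbs_from_kd(117e-9, 288), -9.1, tolerance = 0.05 / 9.1)
  expect_equal(gibbs_from_kd(16.3e-9, 288), -10.3, tolerance = 0.05 / 10.3)
  expect_error(gibbs_from_kd(-1e-9), "domain error")

  expect_equal(entropic_penalty(gibbs_from_kd(117e-9, 288), -49.5), 40.4,
               tolerance = 0.1 / 40.4)
  expect_equal(entropic_penalty(gibbs_from_kd(16.3e-9, 288), -18.1), 7.81,
               tolerance = 0.1 / 7.81)
  expect_equal(entropic_penalty(-5, -5), 0)

  fc <- affinity_fold_change(117e-9, 16.3e-9)
  expect_equal(fc$ratio, 7.18, tolerance = 0.01)
  expect_equal(fc$fold, 7)
  expect_equal(fc$direction, "tighter")
  fc2 <- affinity_fold_change(2.7e-6, 9.0e-6)
  expect_equal(fc2$ratio, 0.30, tolerance = 0.01)
  expect_equal(fc2$fold, 3)
  expect_equal(fc2$direction, "weaker")
  expect_equal(affinity_fold_change(1e-6, 1e-6)$ratio, 1)
  expect_error(affinity_fold_change(0, 1e-6), "domain error")
})

test_that("noisy replicate fits are unbiased with realistic dispersion", {
  sch <- dna_schedule()
  kds <- vapply(1:100, function(i) {
    iso <- simulate_isotherm(sch, kd = 16.3e-9, dh = -18.1, n = 0.5,
                             noise_sd = 0.2, seed = 5000 + i)
    fit_isotherm(iso, fix_n = 0.5)$kd
  }, numeric(1))
  # central tendency on the log scale (Kd is a positive scale parameter
  # with a right-skewed sampling distribution)
  expect_lt(abs(exp(mean(log(kds))) - 16.3e-9) / 16.3e-9, 0.05)
  # printed replicate uncertainty is +/- 5.7 nM on 16.3 nM: same order
  expect_gt(sd(kds), 0.1e-9)
  expect_lt(sd(kds), 20e-9)
})

test_that("isotherms round-trip through TSV", {
  iso <- simulate_isotherm(lamin_schedule(), kd = 2.7e-6, dh = -10,
                           n = 0.5, dilution_offset = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_isotherm_tsv(iso, path)
  back <- read_isotherm_tsv(path)
  expect_equal(back$heats, iso$heats, tolerance = 1e-9)
  expect_equal(back$schedule$cell_concentration, 15e-6)
  fit <- fit_isotherm(back, fix_n = 0.5)
  expect_lt(abs(fit$kd - 2.7e-6) / 2.7e-6, 0.01)
})
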