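# Calorimetric feature extraction: glass transition, CRR size, enthalpy
# recovery, cold crystallization, melting deconvolution, glass fraction.

test_that("a noiseless logistic step is located to grid resolution", {
  sim <- gen_thermogram(tg = list(mid = 55.2, delta_cp = 0.45, width = 4),
                        t_range = c(30, 80), t_step = 0.05, noise = 0)
  gt <- detect_glass_transition(sim$trace)
  expect_equal(gt$tg_mid, 55.2, tolerance = 0.05)
  expect_equal(gt$delta_cp, 0.45, tolerance = 0.005)
  # tangent construction on a logistic of scale w/4 gives width = 4*scale
  expect_equal(gt$width, 4, tolerance = 0.1)
  expect_lt(gt$tg_onset, gt$tg_mid)
  expect_gt(gt$tg_end, gt$tg_mid)
})

test_that("flat traces and sub-noise steps are rejected", {
  flat <- gen_thermogram(tg = NULL, t_range = c(30, 80), t_step = 0.05,
                         noise = 0.003, seed = 3)
  expect_error(detect_glass_transition(flat$trace), "no glass-transition")
  tiny <- gen_thermogram(tg = list(mid = 55, delta_cp = 0.01, width = 4),
                         t_range = c(30, 80), t_step = 0.05, noise = 0.01,
                         seed = 4)
  expect_error(detect_glass_transition(tiny$trace), "no glass-transition")
})

test_that("delta_Cp is unbiased on sloping baselines", {
  sim <- gen_thermogram(tg = list(mid = 55.2, delta_cp = 0.45, width = 4),
                        t_range = c(30, 80), t_step = 0.05,
                        baseline = c(0.2, 0.01), noise = 0)
  gt <- detect_glass_transition(sim$trace)
  expect_equal(gt$delta_cp, 0.45, tolerance = 0.009)  # within 2%
})

test_that("CRR size converts units correctly and obeys the width scaling", {
  gt <- list(tg_onset = 328.4 - 273.15, width = 4.0)
  L <- crr_size(gt, rho = 1.41, cpg = 1.62, cpl = 2.07)
  expect_equal(L, 2.037431, tolerance = 1e-6)  # nm, frozen SI evaluation
  gt2 <- list(tg_onset = gt$tg_onset, width = 8.0)
  expect_equal(crr_size(gt2, 1.41, 1.62, 2.07) / L, 2^(-2 / 3),
               tolerance = 1e-12)
  # detected transition feeds through end to end, landing near 2 nm
  sim <- gen_thermogram(tg = list(mid = 55.2, delta_cp = 0.45, width = 4),
                        t_range = c(30, 80), t_step = 0.05, noise = 0)
  L2 <- crr_size(detect_glass_transition(sim$trace), 1.41, 1.62, 2.07)
  expect_gt(L2, 1); expect_lt(L2, 3)
})

test_that("noiseless enthalpy recovery is fitted exactly, tau^beta matches the table", {
  # design points from the enthalpy-recovery table (tau minutes, beta)
  cases <- list(c(4870, 0.48), c(1890, 0.87), c(2430, 0.67))
  for (cs in cases) {
    sim <- gen_enthalpy_recovery(cs[1], cs[2], dh_inf = 9.09, noise = 0,
                                 seed = 1)
    kf <- fit_enthalpy_recovery(sim$series, tg = 55.2, delta_cp = 0.45,
                                dh_inf = 9.09)
    expect_equal(kf$tau_alpha, cs[1], tolerance = 1e-5)
    expect_equal(kf$beta_kww, cs[2], tolerance = 1e-5)
    expect_equal(kf$unit, "min")
    expect_equal(kf$tau_beta, cs[1]^cs[2], tolerance = 1e-4)
  }
})

test_that("noisy enthalpy recovery meets the 10%/0.05 recovery tolerance", {
  for (s in 1:5) {
    sim <- gen_enthalpy_recovery(4870, 0.48, dh_inf = 9.09, noise = 0.03,
                                 seed = s)
    kf <- fit_enthalpy_recovery(sim$series, tg = 55.2, delta_cp = 0.45,
                                dh_inf = 9.09)
    expect_equal(kf$tau_alpha, 4870, tolerance = 0.10)
    expect_lt(abs(kf$beta_kww - 0.48), 0.05)  # 0.05 absolute on beta
  }
})

test_that("over-recovery raises an error naming the offending times", {
  series <- enthalpy_recovery_series(35, c(10, 100, 1000, 10000),
                                     c(1, 5, 9.5, 10))
  expect_error(fit_enthalpy_recovery(series, tg = 55.2, delta_cp = 0.45,
                                     dh_inf = 9.0),
               "over-recovery.*1000.*10000")
})

test_that("cold-crystallization area and onset are extracted accurately", {
  sim <- gen_thermogram(tg = NULL,
                        exo = list(center = 117, area_jg = 40.6, sd = 3),
                        t_range = c(90, 145), t_step = 0.05, noise = 0)
  cc <- cold_crystallization_features(sim$trace)
  expect_true(cc$detected)
  expect_equal(cc$enthalpy, 40.6, tolerance = 0.01)
  # tangent at the inflection of a Gaussian meets the baseline one sd
  # before the inflection: onset = center - 2*sd
  expect_equal(cc$t_onset, 111, tolerance = 0.3)
  # absence of a peak is an empty result, not an error
  flat <- gen_thermogram(tg = NULL, t_range = c(90, 145), t_step = 0.05,
                         noise = 0.002, seed = 7)
  expect_false(cold_crystallization_features(flat$trace)$detected)
})

test_that("enthalpy integration is invariant to an added linear ramp", {
  sim <- gen_thermogram(tg = NULL,
                        exo = list(center = 117, area_jg = 40.6, sd = 3),
                        t_range = c(90, 145), t_step = 0.05, noise = 0)
  tr <- sim$trace
  ramp <- thermogram(tr$temperature,
                     tr$heat_flow + 0.5 - 0.02 * tr$temperature,
                     scan_rate = tr$scan_rate)
  a <- cold_crystallization_features(tr)$enthalpy
  b <- cold_crystallization_features(ramp)$enthalpy
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("two overlapping exotherms give a single onset at the first peak", {
  T <- seq(90, 145, by = 0.05)
  rate_s <- 10 / 60
  y <- 20 * rate_s / (2 * sqrt(2 * pi)) *
    (exp(-(T - 112)^2 / 8) + exp(-(T - 120)^2 / 8))
  cc <- cold_crystallization_features(thermogram(T, y, scan_rate = 10))
  expect_true(cc$detected)
  expect_equal(cc$t_onset, 112 - 4, tolerance = 0.5)
})

test_that("melting deconvolution recovers areas and the Form I fraction", {
  sim <- gen_thermogram(tg = NULL,
                        melt = list(centers = c(162, 164),
                                    areas_jg = c(30, 10),
                                    half_widths = c(0.5, 0.5)),
                        t_range = c(150, 175), t_step = 0.02, noise = 0)
  md <- deconvolute_melting(sim$trace, centers_init = c(162, 164))
  expect_false(md$degenerate)
  expect_equal(md$form1_fraction, 0.25, tolerance = 0.01)
  expect_equal(md$peaks$center, c(162, 164), tolerance = 0.05)
  # fraction conservation: shares of the two forms sum to one exactly
  form3 <- md$peaks$area[1] / sum(md$peaks$area)
  expect_identical(md$form1_fraction + form3, 1)
  # equal areas split 0.5 by symmetry
  sym <- gen_thermogram(tg = NULL,
                        melt = list(centers = c(162, 164),
                                    areas_jg = c(20, 20),
                                    half_widths = c(0.5, 0.5)),
                        t_range = c(150, 175), t_step = 0.02, noise = 0)
  expect_equal(deconvolute_melting(sym$trace, c(162, 164))$form1_fraction,
               0.5, tolerance = 0.01)
})

test_that("a single melting peak collapses to a degenerate pure-form result", {
  sim <- gen_thermogram(tg = NULL,
                        melt = list(centers = 164, areas_jg = 25,
                                    half_widths = 0.5),
                        t_range = c(155, 172), t_step = 0.02, noise = 0)
  md <- deconvolute_melting(sim$trace, centers_init = c(162, 164))
  if (md$degenerate) {
    expect_equal(md$form1_fraction, 1.0)
  } else {
    expect_gt(md$form1_fraction, 0.95)
  }
})

test_that("remaining glass fraction is a guarded ratio", {
  expect_equal(as.numeric(remaining_glass_fraction(0.45, 0.45)), 1.0)
  expect_equal(as.numeric(remaining_glass_fraction(0, 0.45)), 0.0)
  expect_equal(as.numeric(remaining_glass_fraction(0.30, 0.45)), 2 / 3,
               tolerance = 1e-12)
  r <- remaining_glass_fraction(0.50, 0.45)
  expect_true(attr(r, "above_unity"))
  expect_lte(as.numeric(r), 1.05)
  expect_error(remaining_glass_fraction(0.3, 0), "initial")
})
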