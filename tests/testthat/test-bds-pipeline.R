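# Spectrum deconvolution, mode tracking, VFT/JG analysis, master-plot
# extrapolation.

make_fit <- function(T_K, modes) {
  structure(list(modes = modes, eps_inf = 3, sigma_dc = 0,
                 residual_rms = 0, converged = TRUE, temperature = T_K),
            class = "spectrum_fit")
}

test_that("a noiseless Debye mode is recovered exactly", {
  f <- 10^seq(-2, 7, by = 1 / 8)
  m <- hn_mode(1.5, 1e-4, 1, 1, label = "beta")
  sp <- dielectric_spectrum(250, f,
                            Re(hn_complex_permittivity(f, list(m), 3)),
                            -Im(hn_complex_permittivity(f, list(m))))
  ft <- fit_spectrum(sp, list(mode_template("beta", 1, 1e-3, 0.8)))
  expect_true(ft$converged)
  expect_lt(ft$residual_rms, 1e-10)
  expect_equal(ft$modes[[1]]$delta_eps, 1.5, tolerance = 1e-6)
  expect_equal(ft$modes[[1]]$tau_hn, 1e-4, tolerance = 1e-6)
  expect_equal(ft$modes[[1]]$a, 1, tolerance = 1e-6)
})

test_that("a noisy Cole-Cole mode is recovered within stated tolerances", {
  proc <- list(mode = list(label = "gamma", delta_eps = 0.3, a = 0.3, b = 1),
               law = temperature_law("arrhenius", tau0_s = 1.5e-7 /
                                       exp(20000 / (8.314 * 200)),
                                     ea_kj_mol = 20))
  sim <- gen_dielectric_series(list(proc), T_K = 200, noise = 0.02, seed = 4)
  ft <- fit_spectrum(sim$spectra[[1]],
                     list(mode_template("gamma", 0.5, 1e-6, 0.5)))
  expect_true(ft$converged)
  expect_equal(ft$modes[[1]]$delta_eps, 0.3, tolerance = 0.05)
  expect_equal(ft$modes[[1]]$a, 0.3, tolerance = 0.05)
  expect_equal(ft$modes[[1]]$tau_hn, 1.5e-7, tolerance = 0.10)
})

test_that("three separated CC modes are each recovered within a factor 1.3", {
  f <- 10^seq(-2, 7, by = 1 / 8)
  truth <- list(hn_mode(0.6, 1e-2, 0.45, 1, "beta"),
                hn_mode(1.0, 3e-5, 0.40, 1, "gamma"),
                hn_mode(1.8, 1e-7, 0.55, 1, "delta"))
  set.seed(9)
  loss <- -Im(hn_complex_permittivity(f, truth)) *
    (1 + 0.02 * rnorm(length(f)))
  sp <- dielectric_spectrum(273, f, rep(3, length(f)), loss)
  tmpl <- list(mode_template("beta", 0.3, 3e-2, 0.5),
               mode_template("gamma", 0.5, 1e-5, 0.5),
               mode_template("delta", 1.0, 3e-7, 0.5))
  ft <- fit_spectrum(sp, tmpl)
  for (i in 1:3) {
    ratio <- ft$modes[[i]]$tau_hn / truth[[i]]$tau_hn
    expect_lt(abs(log(ratio)), log(1.3))
  }
})

test_that("underdetermined fits error; nonconvergence is flagged not thrown", {
  f <- 10^seq(0, 1, length.out = 8)
  sp <- dielectric_spectrum(250, f, rep(3, 8), rep(0.1, 8))
  tmpl <- list(mode_template("beta", 1, 1, 0.5),
               mode_template("gamma", 1, 0.1, 0.5),
               mode_template("delta", 1, 0.01, 0.5))
  expect_error(fit_spectrum(sp, tmpl), "fewer data points")
  # flat loss with one mode: must return an object, converged or not
  ft <- suppressWarnings(
    fit_spectrum(sp, list(mode_template("beta", 1, 1, 0.5)), maxit = 2))
  expect_s3_class(ft, "spectrum_fit")
  expect_type(ft$converged, "logical")
})

test_that("mode tracking follows labels, not tau proximity, and prunes sparse processes", {
  # two processes crossing in tau between adjacent temperatures
  f1 <- make_fit(200, list(hn_mode(1, 1e-3, 0.5, 1, "beta"),
                           hn_mode(1, 1e-5, 0.5, 1, "gamma")))
  f2 <- make_fit(210, list(hn_mode(1, 1e-6, 0.5, 1, "beta"),
                           hn_mode(1, 1e-4, 0.5, 1, "gamma")))
  map <- track_modes(list(f1, f2))
  beta <- map$points[map$points$process == "beta", ]
  expect_equal(beta$tau_s[order(beta$T_K)], c(1e-3, 1e-6))
  # a label present at fewer than half the temperatures is dropped
  f3 <- make_fit(220, list(hn_mode(1, 1e-7, 0.5, 1, "beta")))
  f4 <- make_fit(230, list(hn_mode(1, 1e-8, 0.5, 1, "beta")))
  expect_warning(map2 <- track_modes(list(f1, f3, f4)), "excluded")
  expect_false("gamma" %in% map2$points$process)
  # single temperature: map with that point only
  map3 <- track_modes(list(f1))
  expect_equal(nrow(map3$points), 2L)
})

test_that("a synthetic Arrhenius process yields a monotone relaxation map", {
  g <- cel_gamma_process()
  sim <- gen_dielectric_series(list(g$process), T_K = g$T_K, noise = 0.02,
                               seed = 2)
  fits <- lapply(sim$spectra, function(sp)
    fit_spectrum(sp, list(mode_template("gamma", 0.5, 1e-6, 0.5))))
  map <- track_modes(fits)
  pts <- map$points[order(map$points$T_K), ]
  expect_true(all(pts$tau_s > 0 & is.finite(pts$tau_s)))
  expect_true(all(diff(log(pts$tau_s)) < 0))  # tau falls as T rises
})

test_that("full-pipeline gamma activation energy is recovered at 2% noise", {
  g <- cel_gamma_process()
  ea <- vapply(1:3, function(s) {
    sim <- gen_dielectric_series(list(g$process), T_K = g$T_K,
                                 noise = 0.02, seed = s)
    fits <- lapply(sim$spectra, function(sp)
      fit_spectrum(sp, list(mode_template("gamma", 0.5, 1e-6, 0.5))))
    map_fit_arrhenius(track_modes(fits), "gamma")$arrhenius$gamma$ea
  }, numeric(1))
  expect_true(all(abs(ea - 33.9) < 1.5))
})

test_that("VFT fitting recovers noiseless parameters, honors the Tg constraint", {
  truth <- vft_fit(-14, 6.33, 280)
  Ts <- seq(332, 362, by = 3)
  fits <- lapply(Ts, function(Tk)
    make_fit(Tk, list(hn_mode(3, vft_tau(Tk, truth), 1, 1, "alpha"))))
  map <- track_modes(fits)
  v <- fit_alpha_vft(map, fix_log_tau_inf = -14)
  expect_equal(v$D, 6.33, tolerance = 1e-5)
  expect_equal(v$T0, 280, tolerance = 1e-3)
  # free pre-exponential: parameters shift but the curve agrees within 2%
  vf <- fit_alpha_vft(map)
  expect_equal(vft_tau(Ts, vf) / vft_tau(Ts, truth), rep(1, length(Ts)),
               tolerance = 0.02)
  # Tg constraint enforced exactly
  vc <- fit_alpha_vft(map, fix_log_tau_inf = -14,
                      tg_constraint = c(328.35, 100))
  expect_equal(vft_tau(328.35, vc), 100, tolerance = 1e-9)
  expect_error(fit_alpha_vft(track_modes(fits[1:2])), "3 alpha points")
})

test_that("JG prediction applies the Coupling Model along the alpha process", {
  truth <- vft_fit(-14, 6.33, 280)
  Ts <- seq(332, 352, by = 5)
  fits <- lapply(Ts, function(Tk)
    make_fit(Tk, list(hn_mode(3, vft_tau(Tk, truth), 1, 1, "alpha"))))
  map <- track_modes(fits)
  # beta = 1: JG time equals alpha time
  m1 <- predict_jg(map, beta_kww = 1)
  expect_equal(m1$jg_predicted$tau_jg_s,
               map$points$tau_s[map$points$process == "alpha"])
  # spot oracle at each temperature for beta = 0.69
  m2 <- predict_jg(map, beta_kww = 0.69, tc = 2e-12)
  taus <- vft_tau(Ts, truth)
  expect_equal(m2$jg_predicted$tau_jg_s,
               (2e-12)^0.31 * taus^0.69, tolerance = 1e-10)
  # no alpha points: empty prediction
  mg <- track_modes(list(make_fit(200, list(hn_mode(1, 1e-5, 0.5, 1, "gamma")))))
  expect_equal(nrow(predict_jg(mg, 0.69)$jg_predicted), 0L)
})

test_that("normalized HN peaks at different temperatures superpose (TTS)", {
  f <- 10^seq(-2, 7, by = 0.02)
  shape <- function(tau) {
    loss <- -Im(hn_complex_permittivity(f, list(hn_mode(3, tau, 0.85, 0.55,
                                                        "alpha"))))
    i <- which.max(loss)
    list(lf = log10(f / f[i]), y = loss / loss[i])
  }
  s1 <- shape(1e-2); s2 <- shape(1e-5)
  common <- seq(-2, 2, by = 0.05)
  y1 <- approx(s1$lf, s1$y, common)$y
  y2 <- approx(s2$lf, s2$y, common)$y
  expect_lt(sqrt(mean((y1 - y2)^2)), 0.01)
})

test_that("master-plot shifting recovers constructed decade shifts", {
  f <- 10^seq(-2, 7, by = 1 / 8)
  modes <- list(hn_mode(3, 1e-3, 0.8, 0.6, "alpha"))
  loss <- -Im(hn_complex_permittivity(f, modes))
  ref_spec <- dielectric_spectrum(341, f, rep(3, length(f)), loss)
  ref_fit <- fit_spectrum(ref_spec, list(mode_template("alpha", 2, 1e-3,
                                                       0.7, 0.5)))
  # a spectrum shifted against itself: zero shift, tau unchanged
  self <- masterplot_extrapolate(list(ref_spec), ref_fit)
  expect_equal(self$shift_decades, 0, tolerance = 0.01)
  expect_equal(self$tau_alpha_s,
               tau_alpha_from_hn(ref_fit$modes[[1]]), tolerance = 0.03)
  # known 2-decade shift: tau ratio 100
  lo <- dielectric_spectrum(320, f, rep(3, length(f)),
                            -Im(hn_complex_permittivity(f * 100, modes)))
  mp <- masterplot_extrapolate(list(lo), ref_fit)
  expect_equal(mp$shift_decades, 2, tolerance = 0.01)
  expect_equal(mp$tau_alpha_s / self$tau_alpha_s, 100, tolerance = 0.03)
  # Arrhenius-consistent shifts extrapolate colinearly on Arrhenius axes
  Ts <- c(310, 320, 330)
  shifts <- 8000 * (1 / Ts - 1 / 341)  # ln tau linear in 1/T
  specs <- lapply(seq_along(Ts), function(i)
    dielectric_spectrum(Ts[i], f, rep(3, length(f)),
                        -Im(hn_complex_permittivity(f * 10^shifts[i], modes))))
  mp3 <- masterplot_extrapolate(specs, ref_fit)
  r <- stats::lm(log(tau_alpha_s) ~ I(1 / T_K), data = mp3)
  expect_lt(max(abs(stats::resid(r))), 0.02)
})
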