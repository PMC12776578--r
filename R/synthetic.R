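# Seeded generators for every input class the analyses consume, with the
# generating parameters returned alongside as ground truth.  Noise models:
# multiplicative Gaussian for dielectric loss (instrument-like, constant
# relative error across nine decades), additive Gaussian for calorimetric
# signals.  Every generator is bit-reproducible under a fixed seed.

#' Temperature law for a relaxation process
#'
#' @param type \code{"arrhenius"} (\eqn{\tau = \tau_0 e^{E_a/RT}}) or
#'   \code{"vft"}.
#' @param tau0_s Arrhenius prefactor, seconds.
#' @param ea_kj_mol Arrhenius activation energy, kJ/mol.
#' @param vft a [vft_fit()] for \code{type = "vft"}.
#' @return a temperature-law object with a \code{tau_at(T_K)} evaluator.
#' @export
temperature_law <- function(type = c("arrhenius", "vft"),
                            tau0_s = NULL, ea_kj_mol = NULL, vft = NULL) {
  type <- match.arg(type)
  if (type == "arrhenius") {
    stopifnot(tau0_s > 0, ea_kj_mol > 0)
    law <- list(type = type, tau0_s = tau0_s, ea_kj_mol = ea_kj_mol)
    law$tau_at <- function(T_K) tau0_s * exp(ea_kj_mol * 1000 / (.Rgas * T_K))
  } else {
    stopifnot(inherits(vft, "vft_fit"))
    law <- list(type = type, vft = vft)
    law$tau_at <- function(T_K) vft_tau(T_K, vft)
  }
  structure(law, class = "temperature_law")
}

#' Generate a temperature series of dielectric spectra
#'
#' Builds per-temperature complex permittivity from a set of relaxation
#' processes, each an HN/CC mode template whose time follows an Arrhenius
#' or VFT law, then applies multiplicative Gaussian noise to both
#' permittivity components.  A process whose relaxation time never enters
#' the measured frequency window triggers an "unobservable" warning.
#'
#' @param processes list of processes; each a list with \code{mode}
#'   (list: \code{label}, \code{delta_eps}, \code{a}, \code{b}) and
#'   \code{law} (a [temperature_law()]).
#' @param T_K measurement temperatures, K.
#' @param freq frequency grid, Hz (default 8 points/decade over
#'   1e-2..1e7 Hz, the standard broadband window).
#' @param noise multiplicative noise standard deviation (default 0.02).
#' @param eps_inf high-frequency permittivity.
#' @param seed RNG seed.
#' @return list with \code{spectra} (list of [dielectric_spectrum()]) and
#'   \code{truth} (full generating parameter set, class
#'   \code{"ground_truth"}).
#' @export
gen_dielectric_series <- function(processes, T_K,
                                  freq = 10^seq(-2, 7, by = 1 / 8),
                                  noise = 0.02, eps_inf = 3, seed = 1) {
  stopifnot(noise >= 0, length(T_K) >= 1L)
  set.seed(seed)
  for (pr in processes) {
    taus <- pr$law$tau_at(T_K)
    fpk <- 1 / (2 * pi * taus)
    if (all(fpk < min(freq)) || all(fpk > max(freq)))
      warning("process '", pr$mode$label,
              "' is unobservable in the frequency window at all temperatures")
  }
  spectra <- lapply(T_K, function(Tk) {
    modes <- lapply(processes, function(pr)
      hn_mode(pr$mode$delta_eps, pr$law$tau_at(Tk), pr$mode$a,
              if (is.null(pr$mode$b)) 1 else pr$mode$b,
              label = pr$mode$label))
    eps <- hn_complex_permittivity(freq, modes, eps_inf = eps_inf)
    loss <- -Im(eps) * (1 + noise * stats::rnorm(length(freq)))
    re <- Re(eps) * (1 + noise * stats::rnorm(length(freq)))
    dielectric_spectrum(Tk, freq, re, loss)
  })
  truth <- structure(list(kind = "dielectric_series",
                          processes = lapply(processes, function(pr)
                            list(mode = pr$mode,
                                 law = pr$law[setdiff(names(pr$law), "tau_at")])),
                          T_K = T_K, freq = freq, noise = noise,
                          eps_inf = eps_inf, seed = seed),
                     class = "ground_truth")
  list(spectra = spectra, truth = truth)
}

#' Generate a normalized alpha-relaxation loss peak from the KWW transform
#'
#' Evaluates the numerically transformed KWW loss (see
#' [kww_normalized_loss()]) on a reduced-frequency grid and applies
#' multiplicative noise -- the fixture for testing and calibrating
#' [kww_shape_fit()].
#'
#' @param beta generating stretching exponent.
#' @param f_max_hz peak frequency placed on the absolute axis, Hz.
#' @param decades half-width of the reduced-frequency window, decades.
#' @param n_per_decade grid density.
#' @param noise multiplicative noise sd (default 0.01).
#' @param temperature_K recorded temperature.
#' @param seed RNG seed.
#' @return list with \code{spectrum} (a [dielectric_spectrum()]; real part
#'   is a flat placeholder) and \code{truth}.
#' @export
gen_kww_loss_peak <- function(beta, f_max_hz = 1e3, decades = 2.5,
                              n_per_decade = 8, noise = 0.01,
                              temperature_K = 341.15, seed = 1) {
  set.seed(seed)
  f_rel <- 10^seq(-decades, decades, by = 1 / n_per_decade)
  y <- kww_normalized_loss(f_rel, beta)
  y <- y * (1 + noise * stats::rnorm(length(y)))
  spec <- dielectric_spectrum(temperature_K, f_rel * f_max_hz,
                              rep(3, length(f_rel)), y)
  truth <- structure(list(kind = "kww_loss_peak", beta = beta,
                          f_max_hz = f_max_hz, noise = noise, seed = seed),
                     class = "ground_truth")
  list(spectrum = spec, truth = truth)
}

#' Generate an enthalpy-recovery series with known KWW parameters
#'
#' \eqn{\Delta H_t = \Delta H_\infty[1 - \Phi(t)]} plus additive Gaussian
#' noise scaled by \eqn{\Delta H_\infty}.  Generated recoveries are
#' floored at 0 and capped at \eqn{\Delta H_\infty} (a recovery cannot
#' exceed the thermodynamic maximum; the instrument subtraction can
#' produce small negatives, which are floored).
#'
#' @param tau_min generating relaxation time, minutes.
#' @param beta generating stretching exponent.
#' @param dh_inf maximum recovery, J/g.
#' @param t_min annealing-time grid, minutes.
#' @param noise additive noise sd as a fraction of \code{dh_inf}
#'   (default 0.03).
#' @param ta annealing temperature, degC (recorded).
#' @param seed RNG seed.
#' @return list with \code{series} (an [enthalpy_recovery_series()]) and
#'   \code{truth}.
#' @export
gen_enthalpy_recovery <- function(tau_min, beta, dh_inf,
                                  t_min = 10^seq(2, log10(30000),
                                                 length.out = 8),
                                  noise = 0.03, ta = 35, seed = 1) {
  set.seed(seed)
  phi <- kww_decay(t_min, tau_min, beta)
  dh <- dh_inf * (1 - phi) + noise * dh_inf * stats::rnorm(length(t_min))
  dh <- pmin(pmax(dh, 0), dh_inf)
  series <- enthalpy_recovery_series(ta, t_min, dh)
  truth <- structure(list(kind = "enthalpy_recovery", tau_min = tau_min,
                          beta = beta, dh_inf = dh_inf, noise = noise,
                          ta = ta, seed = seed),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Generate a DSC thermogram with known features
#'
#' Additive composition on a linear baseline: a logistic heat-capacity
#' step at the glass transition, an optional Gaussian cold-crystallization
#' exotherm, and optional Lorentzian melting endotherms.  Peak heights are
#' set so that the integrated area over temperature divided by the scan
#' rate reproduces the requested enthalpies in J/g.  In the generated
#' signal the glass step rises by \eqn{\Delta C_p}; exotherms point up and
#' endotherms down when \code{exo_up} (the recorded convention).
#' Features closer than the sum of their widths trigger a warning.
#'
#' @param tg NULL or list(\code{mid}, \code{delta_cp}, \code{width}) in
#'   degC / J/(g K).
#' @param exo NULL or list(\code{center}, \code{area_jg}, \code{sd})
#'   (Gaussian exotherm).
#' @param melt NULL or list(\code{centers}, \code{areas_jg},
#'   \code{half_widths}) (two Lorentzian endotherms).
#' @param t_range,t_step temperature grid, degC.
#' @param baseline c(intercept, slope) of the linear baseline.
#' @param noise additive noise sd, signal units.
#' @param scan_rate degC/min.
#' @param exo_up sign convention flag.
#' @param seed RNG seed.
#' @return list with \code{trace} (a [thermogram()]) and \code{truth}.
#' @export
gen_thermogram <- function(tg = list(mid = 55.2, delta_cp = 0.45, width = 4),
                           exo = NULL, melt = NULL,
                           t_range = c(-20, 180), t_step = 0.1,
                           baseline = c(0, 0), noise = 0,
                           scan_rate = 10, exo_up = TRUE, seed = 1) {
  set.seed(seed)
  T <- seq(t_range[1], t_range[2], by = t_step)
  y <- baseline[1] + baseline[2] * T
  rate_s <- scan_rate / 60
  centers <- c(); widths <- c()
  if (!is.null(tg)) {
    y <- y + tg$delta_cp / (1 + exp(-(T - tg$mid) / (tg$width / 4)))
    centers <- c(centers, tg$mid); widths <- c(widths, tg$width)
  }
  sgn <- if (exo_up) 1 else -1
  if (!is.null(exo)) {
    h <- exo$area_jg * rate_s / (exo$sd * sqrt(2 * pi))
    y <- y + sgn * h * exp(-(T - exo$center)^2 / (2 * exo$sd^2))
    centers <- c(centers, exo$center); widths <- c(widths, 4 * exo$sd)
  }
  if (!is.null(melt)) {
    for (i in seq_along(melt$centers)) {
      amp <- melt$areas_jg[i] * rate_s / (pi * melt$half_widths[i])
      y <- y - sgn * .lorentz(T, amp, melt$centers[i], melt$half_widths[i])
      centers <- c(centers, melt$centers[i])
      widths <- c(widths, 4 * melt$half_widths[i])
    }
  }
  if (length(centers) > 1L) {
    ord <- order(centers)
    gaps <- diff(centers[ord])
    wsum <- widths[ord][-length(widths)] + widths[ord][-1L]
    if (any(gaps < wsum / 2))
      warning("generated features overlap within their widths")
  }
  if (noise > 0) y <- y + noise * stats::rnorm(length(T))
  trace <- thermogram(T, y, scan_rate = scan_rate, exo_up = exo_up)
  truth <- structure(list(kind = "thermogram", tg = tg, exo = exo,
                          melt = melt, baseline = baseline, noise = noise,
                          scan_rate = scan_rate, exo_up = exo_up,
                          t_range = t_range, t_step = t_step, seed = seed),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Generate radial crystal-growth tracks
#'
#' Linear radial growth with Gaussian jitter on the measured radius,
#' floored to be nondecreasing (a crystal front does not retreat).
#' \code{rates} of length 2 with \code{two_population = TRUE} assigns half
#' the directions to each rate, emulating partial poisoning of the growth
#' front.
#'
#' @param n_directions number of radial directions (default 16).
#' @param rates growth rate(s), um/s; recycled over directions, or a
#'   length-2 population pair.
#' @param duration_s observation span, seconds.
#' @param n_points observations per track.
#' @param jitter_um radius measurement noise sd, um.
#' @param two_population split directions evenly between \code{rates[1]}
#'   and \code{rates[2]}.
#' @param seed RNG seed.
#' @return list with \code{tracks} (list of [growth_track()]) and
#'   \code{truth}.
#' @export
gen_growth_tracks <- function(n_directions = 16, rates = 3.0,
                              duration_s = 60, n_points = 10,
                              jitter_um = 0, two_population = FALSE,
                              seed = 1) {
  set.seed(seed)
  rate_vec <- if (two_population) {
    stopifnot(length(rates) == 2L)
    rep(rates, each = ceiling(n_directions / 2))[1:n_directions]
  } else rep_len(rates, n_directions)
  t <- seq(0, duration_s, length.out = n_points)
  tracks <- lapply(seq_len(n_directions), function(d) {
    r <- rate_vec[d] * t + jitter_um * stats::rnorm(n_points)
    r <- cummax(pmax(r, 0))
    growth_track(d, t, r)
  })
  truth <- structure(list(kind = "growth_tracks", rates = rate_vec,
                          duration_s = duration_s, n_points = n_points,
                          jitter_um = jitter_um, seed = seed),
                     class = "ground_truth")
  list(tracks = tracks, truth = truth)
}
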