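#' Havriliak-Negami relaxation mode
#'
#' Constructs one Havriliak-Negami (HN) mode of the complex permittivity,
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \Delta\varepsilon / [1 + (i\omega\tau_{HN})^a]^b,}
#' the empirical lineshape used to deconvolute broadband dielectric spectra
#' of glass-forming liquids.  A Cole-Cole (CC) mode, the symmetric special
#' case used for secondary (beta/gamma/delta) relaxations, is an HN mode
#' with \code{b = 1}.
#'
#' @param delta_eps relaxation strength \eqn{\Delta\varepsilon} (> 0).
#' @param tau_hn HN relaxation time in seconds (> 0).
#' @param a symmetric broadening exponent, in (0, 1].
#' @param b asymmetry exponent, in (0, 1]; 1 gives a Cole-Cole mode.
#' @param label process name, one of \code{"alpha"}, \code{"beta"},
#'   \code{"gamma"}, \code{"delta"}.
#' @return an object of class \code{"hn_mode"}.
#' @seealso [hn_complex_permittivity()], [tau_alpha_from_hn()]
#' @export
hn_mode <- function(delta_eps, tau_hn, a, b = 1,
                    label = c("alpha", "beta", "gamma", "delta")) {
  label <- match.arg(label)
  stopifnot(is.numeric(delta_eps), length(delta_eps) == 1L,
            is.numeric(tau_hn), length(tau_hn) == 1L,
            is.numeric(a), length(a) == 1L,
            is.numeric(b), length(b) == 1L)
  if (!(delta_eps > 0)) stop("delta_eps must be > 0")
  if (!(tau_hn > 0)) stop("tau_hn must be > 0")
  if (!(a > 0 && a <= 1)) stop("a must be in (0, 1]")
  if (!(b > 0 && b <= 1)) stop("b must be in (0, 1]")
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn,
                 a = a, b = b, label = label),
            class = "hn_mode")
}

#' @export
print.hn_mode <- function(x, ...) {
  kind <- if (x$b == 1) "Cole-Cole" else "Havriliak-Negami"
  cat(sprintf("%s mode [%s]: delta_eps = %.4g, tau_HN = %.4g s, a = %.3f, b = %.3f\n",
              kind, x$label, x$delta_eps, x$tau_hn, x$a, x$b))
  invisible(x)
}

#' Complex permittivity of a sum of HN modes plus dc conductivity
#'
#' Evaluates \eqn{\varepsilon^*(\omega) = \varepsilon_\infty + \sum_k
#' \Delta\varepsilon_k/[1+(i\omega\tau_{HN,k})^{a_k}]^{b_k} -
#' i\,\sigma_{dc}/(\varepsilon_0\omega^s)} on a frequency grid.  The
#' convention \eqn{\varepsilon^* = \varepsilon' - i\varepsilon''} is used,
#' so the dielectric loss is \code{-Im()} of the returned values.
#'
#' @param freq_hz strictly positive frequencies in Hz, sorted ascending.
#' @param modes list of [hn_mode()] objects (may be empty).
#' @param eps_inf high-frequency limit permittivity.
#' @param sigma_dc dc conductivity in S/m (>= 0); 0 disables the term.
#' @param s_exp conductivity exponent in (0, 1]; 1 is pure ohmic conduction.
#' @return complex vector of \eqn{\varepsilon^*} values, one per frequency.
#' @examples
#' f <- 10^seq(-2, 7, length.out = 200)
#' m <- hn_mode(1, 1 / (2 * pi), a = 1, b = 1, label = "alpha")
#' loss <- -Im(hn_complex_permittivity(f, list(m), eps_inf = 3))
#' f[which.max(loss)]  # Debye peak at 1 Hz
#' @export
hn_complex_permittivity <- function(freq_hz, modes, eps_inf = 0,
                                    sigma_dc = 0, s_exp = 1) {
  if (!is.numeric(freq_hz) || any(freq_hz <= 0))
    stop("freq_hz must be strictly positive")
  if (is.unsorted(freq_hz))
    stop("freq_hz must be sorted ascending")
  if (!(s_exp > 0 && s_exp <= 1)) stop("s_exp must be in (0, 1]")
  if (sigma_dc < 0) stop("sigma_dc must be >= 0")
  if (inherits(modes, "hn_mode")) modes <- list(modes)
  for (m in modes) {
    if (!inherits(m, "hn_mode")) stop("modes must be hn_mode objects")
    if (m$a * m$b > 1) stop("invalid HN mode: a * b > 1")
  }
  omega <- 2 * pi * freq_hz
  eps <- complex(real = rep(eps_inf, length(omega)), imaginary = 0)
  for (m in modes) {
    eps <- eps + m$delta_eps / (1 + (1i * omega * m$tau_hn)^m$a)^m$b
  }
  if (sigma_dc > 0) {
    eps <- eps - 1i * sigma_dc / (.eps0 * omega^s_exp)
  }
  eps
}

#' Alpha-relaxation time from HN fit parameters
#'
#' Converts the fitted HN time \eqn{\tau_{HN}} to the relaxation time at the
#' loss-peak maximum,
#' \deqn{\tau_\alpha = \tau_{HN}
#'   \left[\sin\frac{\pi a b}{2+2b}\right]^{1/a}
#'   \left[\sin\frac{\pi a}{2+2b}\right]^{-1/a}.}
#' For a Debye or Cole-Cole mode (\code{b = 1}) the two sine factors cancel
#' and \eqn{\tau_\alpha = \tau_{HN}}.
#'
#' @param mode an [hn_mode()] object.
#' @return relaxation time in seconds.
#' @export
tau_alpha_from_hn <- function(mode) {
  stopifnot(inherits(mode, "hn_mode"))
  a <- mode$a; b <- mode$b
  mode$tau_hn *
    sin(pi * a * b / (2 + 2 * b))^(1 / a) *
    sin(pi * a / (2 + 2 * b))^(-1 / a)
}

#' Vogel-Fulcher-Tammann temperature law
#'
#' Container and evaluators for the VFT law
#' \eqn{\tau_\alpha(T) = \tau_\infty \exp[D T_0/(T - T_0)]}, which describes
#' the super-Arrhenius slowdown of structural relaxation approaching the
#' glass transition.  \code{D} is the Angell strength parameter (large D =
#' strong glass) and \eqn{T_0} the Vogel temperature.
#'
#' @param log10_tau_inf decadic log of the pre-exponential time (seconds).
#' @param D Angell strength parameter (> 0), dimensionless.
#' @param T0 Vogel temperature in K (> 0).
#' @param tg_tau relaxation time defining the glass transition, seconds
#'   (conventionally 100 s).
#' @return an object of class \code{"vft_fit"}.
#' @export
vft_fit <- function(log10_tau_inf, D, T0, tg_tau = 100) {
  stopifnot(is.numeric(log10_tau_inf), is.numeric(D), is.numeric(T0))
  if (!(T0 > 0)) stop("T0 must be > 0")
  if (!(D > 0)) stop("D must be > 0")
  if (!(tg_tau > 0)) stop("tg_tau must be > 0")
  structure(list(log10_tau_inf = log10_tau_inf, D = D, T0 = T0,
                 tg_tau = tg_tau),
            class = "vft_fit")
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf("VFT fit: log10(tau_inf/s) = %.3f, D = %.3f, T0 = %.2f K\n",
              x$log10_tau_inf, x$D, x$T0))
  tg <- vft_invert(x$tg_tau, x)
  cat(sprintf("  Tg(tau = %g s) = %.2f K (%.2f C)\n",
              x$tg_tau, tg, kelvin_to_celsius(tg)))
  invisible(x)
}

#' @rdname vft_fit
#' @param T temperature(s) in K, each > \code{T0}.
#' @param fit a \code{vft_fit} object.
#' @return \code{vft_tau}: relaxation time(s) in seconds.
#' @export
vft_tau <- function(T, fit) {
  stopifnot(inherits(fit, "vft_fit"))
  if (any(T <= fit$T0))
    stop("VFT law is defined only for T > T0")
  10^fit$log10_tau_inf * exp(fit$D * fit$T0 / (T - fit$T0))
}

#' @rdname vft_fit
#' @param tau relaxation time(s) in seconds, each > \eqn{\tau_\infty}.
#' @return \code{vft_invert}: temperature(s) in K, from the closed form
#'   \eqn{T = T_0 (1 + D/\ln(\tau/\tau_\infty))}.
#' @export
vft_invert <- function(tau, fit) {
  stopifnot(inherits(fit, "vft_fit"))
  tau_inf <- 10^fit$log10_tau_inf
  if (any(tau <= tau_inf))
    stop("inverse VFT requires tau > tau_inf")
  fit$T0 * (1 + fit$D / log(tau / tau_inf))
}

#' Glass-transition temperature implied by a VFT fit
#'
#' Temperature at which the VFT curve reaches the conventional
#' glass-defining relaxation time (\code{fit$tg_tau}, default 100 s).
#'
#' @param fit a [vft_fit()] object.
#' @return temperature in K.
#' @export
vft_tg <- function(fit) vft_invert(fit$tg_tau, fit)

#' Arrhenius fit of relaxation times (or any rate-like quantity)
#'
#' Ordinary least squares of \eqn{\ln q} on reciprocal temperature;
#' the activation energy is \eqn{E_a = R \cdot} slope, reported in kJ/mol.
#' Unit changes of q rescale only the intercept, never the slope.
#'
#' @param inv_T reciprocal temperatures in 1/K (at least two distinct).
#' @param ln_q natural log of the fitted quantity at each temperature.
#' @return an object of class \code{"arrhenius_fit"} with fields \code{ea}
#'   (kJ/mol), \code{ln_prefactor} (intercept), \code{se_ea} (kJ/mol) and
#'   \code{n_points}.
#' @examples
#' Tk <- c(30, 35, 40, 45) + 273.15
#' tb <- c(158, 58.9, 40.5, 29.8)  # tau^beta, minutes
#' arrhenius_fit(1 / Tk, log(tb))$ea  # ~86.6 kJ/mol
#' @export
arrhenius_fit <- function(inv_T, ln_q) {
  stopifnot(is.numeric(inv_T), is.numeric(ln_q),
            length(inv_T) == length(ln_q))
  if (length(unique(inv_T)) < 2L)
    stop("Arrhenius fit needs at least two distinct temperatures")
  fit <- stats::lm(ln_q ~ inv_T)
  # noiseless data give an "essentially perfect fit" note; se is then 0
  sm <- suppressWarnings(summary(fit)$coefficients)
  se <- if (length(inv_T) > 2L) sm["inv_T", "Std. Error"] else 0
  structure(list(ea = unname(stats::coef(fit)["inv_T"]) * .Rgas / 1000,
                 ln_prefactor = unname(stats::coef(fit)["(Intercept)"]),
                 se_ea = se * .Rgas / 1000,
                 n_points = length(inv_T)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%d points): Ea = %.1f +/- %.1f kJ/mol\n",
              x$n_points, x$ea, x$se_ea))
  invisible(x)
}

#' Predict the fitted quantity from an Arrhenius fit
#'
#' @param fit an [arrhenius_fit()] object.
#' @param T temperatures in K.
#' @return quantity in the units originally fitted.
#' @export
arrhenius_predict <- function(fit, T) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  exp(fit$ln_prefactor + fit$ea * 1000 / (.Rgas * T))
}

#' Coupling Model parameters
#'
#' @param n coupling parameter, \eqn{n = 1 - \beta_{KWW}}, in [0, 1).
#' @param tc crossover time in seconds (default 2 ps).
#' @return an object of class \code{"cm_params"}.
#' @export
cm_params <- function(n, tc = 2e-12) {
  if (!(n >= 0 && n < 1)) stop("coupling parameter n must be in [0, 1)")
  if (!(tc > 0)) stop("tc must be > 0")
  structure(list(tc = tc, n = n), class = "cm_params")
}

#' Coupling-Model primitive (Johari-Goldstein) relaxation time
#'
#' The Coupling Model predicts that the Johari-Goldstein secondary
#' relaxation time approximates the primitive relaxation time
#' \deqn{\tau_{JG} \approx \tau_0 = t_c^{\,n}\,\tau_\alpha^{\,1-n}, \quad
#'   n = 1 - \beta_{KWW},}
#' linking the secondary process to the stretching of the structural
#' relaxation.
#'
#' @param tau_alpha structural relaxation time(s) in seconds.
#' @param beta_kww KWW stretching exponent in (0, 1]; used to form
#'   \code{n = 1 - beta_kww} when \code{params} is missing.
#' @param params optional [cm_params()]; overrides \code{beta_kww}.
#' @return predicted \eqn{\tau_{JG}} in seconds (computed in the log domain
#'   for numerical range safety).
#' @export
cm_primitive_tau <- function(tau_alpha, beta_kww = NULL, params = NULL) {
  if (is.null(params)) {
    if (is.null(beta_kww)) stop("supply beta_kww or params")
    params <- cm_params(n = 1 - beta_kww)
  }
  stopifnot(inherits(params, "cm_params"))
  if (any(tau_alpha <= 0)) stop("tau_alpha must be > 0")
  exp(params$n * log(params$tc) + (1 - params$n) * log(tau_alpha))
}

#' Inputs for the Donth cooperativity length
#'
#' @param tg_onset onset glass-transition temperature, K.
#' @param half_width half of the glass-transition width
#'   \eqn{\Delta_d T_g}, K.
#' @param rho density, kg/m^3.
#' @param cpg specific heat of the glass, J/(kg K).
#' @param cpl specific heat of the supercooled liquid, J/(kg K);
#'   must exceed \code{cpg}.
#' @return an object of class \code{"crr_inputs"}.
#' @export
crr_inputs <- function(tg_onset, half_width, rho, cpg, cpl) {
  if (!(half_width > 0)) stop("half_width must be > 0")
  if (!(rho > 0)) stop("rho must be > 0")
  if (!(cpg > 0)) stop("cpg must be > 0")
  if (!(cpl > cpg)) stop("cpl must exceed cpg")
  if (!(tg_onset > 0)) stop("tg_onset must be > 0 K")
  structure(list(tg_onset = tg_onset, half_width = half_width,
                 rho = rho, cpg = cpg, cpl = cpl),
            class = "crr_inputs")
}

#' Donth estimate of the cooperatively rearranging region size
#'
#' Characteristic length of cooperative molecular motion at the glass
#' transition from calorimetric quantities,
#' \deqn{L = \left\{\frac{3 k T_g^2}{4\pi\rho\,\Delta_d T_g^2}
#'   \left(\frac{1}{C_{pg}} - \frac{1}{C_{pl}}\right)\right\}^{1/3},}
#' with the onset \eqn{T_g}, half the transition width
#' \eqn{\Delta_d T_g}, density \eqn{\rho} and the glass/liquid specific
#' heats.  Typical organic glasses give L of order 2 nm.
#'
#' @param inputs a [crr_inputs()] object (SI units).
#' @return length in meters.
#' @export
donth_crr_length <- function(inputs) {
  stopifnot(inherits(inputs, "crr_inputs"))
  arg <- 3 * .kB * inputs$tg_onset^2 /
    (4 * pi * inputs$rho * inputs$half_width^2) *
    (1 / inputs$cpg - 1 / inputs$cpl)
  arg^(1 / 3)
}

#' KWW stretched-exponential relaxation function
#'
#' \eqn{\Phi(t) = \exp[-(t/\tau)^\beta]}.  \eqn{\beta < 1} reflects a
#' distribution of relaxation times.
#'
#' @param t times (>= 0), in the same unit as \code{tau}.
#' @param tau relaxation time (> 0).
#' @param beta stretching exponent in (0, 1].
#' @return vector of \eqn{\Phi} values in (0, 1].
#' @export
kww_decay <- function(t, tau, beta) {
  if (!(tau > 0)) stop("tau must be > 0")
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  if (any(t < 0)) stop("t must be >= 0")
  exp(-(t / tau)^beta)
}

#' Maximum recoverable enthalpy below the glass transition
#'
#' \eqn{\Delta H_\infty = \Delta C_p (T_g - T_a)}: the enthalpy a glass
#' annealed at \eqn{T_a} can recover toward the extrapolated liquid line.
#'
#' @param delta_cp heat-capacity step at Tg, J/(g K).
#' @param tg glass-transition temperature (K or degC).
#' @param ta annealing temperature, same scale as \code{tg}; must be below
#'   \code{tg}.
#' @return enthalpy in J/g.
#' @export
dh_infinity <- function(delta_cp, tg, ta) {
  if (!(delta_cp > 0)) stop("delta_cp must be > 0")
  if (!(tg > ta)) stop("tg must exceed ta")
  delta_cp * (tg - ta)
}

#' Relaxation function from recovered enthalpy
#'
#' \eqn{\Phi = 1 - \Delta H_t / \Delta H_\infty}.  Values outside [0, 1]
#' (over-recovery) are kept as computed and flagged via the
#' \code{"over_recovery"} attribute, never silently clipped.
#'
#' @param dh_t recovered enthalpy(ies), J/g.
#' @param dh_inf maximum recoverable enthalpy, J/g (> 0).
#' @return \eqn{\Phi} values with logical attribute \code{over_recovery}.
#' @export
phi_from_recovery <- function(dh_t, dh_inf) {
  if (!(dh_inf > 0)) stop("dh_inf must be > 0")
  phi <- 1 - dh_t / dh_inf
  over <- any(dh_t > dh_inf)
  if (over)
    warning("recovered enthalpy exceeds dh_inf for some points (Phi < 0)")
  attr(phi, "over_recovery") <- over
  phi
}

#' KWW fit container
#'
#' @param tau_alpha relaxation time (> 0), in \code{unit}.
#' @param beta_kww stretching exponent in (0, 1].
#' @param unit time unit of \code{tau_alpha} (recorded; \code{"min"} is the
#'   convention for calorimetric enthalpy-recovery fits).
#' @return object of class \code{"kww_fit"}; \code{tau_beta}
#'   (\eqn{\tau_\alpha^{\beta_{KWW}}}, in the same declared unit) is always
#'   recomputed from the two parameters.
#' @export
kww_fit <- function(tau_alpha, beta_kww, unit = "s") {
  if (!(tau_alpha > 0)) stop("tau_alpha must be > 0")
  if (!(beta_kww > 0 && beta_kww <= 1)) stop("beta_kww must be in (0, 1]")
  structure(list(tau_alpha = tau_alpha, beta_kww = beta_kww,
                 tau_beta = tau_alpha^beta_kww, unit = unit),
            class = "kww_fit")
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("KWW fit: tau = %.4g %s, beta = %.3f, tau^beta = %.4g\n",
              x$tau_alpha, x$unit, x$beta_kww, x$tau_beta))
  invisible(x)
}
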