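# One-sided Fourier transform of the KWW decay and alpha-peak shape fitting.
#
# The loss spectrum of a stretched-exponential relaxation is
#   chi''(omega) = Int_0^inf (-dPhi/dt) sin(omega t) dt,  Phi = exp(-(t/tau)^beta).
# Integrating by parts removes the t^(beta-1) singularity of -dPhi/dt:
#   chi''(x) = x Int_0^inf exp(-u^beta) cos(x u) du,   x = omega tau.
# The remaining integrand is smooth, so it is evaluated by piecewise-linear
# Filon quadrature on a log-spaced u grid: within each interval Phi is
# linearized and the product with cos(xu) integrated in closed form, which
# keeps the quadrature accurate even when many oscillations fall inside one
# grid interval.  The Debye limit beta = 1 gives x/(1+x^2) exactly and is
# used as the validation case.

#' KWW loss spectrum (one-sided Fourier transform of the stretched exponential)
#'
#' Dielectric-loss lineshape of a KWW relaxation in reduced frequency
#' \eqn{x = \omega\tau}: \eqn{\chi''(x) = x\int_0^\infty e^{-u^\beta}
#' \cos(xu)\,du}.  For \eqn{\beta = 1} this is the Debye loss
#' \eqn{x/(1+x^2)}.
#'
#' @param x reduced angular frequencies \eqn{\omega\tau} (> 0).
#' @param beta stretching exponent in (0, 1].
#' @param n_grid number of log-spaced quadrature intervals.
#' @return vector of \eqn{\chi''} values.
#' @export
kww_loss_spectrum <- function(x, beta, n_grid = 4096) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  if (any(x <= 0)) stop("x must be > 0")
  u_min <- 1e-6
  u_max <- max(50, (27.6)^(1 / beta))  # exp(-u^beta) ~ 1e-12 at u_max
  u <- exp(seq(log(u_min), log(u_max), length.out = n_grid + 1L))
  phi <- exp(-u^beta)
  u1 <- u[-length(u)]; u2 <- u[-1L]
  p1 <- phi[-length(phi)]; p2 <- phi[-1L]
  du <- u2 - u1
  B <- (p2 - p1) / du
  vapply(x, function(xi) {
    # head [0, u_min]: Phi ~ 1
    head_int <- sin(xi * u_min) / xi
    narrow <- xi * du < 1e-5
    s1 <- sin(xi * u1); s2 <- sin(xi * u2)
    c1 <- cos(xi * u1); c2 <- cos(xi * u2)
    filon <- (p2 * s2 - p1 * s1) / xi + B * (c2 - c1) / xi^2
    trap <- 0.5 * (p1 * c1 + p2 * c2) * du
    xi * (head_int + sum(ifelse(narrow, trap, filon)))
  }, numeric(1))
}

# Reduced peak position and height of the KWW loss for a given beta.
.kww_peak <- function(beta, n_grid = 4096) {
  opt <- stats::optimize(function(lx) -kww_loss_spectrum(exp(lx), beta, n_grid),
                         interval = c(-2.5, 1.5), tol = 1e-6)
  list(x_peak = exp(opt$minimum), chi_max = -opt$objective)
}

#' Normalized KWW loss peak
#'
#' Loss curve normalized to its maximum on both axes, the form in which
#' alpha-relaxation peak shapes are compared across samples:
#' \eqn{\chi''/\chi''_{max}} versus \eqn{f/f_{max}}.
#'
#' @param f_rel reduced frequencies \eqn{f/f_{max}} (> 0).
#' @param beta stretching exponent in (0, 1].
#' @return vector of normalized loss values (1 at \code{f_rel = 1}).
#' @export
kww_normalized_loss <- function(f_rel, beta) {
  pk <- .kww_peak(beta)
  kww_loss_spectrum(f_rel * pk$x_peak, beta) / pk$chi_max
}

#' Stretching exponent from the shape of a normalized alpha-relaxation peak
#'
#' Fits the normalized measured loss peak (\eqn{\varepsilon''/
#' \varepsilon''_{max}} vs \eqn{f/f_{max}}) to the numerically transformed
#' KWW loss by least squares over \eqn{\beta_{KWW}} alone; the frequency
#' axis is anchored by the peak maximum of each curve, so no time-scale
#' parameter is fitted.  Broader peaks yield smaller \eqn{\beta_{KWW}}.
#'
#' @param spec a [dielectric_spectrum()] object containing the alpha peak.
#' @param alpha_window numeric length-2, frequency window (Hz) bracketing
#'   the peak; the peak maximum must fall strictly inside it.
#' @param beta_bounds search interval for \eqn{\beta_{KWW}}.
#' @return list with \code{beta_kww}, \code{f_max} (Hz), \code{rss} and the
#'   fitted normalized curve (\code{f_rel}, \code{loss_fit}).
#' @export
kww_shape_fit <- function(spec, alpha_window = range(spec$freq),
                          beta_bounds = c(0.2, 1)) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  sel <- spec$freq >= alpha_window[1] & spec$freq <= alpha_window[2]
  if (sum(sel) < 5L) stop("fewer than 5 points inside alpha_window")
  f <- spec$freq[sel]; loss <- spec$eps_imag[sel]
  ipk <- which.max(loss)
  if (ipk == 1L || ipk == length(f))
    stop("alpha peak truncated: maximum lies on the window edge")
  f_max <- f[ipk]
  x_data <- f / f_max
  y_data <- loss / loss[ipk]
  obj <- function(beta) sum((kww_normalized_loss(x_data, beta) - y_data)^2)
  opt <- stats::optimize(obj, interval = beta_bounds, tol = 1e-4)
  beta <- opt$minimum
  list(beta_kww = beta, f_max = f_max, rss = opt$objective,
       f_rel = x_data, loss_fit = kww_normalized_loss(x_data, beta))
}
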