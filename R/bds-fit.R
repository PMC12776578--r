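#' Broadband dielectric spectrum at one temperature
#'
#' @param temperature sample temperature in K.
#' @param freq measurement frequencies in Hz, strictly increasing,
#'   length >= 8.
#' @param eps_real real permittivity \eqn{\varepsilon'} at each frequency.
#' @param eps_imag dielectric loss \eqn{\varepsilon''} at each frequency
#'   (cleaned: nonpositive values allowed on input but dropped by fitters).
#' @param sample sample label.
#' @param thickness_mm optional film thickness, mm.
#' @return an object of class \code{"dielectric_spectrum"}.
#' @export
dielectric_spectrum <- function(temperature, freq, eps_real, eps_imag,
                                sample = "sample", thickness_mm = NA_real_) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(freq), is.numeric(eps_real), is.numeric(eps_imag))
  if (length(freq) < 8L) stop("need at least 8 frequency points")
  if (length(freq) != length(eps_real) || length(freq) != length(eps_imag))
    stop("freq, eps_real, eps_imag must have equal length")
  if (any(diff(freq) <= 0)) stop("freq must be strictly increasing")
  structure(list(temperature = temperature, freq = freq,
                 eps_real = eps_real, eps_imag = eps_imag,
                 meta = list(sample = sample, thickness_mm = thickness_mm)),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("Dielectric spectrum [%s] at %.1f K: %d points, %.2g-%.2g Hz\n",
              x$meta$sample, x$temperature, length(x$freq),
              min(x$freq), max(x$freq)))
  invisible(x)
}

#' Mode template for spectrum deconvolution
#'
#' Initial guess for one relaxation mode in [fit_spectrum()].  Secondary
#' (non-alpha) modes are Cole-Cole: \code{b} is fixed at 1.  For the alpha
#' mode \code{b} is a free fit parameter unless \code{fix_b = TRUE}.
#'
#' @param label process name (\code{"alpha"}, \code{"beta"}, \code{"gamma"},
#'   \code{"delta"}).
#' @param delta_eps,tau_hn,a,b starting values (see [hn_mode()]).
#' @param fix_b fix \code{b} at its starting value (always TRUE for
#'   secondary modes).
#' @return list usable in the \code{template} of [fit_spectrum()].
#' @export
mode_template <- function(label, delta_eps, tau_hn, a, b = 1, fix_b = NULL) {
  if (is.null(fix_b)) fix_b <- label != "alpha"
  if (label != "alpha" && b != 1)
    stop("secondary modes are Cole-Cole: b must be 1")
  list(label = label, delta_eps = delta_eps, tau_hn = tau_hn,
       a = a, b = b, fix_b = fix_b)
}

#' Deconvolute one dielectric-loss spectrum into HN/CC modes
#'
#' Nonlinear least squares of \eqn{\log_{10}\varepsilon''} against
#' \eqn{\log_{10} f} (logarithmic residuals weight the nine-decade window
#' evenly, so weak secondary modes are not drowned by the alpha peak).
#' Levenberg-Marquardt with box bounds: \code{0 < a <= 1}, \code{b = 1}
#' fixed for all secondary modes.  Nonpositive loss points are dropped
#' before fitting.
#'
#' @param spec a [dielectric_spectrum()].
#' @param template list of [mode_template()] entries (or a previous
#'   \code{spectrum_fit} whose modes seed the new fit), declaring which
#'   modes to include and their starting values.
#' @param sigma_dc starting dc conductivity (S/m); 0 (default) excludes the
#'   conductivity term from the model, > 0 fits it.
#' @param eps_inf high-frequency permittivity, recorded in the result (the
#'   loss-only objective does not constrain it).
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @return an object of class \code{"spectrum_fit"}: fields \code{modes}
#'   (list of [hn_mode()]), \code{eps_inf}, \code{sigma_dc},
#'   \code{residual_rms} (RMS of log10 residuals), \code{converged},
#'   \code{temperature}.  Optimizer nonconvergence yields
#'   \code{converged = FALSE} with best-effort parameters, never an error.
#' @export
fit_spectrum <- function(spec, template, sigma_dc = 0, eps_inf = 3,
                         maxit = 200) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  if (inherits(template, "spectrum_fit")) template <- .fit_to_template(template)
  labels <- vapply(template, `[[`, character(1), "label")
  if (sum(labels == "alpha") > 1L) stop("at most one alpha mode")
  keep <- spec$eps_imag > 0
  f <- spec$freq[keep]
  y <- log10(spec$eps_imag[keep])

  # parameter packing: per mode log10(delta_eps), log10(tau), a, [b];
  # optional log10(sigma_dc)
  par <- c(); lower <- c(); upper <- c(); idx <- list()
  for (k in seq_along(template)) {
    tm <- template[[k]]
    free_b <- !tm$fix_b
    i0 <- length(par)
    par <- c(par, log10(tm$delta_eps), log10(tm$tau_hn), tm$a,
             if (free_b) tm$b)
    lower <- c(lower, -8, -16, 0.05, if (free_b) 0.05)
    upper <- c(upper, 8, 8, 1, if (free_b) 1)
    idx[[k]] <- list(i = i0, free_b = free_b, b = tm$b, label = tm$label)
  }
  fit_sigma <- sigma_dc > 0
  if (fit_sigma) {
    par <- c(par, log10(sigma_dc)); lower <- c(lower, -20); upper <- c(upper, 2)
  }
  if (length(par) >= length(f))
    stop("fewer data points than free parameters")

  unpack <- function(p) {
    modes <- lapply(idx, function(ix) {
      b <- if (ix$free_b) p[ix$i + 4L] else ix$b
      hn_mode(10^p[ix$i + 1L], 10^p[ix$i + 2L], p[ix$i + 3L], b,
              label = ix$label)
    })
    sdc <- if (fit_sigma) 10^p[length(p)] else 0
    list(modes = modes, sigma_dc = sdc)
  }
  resid_fun <- function(p) {
    mp <- unpack(p)
    loss <- -Im(hn_complex_permittivity(f, mp$modes, eps_inf = 0,
                                        sigma_dc = mp$sigma_dc))
    log10(pmax(loss, 1e-300)) - y
  }
  res <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxit, ftol = 1e-12, ptol = 1e-12))
  mp <- unpack(res$par)
  structure(list(modes = mp$modes, eps_inf = eps_inf,
                 sigma_dc = mp$sigma_dc,
                 residual_rms = sqrt(mean(res$fvec^2)),
                 converged = res$info %in% 1:3,
                 temperature = spec$temperature),
            class = "spectrum_fit")
}

.fit_to_template <- function(fit) {
  lapply(fit$modes, function(m)
    mode_template(m$label, m$delta_eps, m$tau_hn, m$a, m$b))
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Spectrum fit at %.1f K (%sconverged, rms %.3g):\n",
              x$temperature, if (x$converged) "" else "NOT ", x$residual_rms))
  for (m in x$modes) print(m)
  if (x$sigma_dc > 0) cat(sprintf("  sigma_dc = %.3g S/m\n", x$sigma_dc))
  invisible(x)
}
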