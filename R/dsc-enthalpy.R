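#' Enthalpy-recovery series at one annealing temperature
#'
#' Recovered enthalpies \eqn{\Delta H_t} measured after annealing a glass
#' at \eqn{T_a} for increasing times (the subtraction of annealed minus
#' non-annealed nonreversing heat-flow curves is upstream instrument work;
#' this container takes the already-integrated values).
#'
#' @param ta annealing temperature, degC.
#' @param t_min annealing times in minutes, strictly increasing.
#' @param dh_t recovered enthalpies, J/g (>= 0).
#' @param sample sample label.
#' @return an object of class \code{"enthalpy_recovery_series"}.
#' @export
enthalpy_recovery_series <- function(ta, t_min, dh_t, sample = "sample") {
  stopifnot(is.numeric(ta), length(ta) == 1L,
            is.numeric(t_min), is.numeric(dh_t),
            length(t_min) == length(dh_t))
  if (any(diff(t_min) <= 0)) stop("t_min must be strictly increasing")
  if (any(dh_t < 0)) stop("dh_t must be >= 0")
  structure(list(ta = ta, t_min = t_min, dh_t = dh_t, sample = sample),
            class = "enthalpy_recovery_series")
}

#' KWW fit of enthalpy recovery below the glass transition
#'
#' Converts recovered enthalpies to the relaxation function
#' \eqn{\Phi = 1 - \Delta H_t/\Delta H_\infty} with
#' \eqn{\Delta H_\infty = \Delta C_p (T_g - T_a)}, then fits
#' \eqn{\Phi(t) = \exp[-(t/\tau_\alpha)^{\beta_{KWW}}]} by unweighted
#' least squares.  The relaxation time is reported in minutes, the
#' conventional unit for calorimetric annealing experiments, and
#' \eqn{\tau_\alpha^{\beta_{KWW}}} is recomputed from the fitted pair.
#'
#' @param series an [enthalpy_recovery_series()] with >= 4 points.
#' @param tg glass-transition temperature, degC; must exceed
#'   \code{series$ta}.
#' @param delta_cp heat-capacity step at Tg, J/(g K).
#' @param dh_inf optional sample-specific maximum recovery, J/g; overrides
#'   the \eqn{\Delta C_p (T_g - T_a)} default.
#' @return a [kww_fit()] (unit \code{"min"}) with extra fields
#'   \code{dh_inf}, \code{phi}, \code{phi_fit}, \code{rss}.
#' @export
fit_enthalpy_recovery <- function(series, tg, delta_cp, dh_inf = NULL) {
  stopifnot(inherits(series, "enthalpy_recovery_series"))
  if (length(series$t_min) < 4L) stop("need at least 4 time points")
  if (!(tg > series$ta)) stop("annealing temperature must be below tg")
  if (is.null(dh_inf)) dh_inf <- dh_infinity(delta_cp, tg, series$ta)
  phi <- suppressWarnings(phi_from_recovery(series$dh_t, dh_inf))
  if (any(phi < 0))
    stop("over-recovery: Phi < 0 at t = ",
         paste(series$t_min[phi < 0], collapse = ", "), " min")
  t <- series$t_min
  # initial tau: time at which Phi crosses 1/e (log-interpolated), else median t
  tau0 <- if (any(phi < exp(-1)) && any(phi > exp(-1))) {
    exp(stats::approx(rev(as.numeric(phi)), rev(log(t)), xout = exp(-1),
                      ties = mean)$y)
  } else exp(mean(log(t)))
  if (!is.finite(tau0)) tau0 <- exp(mean(log(t)))
  res <- minpack.lm::nls.lm(
    par = c(log(tau0), 0.6),
    lower = c(log(min(t)) - 15, 0.05), upper = c(log(max(t)) + 15, 1),
    fn = function(p) exp(-(t / exp(p[1]))^p[2]) - phi,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-14, ptol = 1e-14))
  tau <- exp(res$par[1]); beta <- res$par[2]
  out <- kww_fit(tau, beta, unit = "min")
  out$dh_inf <- dh_inf
  out$phi <- as.numeric(phi)
  out$phi_fit <- exp(-(t / tau)^beta)
  out$rss <- sum(res$fvec^2)
  out
}
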