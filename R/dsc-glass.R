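#' DSC thermogram container
#'
#' @param temperature program temperature in degC, monotone in the scan
#'   direction, length >= 50.
#' @param heat_flow heat-flow signal (W/g) or heat-capacity-like signal for
#'   reversing channels.
#' @param channel one of \code{"total"}, \code{"reversing"},
#'   \code{"nonreversing"}.
#' @param scan_rate heating (positive) or cooling (negative) rate, degC/min;
#'   must be nonzero.
#' @param exo_up logical; TRUE if exothermic events point up (recorded
#'   convention, used by the peak extractors).
#' @param sample sample label.
#' @return an object of class \code{"thermogram"}.
#' @export
thermogram <- function(temperature, heat_flow, channel = "total",
                       scan_rate = 10, exo_up = TRUE, sample = "sample") {
  stopifnot(is.numeric(temperature), is.numeric(heat_flow),
            length(temperature) == length(heat_flow))
  if (length(temperature) < 50L) stop("need at least 50 points")
  if (scan_rate == 0) stop("scan_rate must be nonzero")
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0)))
    stop("temperature must be monotone in the scan direction")
  channel <- match.arg(channel, c("total", "reversing", "nonreversing"))
  structure(list(temperature = temperature, heat_flow = heat_flow,
                 channel = channel, scan_rate = scan_rate,
                 exo_up = exo_up, sample = sample),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram [%s, %s]: %d points, %.1f to %.1f C at %g C/min\n",
              x$sample, x$channel, length(x$temperature),
              min(x$temperature), max(x$temperature), x$scan_rate))
  invisible(x)
}

#' Slice a thermogram to a temperature window
#'
#' @param trace a [thermogram()].
#' @param range numeric length-2 temperature window, degC.
#' @return a thermogram restricted to the window (same metadata).
#' @export
slice_thermogram <- function(trace, range) {
  stopifnot(inherits(trace, "thermogram"), length(range) == 2L)
  keep <- trace$temperature >= min(range) & trace$temperature <= max(range)
  if (sum(keep) < 50L) stop("window contains fewer than 50 points")
  thermogram(trace$temperature[keep], trace$heat_flow[keep], trace$channel,
             trace$scan_rate, trace$exo_up, trace$sample)
}

# light running-mean smoother used by the feature detectors
.smooth_k <- function(y, k = 5L) {
  if (k <= 1L) return(y)
  as.numeric(stats::filter(y, rep(1 / k, k), sides = 2L)) -> ys
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

#' Detect a glass transition in a heat-capacity step region
#'
#' Standard tangent construction: linear baselines are fitted to the
#' leading and trailing quarters of the slice; the tangent at the point of
#' maximum derivative is intersected with them to give the onset and end
#' temperatures.  The midpoint is where the signal crosses halfway between
#' the baselines, and \eqn{\Delta C_p} is the baseline gap evaluated at
#' the midpoint.  The slice must contain one sigmoidal step; a step
#' smaller than five times the pre-transition noise is rejected.
#'
#' @param tg_region a [thermogram()] slice containing a single
#'   heat-capacity step (signal in J/(g K) units, or any units in which the
#'   step height is \eqn{\Delta C_p}).
#' @param baseline_frac fraction of points at each end used for the
#'   baseline fits.
#' @return object of class \code{"glass_transition"}: \code{tg_onset},
#'   \code{tg_mid}, \code{tg_end} (degC), \code{delta_cp}, \code{width}.
#' @export
detect_glass_transition <- function(tg_region, baseline_frac = 0.25) {
  stopifnot(inherits(tg_region, "thermogram"))
  x <- tg_region$temperature; y <- tg_region$heat_flow
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  n <- length(x)
  nb <- max(5L, floor(n * baseline_frac))
  pre <- stats::lm(y ~ x, data = data.frame(x = x[1:nb], y = y[1:nb]))
  post <- stats::lm(y ~ x,
                    data = data.frame(x = x[(n - nb + 1):n],
                                      y = y[(n - nb + 1):n]))
  pre_at <- function(t) stats::coef(pre)[1] + stats::coef(pre)[2] * t
  post_at <- function(t) stats::coef(post)[1] + stats::coef(post)[2] * t
  noise <- stats::sd(stats::resid(pre))

  ys <- .smooth_k(y)
  dydx <- diff(ys) / diff(x)
  interior <- seq.int(nb, n - nb)
  imax <- interior[which.max(dydx[pmin(interior, n - 1L)])]
  slope <- dydx[imax]
  xt <- (x[imax] + x[imax + 1L]) / 2
  yt <- (ys[imax] + ys[imax + 1L]) / 2

  onset <- (stats::coef(pre)[1] - (yt - slope * xt)) /
    (slope - stats::coef(pre)[2])
  tg_end <- (stats::coef(post)[1] - (yt - slope * xt)) /
    (slope - stats::coef(post)[2])
  onset <- unname(onset); tg_end <- unname(tg_end)
  if (!is.finite(onset) || !is.finite(tg_end) || tg_end <= onset)
    stop("no glass-transition step found in the region")

  # midpoint: signal crosses halfway between the two baselines
  half <- (pre_at(x) + post_at(x)) / 2
  cross <- which(diff(sign(ys - half)) != 0)
  cross <- cross[x[cross] > onset - 2 & x[cross] < tg_end + 2]
  if (length(cross) == 0L)
    stop("no glass-transition step found in the region")
  i <- cross[1L]
  frac <- (half[i] - ys[i]) / ((ys[i + 1L] - ys[i]) - (half[i + 1L] - half[i]))
  tg_mid <- x[i] + frac * (x[i + 1L] - x[i])

  delta_cp <- unname(post_at(tg_mid) - pre_at(tg_mid))
  if (!is.finite(delta_cp) || delta_cp < 5 * noise || delta_cp <= 0)
    stop("no glass-transition step found in the region ",
         "(step below 5x baseline noise)")
  structure(list(tg_onset = onset, tg_mid = unname(tg_mid),
                 tg_end = tg_end, delta_cp = delta_cp,
                 width = tg_end - onset),
            class = "glass_transition")
}

#' @export
print.glass_transition <- function(x, ...) {
  cat(sprintf(
    "Glass transition: onset %.2f C, mid %.2f C, end %.2f C (width %.2f C), delta_Cp %.3f\n",
    x$tg_onset, x$tg_mid, x$tg_end, x$width, x$delta_cp))
  invisible(x)
}

#' Cooperatively-rearranging-region size from a detected glass transition
#'
#' Converts laboratory units (degC, g/cm^3, J/(g K)) to SI, forms the
#' Donth inputs (onset Tg; half the transition width) and reports the CRR
#' length in nanometers.  See [donth_crr_length()].
#'
#' @param gt a [detect_glass_transition()] result, or any list with
#'   \code{tg_onset} (degC) and \code{width} (degC).
#' @param rho density, g/cm^3.
#' @param cpg,cpl glass and supercooled-liquid specific heats, J/(g K).
#' @return CRR length in nm.
#' @export
crr_size <- function(gt, rho, cpg, cpl) {
  stopifnot(!is.null(gt$tg_onset), !is.null(gt$width))
  inputs <- crr_inputs(tg_onset = celsius_to_kelvin(gt$tg_onset),
                       half_width = gt$width / 2,
                       rho = rho * 1000,
                       cpg = cpg * 1000, cpl = cpl * 1000)
  donth_crr_length(inputs) * 1e9
}

#' Remaining glass fraction from the heat-capacity step
#'
#' The ratio of the measured \eqn{\Delta C_p} at Tg after storage to its
#' initial value tracks the surviving amorphous fraction during isothermal
#' crystallization.  Values slightly above 1 (measurement scatter) are kept
#' up to 1.05 and flagged; the result is clipped to [0, 1.05].
#'
#' @param delta_cp_stored heat-capacity step after storage, J/(g K).
#' @param delta_cp_initial initial heat-capacity step, J/(g K) (> 0).
#' @return fraction in [0, 1.05] with logical attribute
#'   \code{"above_unity"}.
#' @export
remaining_glass_fraction <- function(delta_cp_stored, delta_cp_initial) {
  if (!(delta_cp_initial > 0)) stop("delta_cp_initial must be > 0")
  if (any(delta_cp_stored < 0)) stop("delta_cp_stored must be >= 0")
  r <- delta_cp_stored / delta_cp_initial
  above <- any(r > 1)
  r <- pmin(pmax(r, 0), 1.05)
  attr(r, "above_unity") <- above
  r
}
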