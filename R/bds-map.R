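# Relaxation maps: per-process tau(T) collected across temperatures, with
# Arrhenius fits for secondary processes, a VFT fit for the alpha process,
# and Coupling-Model Johari-Goldstein predictions.

#' Build a relaxation map from per-temperature spectrum fits
#'
#' Associates fitted modes across temperatures by their process label
#' (label continuity wins over tau proximity; a crossing of two processes
#' in tau does not swap them) and converts every mode to its model-free
#' relaxation time via [tau_alpha_from_hn()].  Candidate ambiguity -- two
#' modes of adjacent temperatures closer than 0.3 in \eqn{\log_{10}\tau}
#' but with different labels -- is flagged, not resolved by proximity.
#' A label present at fewer than half of the temperatures is excluded with
#' a warning.
#'
#' @param fits list of [fit_spectrum()] results, ordered by temperature.
#' @return object of class \code{"relaxation_map"}: \code{points} (data
#'   frame with \code{process}, \code{T_K}, \code{tau_s},
#'   \code{delta_eps}), plus slots \code{arrhenius} (named list, filled by
#'   [map_fit_arrhenius()]), \code{vft} ([fit_alpha_vft()]) and
#'   \code{jg_predicted} ([predict_jg()]).
#' @export
track_modes <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "spectrum_fit")))
  ord <- order(vapply(fits, `[[`, numeric(1), "temperature"))
  fits <- fits[ord]
  rows <- do.call(rbind, lapply(fits, function(ft) {
    do.call(rbind, lapply(ft$modes, function(m)
      data.frame(process = m$label, T_K = ft$temperature,
                 tau_s = tau_alpha_from_hn(m), delta_eps = m$delta_eps,
                 stringsAsFactors = FALSE)))
  }))
  if (any(rows$tau_s <= 0) || any(!is.finite(rows$tau_s)))
    stop("non-positive or non-finite tau in fits")
  n_T <- length(fits)
  counts <- table(rows$process)
  drop <- names(counts)[counts < n_T / 2 & n_T > 1L]
  if (length(drop)) {
    warning("process(es) missing at more than half of the temperatures, ",
            "excluded: ", paste(drop, collapse = ", "))
    rows <- rows[!rows$process %in% drop, , drop = FALSE]
  }
  # flag ambiguous adjacent-temperature assignments (diagnostic only)
  ambiguous <- FALSE
  for (i in seq_len(n_T - 1L)) {
    a <- fits[[i]]$modes; b <- fits[[i + 1L]]$modes
    for (ma in a) for (mb in b) {
      if (ma$label != mb$label &&
          abs(log10(tau_alpha_from_hn(ma)) -
              log10(tau_alpha_from_hn(mb))) < 0.3)
        ambiguous <- TRUE
    }
  }
  structure(list(points = rows, arrhenius = list(), vft = NULL,
                 jg_predicted = NULL, ambiguous = ambiguous),
            class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat("Relaxation map:\n")
  for (p in unique(x$points$process)) {
    sub <- x$points[x$points$process == p, ]
    cat(sprintf("  %-6s %2d temperatures, tau %.3g-%.3g s\n",
                p, nrow(sub), min(sub$tau_s), max(sub$tau_s)))
  }
  if (length(x$arrhenius))
    for (p in names(x$arrhenius))
      cat(sprintf("  Arrhenius[%s]: Ea = %.1f kJ/mol\n", p, x$arrhenius[[p]]$ea))
  if (!is.null(x$vft)) print(x$vft)
  invisible(x)
}

#' Arrhenius fit of one secondary process in a relaxation map
#'
#' @param map a [track_modes()] relaxation map.
#' @param process process label to fit (e.g. \code{"gamma"}).
#' @return the map with \code{arrhenius[[process]]} set to an
#'   [arrhenius_fit()] of \eqn{\ln\tau} vs 1/T.
#' @export
map_fit_arrhenius <- function(map, process) {
  stopifnot(inherits(map, "relaxation_map"))
  sub <- map$points[map$points$process == process, ]
  if (nrow(sub) < 2L) stop("need >= 2 temperatures for process ", process)
  map$arrhenius[[process]] <- arrhenius_fit(1 / sub$T_K, log(sub$tau_s))
  map
}

#' VFT fit of the alpha process in a relaxation map
#'
#' Least squares of \eqn{\log_{10}\tau_\alpha} on T with the VFT law.
#' \code{fix_log_tau_inf} pins the pre-exponential (the conventional
#' choice \eqn{\log_{10}\tau_\infty = -14} keeps D and \eqn{T_0}
#' physically interpretable; freeing it typically drifts it to unusually
#' small values).  \code{tg_constraint} enforces
#' \eqn{\tau(T_g) = \tau_g} exactly by eliminating D:
#' \eqn{D = \ln(\tau_g/\tau_\infty)(T_g - T_0)/T_0}.
#'
#' @param map a [track_modes()] relaxation map with >= 3 alpha points.
#' @param fix_log_tau_inf optional fixed \eqn{\log_{10}\tau_\infty}.
#' @param tg_constraint optional \code{c(Tg_K, tau_g_s)}; the fitted curve
#'   passes through it exactly.
#' @return a [vft_fit()] object.
#' @export
fit_alpha_vft <- function(map, fix_log_tau_inf = NULL, tg_constraint = NULL) {
  stopifnot(inherits(map, "relaxation_map"))
  sub <- map$points[map$points$process == "alpha", ]
  if (nrow(sub) < 3L) stop("need >= 3 alpha points for a VFT fit")
  T <- sub$T_K; lt <- log10(sub$tau_s)
  T0_max <- min(T) - 1
  free_lti <- is.null(fix_log_tau_inf)
  constrained <- !is.null(tg_constraint)
  if (constrained) {
    stopifnot(length(tg_constraint) == 2L, tg_constraint[2] > 0)
    Tg <- tg_constraint[1]; tau_g <- tg_constraint[2]
  }
  model_lt <- function(p) {
    lti <- if (free_lti) p[1] else fix_log_tau_inf
    T0 <- p[length(p)]
    D <- if (constrained) {
      log(tau_g / 10^lti) * (Tg - T0) / T0
    } else p[length(p) - 1L]
    lti + D * T0 / (log(10) * (T - T0))
  }
  if (constrained) {
    par <- c(if (free_lti) -14, 0.8 * min(T))
    lower <- c(if (free_lti) -20, 10); upper <- c(if (free_lti) -6, T0_max)
  } else {
    par <- c(if (free_lti) -14, 7, 0.8 * min(T))
    lower <- c(if (free_lti) -20, 0.1, 10)
    upper <- c(if (free_lti) -6, 100, T0_max)
  }
  res <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = function(p) model_lt(p) - lt,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- res$par
  lti <- if (free_lti) p[1] else fix_log_tau_inf
  T0 <- p[length(p)]
  D <- if (constrained) log(tau_g / 10^lti) * (Tg - T0) / T0
       else p[length(p) - 1L]
  vft_fit(lti, D, T0)
}

#' Coupling-Model JG predictions along the alpha process
#'
#' Applies [cm_primitive_tau()] at every temperature of the map's alpha
#' process, giving the predicted Johari-Goldstein relaxation times (the
#' "primitive" times of the Coupling Model).
#'
#' @param map a [track_modes()] relaxation map.
#' @param beta_kww stretching exponent of the alpha process.
#' @param tc crossover time, seconds (default 2 ps).
#' @return the map with \code{jg_predicted} set to a data frame
#'   (\code{T_K}, \code{tau_jg_s}); empty if the map has no alpha points.
#' @export
predict_jg <- function(map, beta_kww, tc = 2e-12) {
  stopifnot(inherits(map, "relaxation_map"))
  sub <- map$points[map$points$process == "alpha", ]
  if (nrow(sub) == 0L) {
    map$jg_predicted <- data.frame(T_K = numeric(0), tau_jg_s = numeric(0))
    return(map)
  }
  pars <- cm_params(n = 1 - beta_kww, tc = tc)
  map$jg_predicted <- data.frame(
    T_K = sub$T_K,
    tau_jg_s = cm_primitive_tau(sub$tau_s, params = pars))
  map
}

#' Extrapolate alpha-relaxation times below Tg by master-plot shifting
#'
#' Time-temperature superposition: each below-Tg loss spectrum is
#' normalized to its maximum in the window and shifted horizontally in
#' \eqn{\log_{10} f} until it superposes on the reference curve (the model
#' loss of \code{reference}, whose alpha time is known).  The overlap
#' metric is the mean squared difference of the normalized curves on the
#' shared log-frequency support; the shift is located by a 0.01-decade
#' grid search followed by parabolic refinement.  A spectrum requiring a
#' shift of s decades to the right corresponds to
#' \eqn{\tau_\alpha = \tau_{\alpha,ref}\cdot 10^{s}}.
#'
#' @param specs_below_tg list of [dielectric_spectrum()] measured below Tg.
#' @param reference a [fit_spectrum()] result with a resolved alpha mode.
#' @param shift_range decades searched either side of zero.
#' @return data frame with \code{T_K}, \code{shift_decades},
#'   \code{tau_alpha_s}.
#' @export
masterplot_extrapolate <- function(specs_below_tg, reference,
                                   shift_range = c(-2, 10)) {
  stopifnot(inherits(reference, "spectrum_fit"))
  if (inherits(specs_below_tg, "dielectric_spectrum"))
    specs_below_tg <- list(specs_below_tg)
  alpha <- Filter(function(m) m$label == "alpha", reference$modes)
  if (length(alpha) != 1L) stop("reference must contain one alpha mode")
  tau_ref <- tau_alpha_from_hn(alpha[[1L]])
  # reference curve on a dense grid, wide enough for any admissible shift
  lf_ref <- seq(-6 + shift_range[1], 9 + shift_range[2], by = 0.01)
  loss_ref <- -Im(hn_complex_permittivity(10^lf_ref, reference$modes,
                                          eps_inf = 0))
  loss_ref <- loss_ref / max(loss_ref)
  ref_at <- stats::approxfun(lf_ref, loss_ref)

  out <- lapply(specs_below_tg, function(sp) {
    keep <- sp$eps_imag > 0
    lf <- log10(sp$freq[keep])
    yn <- sp$eps_imag[keep] / max(sp$eps_imag[keep])
    metric <- function(s) {
      ys <- ref_at(lf + s)
      ok <- !is.na(ys)
      if (sum(ok) < 5L) return(NA_real_)
      mean((yn[ok] - ys[ok])^2)
    }
    grid <- seq(shift_range[1], shift_range[2], by = 0.01)
    m <- vapply(grid, metric, numeric(1))
    if (all(is.na(m)))
      stop("no overlap between spectrum and reference in any shift")
    i <- which.min(m)
    s <- grid[i]
    if (i > 1L && i < length(grid) &&
        is.finite(m[i - 1L]) && is.finite(m[i + 1L])) {
      # parabolic refinement through the three bracketing grid points
      d <- (m[i - 1L] - m[i + 1L]) / (2 * (m[i - 1L] - 2 * m[i] + m[i + 1L]))
      if (is.finite(d) && abs(d) <= 1) s <- s + d * 0.01
    }
    data.frame(T_K = sp$temperature, shift_decades = s,
               tau_alpha_s = tau_ref * 10^s)
  })
  do.call(rbind, out)
}
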