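# Long-term stability summaries: nucleation assay probabilities,
# polarized-light-microscopy radial growth rates, storage trends.

#' Summarize a cold-crystallization nucleation assay
#'
#' A nucleation assay anneals replicate glass samples at a candidate
#' nucleation temperature and scores each for cold crystallization on
#' reheating.  The crystallization probability is the exact fraction
#' \eqn{k/n}; enthalpy and onset statistics are means over the
#' crystallized replicates only.  A Clopper-Pearson 95 percent interval
#' for the probability is included.
#'
#' @param crystallized logical vector, one flag per replicate.
#' @param ta annealing temperature, degC.
#' @param enthalpy optional per-replicate cold-crystallization enthalpies,
#'   J/g (NA for non-crystallized replicates is fine).
#' @param t_onset optional per-replicate onset temperatures, degC.
#' @return object of class \code{"nucleation_assay"}: \code{ta},
#'   \code{n_total}, \code{n_crystallized}, \code{probability},
#'   \code{ci95}, \code{enthalpy_mean}, \code{enthalpy_sd},
#'   \code{t_onset_mean}, \code{t_onset_sd}.
#' @export
nucleation_summary <- function(crystallized, ta = NA_real_,
                               enthalpy = NULL, t_onset = NULL) {
  stopifnot(is.logical(crystallized), length(crystallized) >= 1L)
  n <- length(crystallized); k <- sum(crystallized)
  ci <- as.numeric(stats::binom.test(k, n)$conf.int)
  stat <- function(v) {
    if (is.null(v)) return(c(NA_real_, NA_real_))
    v <- v[crystallized & !is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1L) stats::sd(v) else NA_real_)
  }
  e <- stat(enthalpy); o <- stat(t_onset)
  structure(list(ta = ta, n_total = n, n_crystallized = k,
                 probability = k / n, ci95 = ci,
                 enthalpy_mean = e[1], enthalpy_sd = e[2],
                 t_onset_mean = o[1], t_onset_sd = o[2]),
            class = "nucleation_assay")
}

#' @export
print.nucleation_assay <- function(x, ...) {
  cat(sprintf("Nucleation assay at %.0f C: %d/%d crystallized (p = %.2f, 95%% CI %.2f-%.2f)\n",
              x$ta, x$n_crystallized, x$n_total, x$probability,
              x$ci95[1], x$ci95[2]))
  if (!is.na(x$enthalpy_mean))
    cat(sprintf("  enthalpy %.1f +/- %.1f J/g, T_onset %.1f +/- %.1f C\n",
                x$enthalpy_mean, x$enthalpy_sd, x$t_onset_mean, x$t_onset_sd))
  invisible(x)
}

#' Radial crystal growth track
#'
#' @param direction direction index (1-16 for the standard 16-line radial
#'   analysis).
#' @param time_s observation times, seconds.
#' @param radius_um crystal radii, micrometers, nondecreasing.
#' @return an object of class \code{"growth_track"}.
#' @export
growth_track <- function(direction, time_s, radius_um) {
  stopifnot(length(time_s) == length(radius_um), length(time_s) >= 2L)
  if (any(diff(radius_um) < 0)) stop("radius must be nondecreasing")
  structure(list(direction = direction, time_s = time_s,
                 radius_um = radius_um),
            class = "growth_track")
}

#' Per-direction crystal growth rates and their distribution
#'
#' Each radial track contributes the least-squares slope of radius versus
#' time (so the result is invariant to time-origin shifts).  The summary
#' reports the mean and sample standard deviation over directions and,
#' when two growth populations are present (partial adsorption of polymer
#' on the growth front splits the rate distribution), an optional
#' two-component equal-variance Gaussian mixture fitted by EM; the split
#' is reported only when BIC prefers two components over one.
#'
#' @param tracks list of [growth_track()] objects (>= 1).
#' @param mixture attempt the two-component mixture split (needs >= 6
#'   usable tracks).
#' @return object of class \code{"growth_rates"}: \code{rates} (data frame
#'   direction/rate_um_s), \code{mean}, \code{sd}, \code{n_rejected}, and
#'   \code{mixture} (NULL, or list with \code{means}, \code{weights},
#'   \code{sd}) when a two-population split is supported.
#' @export
growth_rates <- function(tracks, mixture = TRUE) {
  if (inherits(tracks, "growth_track")) tracks <- list(tracks)
  rates <- numeric(0); dirs <- numeric(0); rejected <- 0L
  for (tr in tracks) {
    if (!inherits(tr, "growth_track")) {
      # raw list input: validate here, rejecting decreasing tracks
      ok <- tryCatch({ tr <- growth_track(tr$direction, tr$time_s, tr$radius_um); TRUE },
                     error = function(e) FALSE)
      if (!ok) { rejected <- rejected + 1L
                 warning("track rejected (decreasing radius)"); next }
    }
    slope <- unname(stats::coef(stats::lm(tr$radius_um ~ tr$time_s))[2])
    rates <- c(rates, slope); dirs <- c(dirs, tr$direction)
  }
  if (length(rates) == 0L) stop("no usable tracks")
  mix <- NULL
  if (mixture && length(rates) >= 6L && stats::sd(rates) > 0) {
    fit2 <- tryCatch(
      Mclust(rates, G = 2, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
    fit1 <- tryCatch(
      Mclust(rates, G = 1, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit1) && !is.null(fit2) && fit2$bic > fit1$bic) {
      mix <- list(means = as.numeric(fit2$parameters$mean),
                  weights = as.numeric(fit2$parameters$pro),
                  sd = sqrt(fit2$parameters$variance$sigmasq))
    }
  }
  structure(list(rates = data.frame(direction = dirs, rate_um_s = rates),
                 mean = mean(rates),
                 sd = if (length(rates) > 1L) stats::sd(rates) else 0,
                 n_rejected = rejected, mixture = mix),
            class = "growth_rates")
}

#' @export
print.growth_rates <- function(x, ...) {
  cat(sprintf("Growth rates (%d directions): %.2f +/- %.2f um/s\n",
              nrow(x$rates), x$mean, x$sd))
  if (!is.null(x$mixture))
    cat(sprintf("  two-population split: %.2f / %.2f um/s (weights %.2f / %.2f)\n",
                x$mixture$means[1], x$mixture$means[2],
                x$mixture$weights[1], x$mixture$weights[2]))
  invisible(x)
}

#' Two-sample comparison of growth-rate distributions
#'
#' Descriptive Welch t-test between two sets of per-direction growth
#' rates (e.g. with and without polymer).
#'
#' @param gr1,gr2 [growth_rates()] objects.
#' @return the \code{htest} from [stats::t.test()].
#' @export
growth_rate_test <- function(gr1, gr2) {
  stopifnot(inherits(gr1, "growth_rates"), inherits(gr2, "growth_rates"))
  stats::t.test(gr1$rates$rate_um_s, gr2$rates$rate_um_s)
}

#' Storage-series trend summary
#'
#' Quantifies how cold-crystallization onset and the remaining glass
#' fraction evolve with storage time: the onset slope is an ordinary
#' least-squares rate (degC/day), and the time at which the glass
#' fraction first crosses one half is found by linear interpolation
#' (NA when never crossed).
#'
#' @param days storage times in days, nonnegative increasing.
#' @param t_onset cold-crystallization onset at each time, degC
#'   (NA allowed).
#' @param glass_fraction optional remaining glass fraction at each time.
#' @return list with \code{onset_slope} (degC/day), \code{onset_se},
#'   \code{t_half_days}.
#' @export
storage_trend <- function(days, t_onset, glass_fraction = NULL) {
  stopifnot(length(days) >= 2L, all(days >= 0), !is.unsorted(days))
  ok <- !is.na(t_onset)
  if (sum(ok) < 2L) stop("need >= 2 onset observations")
  fit <- stats::lm(t_onset[ok] ~ days[ok])
  slope <- unname(stats::coef(fit)[2])
  se <- if (sum(ok) > 2L)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  t_half <- NA_real_
  if (!is.null(glass_fraction)) {
    gf <- glass_fraction
    cross <- which(gf[-length(gf)] > 0.5 & gf[-1L] <= 0.5)
    if (length(cross)) {
      i <- cross[1L]
      t_half <- days[i] + (0.5 - gf[i]) / (gf[i + 1L] - gf[i]) *
        (days[i + 1L] - days[i])
    }
  }
  list(onset_slope = slope, onset_se = se, t_half_days = t_half)
}
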