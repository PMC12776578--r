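#' Celecoxib/PVPVA study presets
#'
#' Named parameter sets for celecoxib (CEL) glass and its mixtures with
#' 2 and 5 weight-percent vinylpyrrolidone-vinyl acetate copolymer
#' (PVPVA): glass-transition midpoints, VFT parameters of the alpha
#' process (with the conventional \eqn{\log_{10}\tau_\infty = -14}),
#' alpha-peak stretching exponents, Arrhenius activation energies of the
#' beta/gamma/delta secondary relaxations, calorimetric constants
#' (\eqn{C_{pg}} 1.62 and \eqn{C_{pl}} 2.07 J/(g K), density
#' 1.41 g/cm^3), the enthalpy-recovery KWW table (relaxation time in
#' minutes, stretching exponent and reported tau^beta per annealing
#' temperature), polymorph
#' melting centers (Form III 162 C, Form I 164 C) and mean crystal growth
#' rates at 120 C.  These drive the synthetic-data generators so that the
#' full pipeline can be exercised at realistic parameter points.
#'
#' @param sample \code{"pure"}, \code{"pvpva2"} or \code{"pvpva5"}.
#' @return a named list of parameters.
#' @examples
#' p <- cel_preset("pure")
#' vft_tg(p$vft)  # ~328 K
#' @export
cel_preset <- function(sample = c("pure", "pvpva2", "pvpva5")) {
  sample <- match.arg(sample)
  common <- list(cpg = 1.62, cpl = 2.07, rho = 1.41, delta_cp = 0.45,
                 melting_centers = c(form3 = 162, form1 = 164),
                 tc_s = 2e-12)
  spec <- switch(sample,
    pure = list(
      tg_mid = 55.2,
      vft = vft_fit(-14, 6.33, 280),
      beta_kww_alpha = 0.69,
      secondary_ea = c(beta = 79.1, gamma = 33.9, delta = 23.9),
      kww_table = data.frame(
        ta = c(30, 35, 40, 45),
        tau_min = c(27200, 4870, 647, 315),
        beta = c(0.50, 0.48, 0.57, 0.59),
        tau_beta = c(158, 58.9, 40.5, 29.8)),
      growth = list(mean = 3.08, sd = 1.65)),
    pvpva2 = list(
      tg_mid = 56.0,
      vft = vft_fit(-14, 6.30, 281),
      beta_kww_alpha = 0.61,
      secondary_ea = c(beta = 78.9, gamma = 46.5, delta = 27.8),
      kww_table = data.frame(
        ta = c(35, 40, 45),
        tau_min = c(2430, 981, 266),
        beta = c(0.67, 0.56, 0.49),
        tau_beta = c(186, 47.4, 15.4)),
      growth = list(mean = 4.61, sd = 2.36)),
    pvpva5 = list(
      tg_mid = 57.8,
      vft = vft_fit(-14, 6.83, 279),
      beta_kww_alpha = 0.58,
      secondary_ea = c(beta = 72.8, gamma = 49.4, delta = 26.8),
      kww_table = data.frame(
        ta = c(35, 40, 45),
        tau_min = c(1890, 1380, 347),
        beta = c(0.87, 0.58, 0.57),
        tau_beta = c(709, 66.3, 28.0)),
      growth = list(mean = NA_real_, sd = NA_real_)))
  c(list(sample = sample), spec, common)
}

#' Gamma-process generator settings for the pure-CEL glass
#'
#' Convenience wrapper bundling the Cole-Cole gamma-relaxation process of
#' pure celecoxib glass (activation energy 33.9 kJ/mol, prefactor 1e-16 s,
#' relaxation strength 0.3, broadening a = 0.3) with the standard sub-zero
#' measurement grid (-120 to -40 C every 4 C), for parameter-recovery
#' studies.
#'
#' @return list with \code{process} (for [gen_dielectric_series()]) and
#'   \code{T_K}.
#' @export
cel_gamma_process <- function() {
  list(process = list(
         mode = list(label = "gamma", delta_eps = 0.3, a = 0.3, b = 1),
         law = temperature_law("arrhenius", tau0_s = 1e-16,
                               ea_kj_mol = 33.9)),
       T_K = celsius_to_kelvin(seq(-120, -40, by = 4)))
}
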