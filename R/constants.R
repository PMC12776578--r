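# Physical constants (SI)
.kB   <- 1.380649e-23   # Boltzmann constant, J/K
.Rgas <- 8.314          # gas constant, J/(mol K)
.eps0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Temperature scale conversion
#'
#' @param x temperatures in degC (\code{celsius_to_kelvin}) or K
#'   (\code{kelvin_to_celsius}).
#' @return converted temperatures.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
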