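## Physical constants (CODATA) and the package-wide unit conventions.
## Lengths nm, times ps, D reported in 1e-5 cm^2/s, viscosity mPa.s,
## rates 1e-3 ns^-1.

#' Physical constants bundle
#'
#' Boltzmann constant, gas constant and a working temperature, grouped so
#' that rate and Stokes-Einstein computations share one source of truth.
#'
#' @param temperature Temperature in K (default 300; tert-butanol style
#'   runs may use 301).
#' @return A list with `k_B` (J/K), `R` (J/(mol K)) and `T` (K).
#' @export
#' @examples
#' phys_constants()$R
phys_constants <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number (K)")
  }
  list(k_B = 1.380649e-23, R = 8.314462618, T = temperature)
}

#' Unit conversions for diffusion coefficients
#'
#' Internally diffusion coefficients are carried in nm^2/ps; results are
#' reported in units of 1e-5 cm^2/s, the conventional scale for solvent
#' self-diffusion. 1 nm^2/ps = 1e-14 cm^2 / 1e-12 s = 1e3 x 1e-5 cm^2/s.
#'
#' @param D Diffusion coefficient(s).
#' @return Converted value(s).
#' @export
diffusion_nm2ps_to_report <- function(D) D * 1e3

#' @rdname diffusion_nm2ps_to_report
#' @export
diffusion_report_to_nm2ps <- function(D) D / 1e3

#' Percent deviation of a model value from a reference value
#'
#' @param model Model value.
#' @param reference Reference (e.g. experimental) value; must be nonzero.
#' @return 100 * |model - reference| / |reference|.
#' @export
#' @examples
#' percent_error(2.49, 2.3) # water model diffusion vs experiment -> 8.3%
percent_error <- function(model, reference) {
  if (any(reference == 0)) stop("reference value must be nonzero")
  100 * abs(model - reference) / abs(reference)
}
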