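# CODATA 2018 values, SI units.
.const <- list(
  h  = 6.62607015e-34,   # Planck, J s
  m0 = 9.1093837015e-31, # electron rest mass, kg
  e  = 1.602176634e-19,  # elementary charge, C
  c  = 299792458         # speed of light, m/s
)

#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage_kv`
#' kilovolts, including the relativistic correction:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}}
#'
#' @param voltage_kv Accelerating voltage in kV. Must be positive.
#' @return Wavelength in picometres (1.969 pm at 300 kV).
#' @examples
#' electron_wavelength(300)
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(!is.finite(voltage_kv)) || any(voltage_kv <= 0)) {
    stop("`voltage_kv` must be positive and finite", call. = FALSE)
  }
  v <- voltage_kv * 1e3
  with(.const, h / sqrt(2 * m0 * e * v * (1 + e * v / (2 * m0 * c^2)))) * 1e12
}

#' Relativistic beam-specimen interaction constant
#'
#' The phase accumulated per volt-angstrom of projected potential,
#' \eqn{\sigma = 2\pi \gamma m_0 e \lambda / h^2}, used by the multislice
#' phase gratings.
#'
#' @param voltage_kv Accelerating voltage in kV.
#' @return Interaction constant in rad/(V \eqn{\cdot} \ifelse{html}{\out{&#8491;}}{Angstrom})
#'   (6.526e-4 at 300 kV).
#' @export
interaction_sigma <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  lambda_m <- electron_wavelength(voltage_kv) * 1e-12
  gamma <- 1 + with(.const, e * v / (m0 * c^2))
  with(.const, 2 * pi * gamma * m0 * e * lambda_m / h^2) * 1e-10
}

# electrons per second carried by a current in pA
.electrons_per_second <- function(current_pa) current_pa * 1e-12 / .const$e
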