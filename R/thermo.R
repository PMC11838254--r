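#' Thermodynamic context: temperature and energy-unit conventions
#'
#' Cooperativity energies in this package are expressed in kcal/mol and are
#' converted to dimensionless Boltzmann factors through
#' \eqn{\alpha = \exp(-C / (k_B T))}.  A `thermo_context` fixes the
#' temperature and the value of the Boltzmann (gas) constant used for that
#' conversion.  "Room temperature" is taken as 298.15 K; any temperature in
#' the 293--310 K range gives \eqn{-k_B T \ln 10 \approx -1.4} kcal/mol for a
#' factor of 10.
#'
#' @param temperature Absolute temperature in kelvin. Default 298.15.
#' @return An object of class `thermo_context` with fields `temperature`
#'   (K) and `boltzmann_constant` (kcal mol^-1 K^-1, fixed at
#'   1.987204259e-3).
#' @examples
#' th <- thermo_context()
#' factor_from_energy(-1.364, th) # about 10
#' @export
thermo_context <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite number (kelvin)")
  }
  structure(
    list(temperature = temperature,
         boltzmann_constant = 1.987204259e-3),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, kB = %g kcal/(mol K), kB*T = %g kcal/mol\n",
              x$temperature, x$boltzmann_constant,
              x$boltzmann_constant * x$temperature))
  invisible(x)
}

#' Convert a cooperativity energy to a Boltzmann factor (and back)
#'
#' A nearest-neighbor cooperativity energy \eqn{C} (kcal/mol; negative =
#' favorable stacking) corresponds to the multiplicative statistical weight
#' \eqn{\alpha = \exp(-C / (k_B T))} applied once per adjacent pair of bound
#' ligands.  `energy_from_factor()` is the exact inverse,
#' \eqn{C = -k_B T \ln\alpha}.
#'
#' @param c_energy Cooperativity energy in kcal/mol. Must be finite.
#' @param thermo A [thermo_context()].
#' @return Dimensionless Boltzmann factor (strictly positive).
#' @examples
#' factor_from_energy(0)                     # 1
#' energy_from_factor(10)                    # about -1.4 kcal/mol at 298.15 K
#' @export
factor_from_energy <- function(c_energy, thermo = thermo_context()) {
  stopifnot(inherits(thermo, "thermo_context"))
  if (!is.numeric(c_energy) || any(!is.finite(c_energy))) {
    stop("`c_energy` must be finite (kcal/mol)")
  }
  exp(-c_energy / (thermo$boltzmann_constant * thermo$temperature))
}

#' @param alpha Dimensionless Boltzmann factor, strictly positive.
#' @rdname factor_from_energy
#' @export
energy_from_factor <- function(alpha, thermo = thermo_context()) {
  stopifnot(inherits(thermo, "thermo_context"))
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be finite and > 0")
  }
  -thermo$boltzmann_constant * thermo$temperature * log(alpha)
}
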