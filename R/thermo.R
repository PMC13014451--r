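# Internal unit conventions: energies kcal/mol, lengths Angstrom, times ps.
# Conversion to cm-based units happens only when results are reported.

#' Boltzmann constant in kcal mol-1 K-1
#' @keywords internal
.kB <- 0.0019872041

#' Coulomb constant in kcal Angstrom mol-1 e-2
#' @keywords internal
.k_coulomb <- 332.0637

#' Thermodynamic state
#'
#' Bundles the absolute temperature with the inverse thermal energy
#' beta = 1/(kB T) used throughout the free-energy and kinetics machinery.
#'
#' @param temperature absolute temperature in kelvin (default 310 K,
#'   physiological).
#' @return an object of class `thermo_state` with fields `temperature`,
#'   `kB` (kcal mol-1 K-1), `kT` (kcal mol-1) and `beta` (mol kcal-1).
#' @examples
#' th <- thermo_state(310)
#' th$kT  # ~0.616 kcal/mol
#' @export
thermo_state <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive finite number (kelvin)")
  }
  kT <- .kB * temperature
  structure(
    list(temperature = temperature, kB = .kB, kT = kT, beta = 1 / kT),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Thermodynamic state: T = %g K, kT = %.5f kcal/mol, beta = %.5f mol/kcal\n",
              x$temperature, x$kT, x$beta))
  invisible(x)
}

.as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_state")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1L) return(thermo_state(thermo))
  stop("thermo must be a thermo_state or a temperature in kelvin")
}

#' Convert a diffusion coefficient between internal and reporting units
#'
#' Internally diffusivities are carried in Angstrom^2/ps; reports use
#' cm^2/s. The factor is exactly 1e-4 (1 A^2/ps = 1e-4 cm^2/s).
#'
#' @param value numeric vector of diffusivities.
#' @param from,to unit strings, one of `"A2/ps"`, `"cm2/s"`.
#' @return converted numeric vector.
#' @export
convert_diffusivity <- function(value, from, to) {
  units <- c("A2/ps" = 1e-4, "cm2/s" = 1)  # factor to cm2/s
  if (!from %in% names(units)) stop("unknown diffusivity unit: ", from)
  if (!to %in% names(units)) stop("unknown diffusivity unit: ", to)
  value * units[[from]] / units[[to]]
}
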