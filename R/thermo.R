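#' Thermodynamic context
#'
#' Bundles the temperature, Boltzmann constant and standard-state volume used
#' throughout the package. The standard-state volume V° = 1660 Å³ is the
#' volume per molecule of an ideal solution at 1 M and sets the reference
#' concentration for all release free energies.
#'
#' @param temperature Temperature in kelvin. Default 298 K.
#' @param boltzmann_constant Boltzmann constant in kcal mol⁻¹ K⁻¹.
#' @param standard_volume Standard-state volume V° in Å³. Default 1660.
#'
#' @return An object of class `thermo_context`: a list with fields
#'   `temperature`, `boltzmann_constant`, `standard_volume`, `kT`
#'   (kcal mol⁻¹) and `beta` (mol kcal⁻¹, exactly `1/kT`).
#' @examples
#' ctx <- thermo_context()
#' ctx$kT # ~0.593 kcal/mol at 298 K
#' @export
thermo_context <- function(temperature = 298,
                           boltzmann_constant = 1.9872041e-3,
                           standard_volume = 1660) {
  stopifnot(
    is.numeric(temperature), length(temperature) == 1, temperature > 0,
    is.numeric(boltzmann_constant), boltzmann_constant > 0,
    is.numeric(standard_volume), standard_volume > 0
  )
  kT <- boltzmann_constant * temperature
  structure(
    list(
      temperature = temperature,
      boltzmann_constant = boltzmann_constant,
      standard_volume = standard_volume,
      kT = kT,
      beta = 1 / kT
    ),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf(
    "<thermo_context> T = %g K, kB = %g kcal/mol/K, V° = %g Å³ (kT = %.5f kcal/mol)\n",
    x$temperature, x$boltzmann_constant, x$standard_volume, x$kT
  ))
  invisible(x)
}

as_thermo_context <- function(x) {
  if (inherits(x, "thermo_context")) return(x)
  if (is.null(x)) return(thermo_context())
  stop("`context` must be a thermo_context() object", call. = FALSE)
}
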