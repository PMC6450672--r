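# CODATA 2018 exact/recommended values (SI)
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  NAv  = 6.02214076e23,     # Avogadro constant, 1/mol
  R    = 8.314462618        # molar gas constant, J/(mol K)
)

#' Physical constants used by the package
#'
#' Returns the CODATA constants the thermodynamic maps are built on
#' (elementary charge, vacuum permittivity, Boltzmann, Avogadro and molar gas
#' constants, all SI).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' physical_constants()$kB
physical_constants <- function() .const
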