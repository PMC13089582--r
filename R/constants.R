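# Physical constants and unit conversions used by the thermodynamic
# estimators. Energies are kcal/mol internally; lengths Angstrom; pressures
# MPa on input, Pa internally.

.KB_KCAL <- 1.987204259e-3   # Boltzmann constant, kcal mol^-1 K^-1
.KB_J <- 1.380649e-23        # J K^-1 (per molecule)
.HBAR <- 1.054571817e-34     # J s
.AVOGADRO <- 6.02214076e23
.AMU <- 1.66053906660e-27    # kg
.KCALMOL_J <- 4184 / .AVOGADRO        # J per (kcal/mol)
.PA_A3_KCALMOL <- 1e-30 * .AVOGADRO / 4184  # Pa*A^3 -> kcal/mol

#' Thermodynamic constants for pressure analyses
#'
#' Bundles the constants the trajectory estimators need: temperature, water
#' dielectric constants at the two pressure conditions, the water surface
#' tension used by the nonpolar solvation estimate, and the analysis-window
#' and block-averaging defaults.
#'
#' @param temperature Kelvin (default 300).
#' @param dielectric Named numeric: water dielectric constant per condition,
#'   default `c("0.1MPa" = 77.75, "30MPa" = 78.83)`.
#' @param surface_tension Water surface tension, kcal mol^-1 A^-2
#'   (default 0.1032, i.e. 71.73 mN/m at 300 K).
#' @param window_fraction Fraction of each trajectory tail analysed
#'   (default 0.5: the final half, after equilibration).
#' @param n_blocks Non-overlapping blocks for uncertainty estimates
#'   (default 5).
#' @return Object of class `thermo_constants`.
#' @export
thermo_constants <- function(temperature = 300,
                             dielectric = c("0.1MPa" = 77.75,
                                            "30MPa" = 78.83),
                             surface_tension = 0.1032,
                             window_fraction = 0.5,
                             n_blocks = 5) {
  stopifnot(temperature > 0, all(dielectric > 0), surface_tension > 0,
            window_fraction > 0, window_fraction <= 1, n_blocks >= 1)
  structure(list(temperature = temperature, dielectric = dielectric,
                 surface_tension = surface_tension,
                 window_fraction = window_fraction,
                 n_blocks = as.integer(n_blocks),
                 kB = .KB_KCAL),
            class = "thermo_constants")
}
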