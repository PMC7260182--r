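# Physical constants (CODATA 2018, exact SI where defined)
.h      <- 6.62607015e-34     # J s
.c_cm   <- 2.99792458e10      # cm/s, pairs with wavenumbers in cm^-1
.kB     <- 1.380649e-23       # J/K
.NA     <- 6.02214076e23      # 1/mol
.Rgas   <- 8.31446261815324   # J/(mol K)
.hartree_J <- 4.3597447222071e-18

#' Energy unit conversions
#'
#' Energies are carried in kJ/mol throughout the package; hartree and
#' kcal/mol appear only at the boundaries (quantum-chemistry files, map
#' contouring). These helpers convert between the three.
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit.
#' @examples
#' hartree_to_kjmol(1)            # 2625.4996...
#' kjmol_to_hartree(hartree_to_kjmol(2.5))
#' @export
hartree_to_kjmol <- function(x) x * (.hartree_J * .NA / 1000)

#' @rdname hartree_to_kjmol
#' @export
kjmol_to_hartree <- function(x) x / (.hartree_J * .NA / 1000)

#' @rdname hartree_to_kjmol
#' @export
kjmol_to_kcalmol <- function(x) x / 4.184

#' @rdname hartree_to_kjmol
#' @export
kcalmol_to_kjmol <- function(x) x * 4.184

# Gas constant in kJ/(mol K), used by Boltzmann weighting and thermochemistry
.R_kj <- .Rgas / 1000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# standard atomic weights (u) for the elements this package meets
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904)

# covalent radii (Å, Cordero 2008) for bond perception and embedding bounds
.cov_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66,
                 F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20)

# van der Waals radii (Å, Bondi) for nonbonded terms and distance bounds
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                 F = 1.47, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85)

# Pauling electronegativities, drive the bond-increment partial charges
.electroneg <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44,
                 F = 3.98, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96)
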