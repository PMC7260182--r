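# shared fixtures, all built in code

# tetrahydropyranyl oxocarbenium: the smallest pyranosyl-cation model
thp_cation_smiles <- "C1=[O+]CCCC1"

# the same ring carrying an acetyl ester (probes rotamer detection / R1-R2)
acetoxy_thp_smiles <- "C1=[O+]CC(CC1)OC(C)=O"

# cached parsed structures (SMILES -> 3D goes through Open Babel once)
local_thp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- smiles_to_mol3d(thp_cation_smiles, "thp")
    cache
  }
})

# a regular hexagon with prescribed out-of-plane displacements, matching the
# package's clockwise ring-traversal convention
hexagon_with_z <- function(z, r = 1.466) {
  j <- 0:5
  cbind(r * cos(2 * pi * j / 6), -r * sin(2 * pi * j / 6), z)
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal Gaussian-style log text for the parser tests
gaussian_log_fixture <- function(energy_hartree = -497.123456789,
                                 frequencies = c(-45.1234, 1200.5678, 1650.0),
                                 intensities = c(10, 50, 100),
                                 with_freq_block = TRUE) {
  lines <- c(
    " Entering Gaussian System",
    " #P B3LYP/6-311G(d,p) Opt Freq",
    sprintf(" SCF Done:  E(RB3LYP) =  %.9f     A.U. after   12 cycles",
            energy_hartree),
    "                         Standard orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    "      1          8           0        0.000000    0.000000    0.100000",
    "      2          6           0        1.200000    0.000000    0.000000",
    " ---------------------------------------------------------------------")
  if (with_freq_block) {
    lines <- c(lines,
               paste(" Frequencies --",
                     paste(sprintf("%12.4f", frequencies), collapse = " ")),
               paste(" IR Inten    --",
                     paste(sprintf("%12.4f", intensities), collapse = " ")))
  }
  paste(lines, collapse = "\n")
}

# synthetic broadened trace with bands at given positions
synthetic_band_trace <- function(positions, heights = rep(1, length(positions)),
                                 width = 20) {
  broaden(spectrum_ir(positions, heights, kind = "lines"), width = width)
}
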