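# Rigid-rotor / harmonic-oscillator thermochemistry with the
# frequency-raising quasi-harmonic variant for low modes.

#' Harmonic and quasi-harmonic thermochemistry from frequencies
#'
#' Computes the zero-point energy, thermal enthalpy correction, entropy, and
#' the resulting Gibbs free energy at temperature `T` from a set of real
#' harmonic frequencies, under the ideal-gas rigid-rotor--harmonic-oscillator
#' model. Under the quasi-harmonic scheme, frequencies below `qh_cutoff` are
#' raised to the cutoff before the entropy evaluation (only there), which
#' tames the harmonic-oscillator entropy divergence of soft torsional modes;
#' quasi-harmonic and harmonic results agree exactly when all frequencies
#' are at or above the cutoff.
#'
#' Rotational and translational contributions use the standard ideal-gas
#' formulas (1 bar standard state, symmetry number 1, appropriate for the
#' asymmetric cations this toolkit studies) and are included when a
#' structure is supplied; with frequencies alone, only the vibrational parts
#' are returned, which is what relative energies of conformers of one
#' molecule need.
#'
#' @param frequencies harmonic frequencies in cm^-1; all must be > 0
#'   (imaginary modes must be removed or the record discarded upstream).
#' @param T temperature in Kelvin. The conformational maps default to
#'   213.15 K (the -60 C glycosylation conditions) elsewhere in the package;
#'   IR free energies default to 298 K.
#' @param scheme `"harmonic"` or `"quasi-harmonic"`.
#' @param qh_cutoff quasi-harmonic raising cutoff in cm^-1 (default 100).
#' @param electronic electronic energy in kJ/mol to which the corrections
#'   are added for the `gibbs` field (default 0: `gibbs` is then the
#'   correction itself).
#' @param structure optional [mol3d]; enables rotational + translational
#'   contributions.
#' @return list of class `thermo_result`: `zpe`, `thermal` (enthalpy
#'   correction beyond ZPE, including RT and any rot/trans parts), `entropy`
#'   (J/(mol K)), `gibbs` (kJ/mol), `temperature`, `scheme`.
#' @examples
#' thermo_corrections(1000, T = 298)$zpe   # ~5.98 kJ/mol
#' @export
thermo_corrections <- function(frequencies, T = 298,
                               scheme = c("quasi-harmonic", "harmonic"),
                               qh_cutoff = 100, electronic = 0,
                               structure = NULL) {
  scheme <- match.arg(scheme)
  if (T <= 0) stop("temperature must be > 0")
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0))
    stop("negative or zero frequency supplied: remove imaginary modes ",
         "(see the record's has_imaginary flag) before thermochemistry")
  zpe <- sum(0.5 * .h * .c_cm * frequencies) * .NA / 1000
  x <- .h * .c_cm * frequencies / (.kB * T)
  e_vib <- sum(.h * .c_cm * frequencies / (expm1(x))) * .NA / 1000
  nu_s <- if (scheme == "quasi-harmonic") pmax(frequencies, qh_cutoff) else frequencies
  xs <- .h * .c_cm * nu_s / (.kB * T)
  s_vib <- .Rgas * sum(xs / expm1(xs) - log1p(-exp(-xs)))
  thermal <- e_vib
  entropy <- s_vib
  if (!is.null(structure)) {
    m_kg <- sum(.atomic_mass[structure$elements]) / .NA / 1000
    q_trans <- (2 * pi * m_kg * .kB * T / .h^2)^1.5 * (.kB * T / 1e5)
    s_trans <- .Rgas * (log(q_trans) + 2.5)
    X <- sweep(structure$coords, 2, colMeans(structure$coords)) * 1e-10
    m <- .atomic_mass[structure$elements] / .NA / 1000
    I <- matrix(0, 3, 3)
    for (i in seq_along(m)) {
      r <- X[i, ]
      I <- I + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    Imom <- pmax(eigen(I, symmetric = TRUE, only.values = TRUE)$values, 1e-55)
    q_rot <- sqrt(pi * prod(8 * pi^2 * Imom * .kB * T / .h^2))
    s_rot <- .Rgas * (log(q_rot) + 1.5)
    thermal <- thermal + 1.5 * .Rgas * T / 1000 + 1.5 * .Rgas * T / 1000 +
      .Rgas * T / 1000                       # trans + rot + pV
    entropy <- entropy + s_trans + s_rot
  }
  gibbs <- electronic + zpe + thermal - T * entropy / 1000
  structure(list(zpe = zpe, thermal = thermal, entropy = entropy,
                 gibbs = gibbs, temperature = T, scheme = scheme,
                 qh_cutoff = qh_cutoff),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(paste0("thermo (%s, %g K): ZPE %.3f kJ/mol, thermal %.3f kJ/mol, ",
                     "S %.3f J/(mol K), G %.3f kJ/mol\n"),
              x$scheme, x$temperature, x$zpe, x$thermal, x$entropy, x$gibbs))
  invisible(x)
}

#' Boltzmann weights of an ensemble
#'
#' Weights proportional to exp(-(G - min G) / RT), normalized to sum to one.
#' Invariant to adding any constant to all energies.
#'
#' @param gibbs numeric vector of free energies in kJ/mol.
#' @param T temperature in Kelvin.
#' @return numeric vector of weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 0), 298)                        # 0.5, 0.5
#' boltzmann_weights(c(0, 8.31446e-3 * 298 * log(2)), 298)  # 2/3, 1/3
#' @export
boltzmann_weights <- function(gibbs, T = 298) {
  if (!length(gibbs)) stop("at least one energy required")
  if (T <= 0) stop("temperature must be > 0")
  w <- exp(-(gibbs - min(gibbs)) / (.R_kj * T))
  w / sum(w)
}
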