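# Energy backend contract
#
# A backend is an S3 object (class "energy_backend") bundling closures:
#   energy(mol)                 -> kJ/mol
#   optimize(mol, restraints)   -> mol3d with attr "energy" (kJ/mol), only
#                                  when "optimize" is declared
#   frequencies(mol)            -> list(frequencies, intensities, n_imaginary),
#                                  only when declared
# plus metadata: name, capabilities, level, solvent. Energies cross the
# boundary in kJ/mol; hartree appears only in quantum-chemistry files.

new_energy_backend <- function(name, capabilities, level = NA_character_,
                               solvent = NA_character_, energy = NULL,
                               optimize = NULL, frequencies = NULL) {
  caps <- match.arg(capabilities,
                    c("energy", "optimize", "frequencies", "intensities"),
                    several.ok = TRUE)
  structure(list(name = name, capabilities = caps, level = level,
                 solvent = solvent, energy = energy, optimize = optimize,
                 frequencies = frequencies),
            class = "energy_backend")
}

#' @export
print.energy_backend <- function(x, ...) {
  cat(sprintf("energy backend '%s' [%s] level: %s%s\n", x$name,
              paste(x$capabilities, collapse = ", "), x$level,
              if (!is.na(x$solvent)) paste0(", solvent: ", x$solvent) else ""))
  invisible(x)
}

#' Analytic toy energy backend
#'
#' A smooth surrogate potential over the Cremer-Pople sphere: inverted
#' Gaussian wells planted at chosen (theta, phi) positions, plus an optional
#' cosine preference for a rotamer torsion. Because the landscape is known
#' in closed form, toolkit runs against this backend have exact expected
#' outcomes (well positions, relative depths), which is how the mapping
#' pipeline is validated end to end without any quantum chemistry.
#'
#' @param wells data.frame with columns `theta`, `phi` (degrees), `depth`
#'   (kJ/mol, > 0 lowers the energy), `width` (great-circle degrees).
#' @param base constant offset, kJ/mol.
#' @param rotamer_torsion optional list(`atoms` = 4 indices, `target` =
#'   degrees, `amplitude` = kJ/mol) adding
#'   `amplitude/2 * (1 - cos(phi - target))`.
#' @param ring optional six ordered ring-atom indices passed to
#'   [cp_coordinates]; the `"ring"` attribute of the structure is used when
#'   present.
#' @return an `energy_backend` with the `energy` capability.
#' @examples
#' tb <- toy_backend(data.frame(theta = 0, phi = 0, depth = 20, width = 30))
#' tb$energy(ideal_ring_geometry("4C1", 0.55))   # deep: in the well
#' tb$energy(ideal_ring_geometry("1C4", 0.55))   # ~0: far from it
#' @export
toy_backend <- function(wells, base = 0, rotamer_torsion = NULL, ring = NULL) {
  stopifnot(all(c("theta", "phi", "depth", "width") %in% names(wells)))
  energy <- function(mol) {
    idx <- attr(mol, "ring")
    if (is.null(idx)) idx <- ring
    cp <- cp_coordinates(mol, ring_idx = idx)
    e <- base
    if (!cp$planar) {
      d <- gc_distance(cp$theta, cp$phi, wells$theta, wells$phi)
      e <- e - sum(wells$depth * exp(-(d / wells$width)^2 / 2))
    }
    if (!is.null(rotamer_torsion)) {
      a <- rotamer_torsion$atoms
      phi <- dihedral_angle(mol$coords, a[1], a[2], a[3], a[4])
      e <- e + rotamer_torsion$amplitude / 2 *
        (1 - cos(deg2rad(phi - rotamer_torsion$target)))
    }
    e
  }
  new_energy_backend("toy", c("energy"), level = "analytic surrogate",
                     energy = energy)
}

#' Classical valence-forcefield backend
#'
#' Wraps the package's generic valence forcefield (harmonic bonds/angles,
#' cosine torsions, 12-6 nonbonded) as an energy backend with energy,
#' restrained optimization, and harmonic frequency/intensity capabilities.
#' This is the desk-scale stand-in for both the screening level and the
#' production level of the staged workflows.
#'
#' @param maxit optimizer iteration cap.
#' @return an `energy_backend` with all four capabilities.
#' @export
forcefield_backend <- function(maxit = 400) {
  new_energy_backend(
    "valence-ff",
    c("energy", "optimize", "frequencies", "intensities"),
    level = "generic valence forcefield",
    energy = function(mol) ff_energy_gradient(mol$coords, ff_params(mol))$E,
    optimize = function(mol, restraints = NULL)
      ff_minimize(mol, restraints = restraints, maxit = maxit),
    frequencies = function(mol) ff_frequencies(mol))
}

## ---- external quantum-chemistry dialect ------------------------------------

.element_z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                Cl = 17, Br = 35)

#' Write an input deck for an external quantum-chemistry program
#'
#' Emits a Gaussian-style input deck: route line, title, charge and spin
#' multiplicity, Cartesian coordinates, and (for constrained optimizations)
#' a ModRedundant block fixing the prefixed dihedrals. Continuum-solvent
#' keywords are added when a solvent is requested. Output is byte-stable for
#' identical arguments.
#'
#' @param mol a [mol3d] object; its `charge` is written to the deck.
#' @param job one of `"opt"`, `"freq"`, `"opt+freq"`, `"sp"`.
#' @param level model chemistry string, e.g. `"B3LYP/6-311G(d,p)"`.
#' @param solvent solvent name for the polarizable continuum model, e.g.
#'   `"dichloromethane"`, or `NULL` for gas phase.
#' @param constraints optional data.frame(`i`, `j`, `k`, `l`, `target_deg`)
#'   of dihedrals to hold fixed; only valid for optimization jobs.
#' @param multiplicity spin multiplicity, default 1.
#' @return the deck as a single string.
#' @export
write_qc_input <- function(mol, job = c("opt", "freq", "opt+freq", "sp"),
                           level = "B3LYP/6-311G(d,p)", solvent = NULL,
                           constraints = NULL, multiplicity = 1L) {
  job <- match.arg(job)
  if (!is.null(constraints) && !grepl("opt", job))
    stop("configuration error: dihedral constraints require an optimization job")
  kw <- character()
  if (grepl("opt", job))
    kw <- c(kw, if (!is.null(constraints)) "Opt=ModRedundant" else "Opt")
  if (grepl("freq", job)) kw <- c(kw, "Freq")
  if (!is.null(solvent))
    kw <- c(kw, sprintf("SCRF=(PCM,Solvent=%s)", solvent))
  lines <- c(
    sprintf("#P %s %s", level, paste(kw, collapse = " ")),
    "",
    mol$name,
    "",
    sprintf("%d %d", mol$charge, as.integer(multiplicity)),
    sprintf("%-2s %14.8f %14.8f %14.8f", mol$elements,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
  if (!is.null(constraints)) {
    lines <- c(lines, "",
               sprintf("D %d %d %d %d =%.4f F",
                       constraints$i, constraints$j, constraints$k,
                       constraints$l, constraints$target_deg))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse external quantum-chemistry output
#'
#' Reads either a Gaussian-style log (final `SCF Done` energy, last
#' `Standard orientation` geometry, `Frequencies --` / `IR Inten` blocks) or
#' a record of the neutral interchange format (see [write_interchange]).
#' Frequencies below zero are counted as imaginary modes and flag the
#' record.
#'
#' @param text log-file text (single string or character vector of lines).
#' @param expect_frequencies require a frequency block; defaults to TRUE
#'   when the route section requests `Freq`.
#' @return list of class `qc_result`: `energy_kjmol`, `energy_hartree`,
#'   `elements`, `coords`, `frequencies` (cm^-1), `intensities`,
#'   `n_imaginary`, `has_imaginary`.
#' @export
parse_qc_output <- function(text, expect_frequencies = NULL) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  scf <- grep("SCF Done:", lines, value = TRUE)
  if (!length(scf))
    stop("parse error: missing 'SCF Done' energy section")
  e_h <- as.numeric(sub(".*=\\s*(-?[0-9.]+([DEde][+-][0-9]+)?).*", "\\1",
                        scf[length(scf)]))
  geo_at <- grep("Standard orientation:|Input orientation:", lines)
  if (!length(geo_at)) stop("parse error: missing geometry section")
  g0 <- geo_at[length(geo_at)] + 5
  rows <- list()
  for (i in g0:length(lines)) {
    if (grepl("^\\s*---", lines[i])) break
    rows[[length(rows) + 1]] <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
  }
  if (!length(rows)) stop("parse error: empty geometry block")
  gm <- do.call(rbind, rows)
  zsym <- names(.element_z)[match(gm[, 2], .element_z)]
  coords <- gm[, (ncol(gm) - 2):ncol(gm), drop = FALSE]
  route <- grep("^\\s*#", lines, value = TRUE)
  if (is.null(expect_frequencies))
    expect_frequencies <- any(grepl("freq", route, ignore.case = TRUE))
  fl <- grep("Frequencies --", lines)
  if (!length(fl) && expect_frequencies)
    stop("parse error: missing frequency section for a Freq job")
  grab <- function(idx, tag) unlist(lapply(idx, function(i)
    as.numeric(strsplit(trimws(sub(paste0(".*", tag, "\\s*--"), "", lines[i])),
                        "\\s+")[[1]])))
  freqs <- if (length(fl)) grab(fl, "Frequencies") else NULL
  il <- grep("IR Inten", lines)
  inten <- if (length(il)) grab(il, "IR Inten") else NULL
  if (!is.null(freqs) && !is.null(inten) && length(freqs) != length(inten))
    stop("parse error: frequency and intensity blocks disagree in length")
  n_imag <- if (is.null(freqs)) 0L else sum(freqs < 0)
  structure(list(energy_kjmol = hartree_to_kjmol(e_h), energy_hartree = e_h,
                 elements = zsym, coords = coords, frequencies = freqs,
                 intensities = inten, n_imaginary = n_imag,
                 has_imaginary = n_imag > 0L),
            class = "qc_result")
}

## ---- neutral interchange format --------------------------------------------

#' Neutral structured interchange for conformer ensembles
#'
#' The canonical backend boundary: one JSON object per line per conformer
#' (energy in kJ/mol, element symbols, coordinates, frequencies in cm^-1,
#' intensities). Any external program's results can be converted to this
#' format once and consumed by every downstream stage, so no test or
#' analysis run ever needs the external program itself.
#'
#' @param records list of [conformer_record] objects.
#' @param path file path.
#' @return `write_interchange` returns `path` invisibly; `read_interchange`
#'   returns a list of [conformer_record] objects.
#' @export
write_interchange <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      name = r$structure$name, status = r$status, rotamer = r$rotamer,
      charge = r$structure$charge,
      energy_kjmol = r$energy, gibbs_kjmol = r$gibbs,
      elements = r$structure$elements,
      coords = unname(r$structure$coords),
      frequencies = r$frequencies, intensities = r$intensities),
      auto_unbox = TRUE, digits = NA, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_interchange
#' @export
read_interchange <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    mol <- mol3d(x$elements, matrix(x$coords, ncol = 3),
                 charge = if (is.null(x$charge)) 0L else x$charge,
                 name = if (is.null(x$name)) "mol" else x$name)
    mol$bonds <- perceive_bonds(mol)
    conformer_record(mol,
                     energy = if (is.null(x$energy_kjmol)) NA_real_ else x$energy_kjmol,
                     gibbs = if (is.null(x$gibbs_kjmol)) NA_real_ else x$gibbs_kjmol,
                     frequencies = x$frequencies, intensities = x$intensities,
                     rotamer = if (is.null(x$rotamer)) NA_character_ else x$rotamer,
                     status = if (is.null(x$status)) "ok" else x$status)
  })
}
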