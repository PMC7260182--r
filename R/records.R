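#' Conformer record
#'
#' One 3D conformer with its provenance and computed properties: backend
#' electronic energy, Gibbs free energy, harmonic frequencies and IR
#' intensities, the imaginary-mode count, and a status flag. Ensemble
#' operations (CEL maps, diversity selection, Boltzmann averaging) consume
#' lists of these.
#'
#' @param structure a [mol3d] object.
#' @param energy backend electronic (or forcefield) energy, kJ/mol.
#' @param gibbs Gibbs free energy, kJ/mol, when thermochemistry has run.
#' @param frequencies harmonic frequencies, cm^-1 (negative = imaginary).
#' @param intensities IR intensities, arbitrary units, same length as
#'   `frequencies`.
#' @param rotamer acyl rotamer label, `"R1"` or `"R2"`, when applicable.
#' @param status `"ok"` or `"failed"`.
#' @param source free-form provenance (grid point, seed index, ...).
#' @return an object of class `conformer_record`.
#' @export
conformer_record <- function(structure, energy = NA_real_, gibbs = NA_real_,
                             frequencies = NULL, intensities = NULL,
                             rotamer = NA_character_, status = "ok",
                             source = list()) {
  if (!is.null(frequencies) && !is.null(intensities) &&
      length(frequencies) != length(intensities))
    stop("frequencies and intensities must have equal length")
  n_imag <- if (is.null(frequencies)) 0L else sum(frequencies < 0)
  structure(list(structure = structure, energy = energy, gibbs = gibbs,
                 frequencies = frequencies, intensities = intensities,
                 n_imaginary = n_imag, has_imaginary = n_imag > 0L,
                 rotamer = rotamer, status = status, source = source),
            class = "conformer_record")
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("conformer [%s]%s E = %.3f kJ/mol%s%s\n",
              x$status,
              if (!is.na(x$rotamer)) paste0(" ", x$rotamer) else "",
              x$energy,
              if (!is.na(x$gibbs)) sprintf(", G = %.3f kJ/mol", x$gibbs) else "",
              if (x$has_imaginary) sprintf(" (%d imaginary)", x$n_imaginary) else ""))
  invisible(x)
}

# pull an ensemble manifest out of a record list
#' Summarize a list of conformer records as a data.frame
#'
#' @param records list of [conformer_record] objects.
#' @return data.frame with one row per record: index, status, rotamer,
#'   energy, Gibbs energy, imaginary-mode count.
#' @export
records_manifest <- function(records) {
  data.frame(
    index = seq_along(records),
    status = vapply(records, function(r) r$status, ""),
    rotamer = vapply(records, function(r) r$rotamer, ""),
    energy_kjmol = vapply(records, function(r) r$energy, 0),
    gibbs_kjmol = vapply(records, function(r) r$gibbs, 0),
    n_imaginary = vapply(records, function(r) r$n_imaginary, 0L))
}
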