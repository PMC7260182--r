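# Staged IR-spectrum simulation pipeline:
#   SMILES -> distance-geometry conformer search (500 embeddings, forcefield
#   minimized) -> max-min RMSD diversity selection (<= 40) -> relative-energy
#   filter (40 kJ/mol; 80 for pyranosyl cations) -> harmonic frequencies and
#   intensities -> 0.975 frequency scaling -> 20 cm^-1 FWHM Gaussian
#   broadening -> Boltzmann ensemble at 298 K -> diagnostic-band assignment.

#' IR pipeline configuration
#'
#' Defaults are the staged-workflow parameters this pipeline emulates: 500
#' random 3D conformations, at most 40 kept after diversity selection, a
#' 40 kJ/mol relative-energy window (80 kJ/mol for pyranosyl cations, whose
#' ring-opened rearrangements span a wider range), harmonic frequencies
#' scaled by 0.975, 20 cm^-1 FWHM Gaussian broadening, free energies at
#' 298 K.
#'
#' @param n_conformers conformers generated by the stochastic search.
#' @param max_selected cap after diversity selection.
#' @param energy_cutoff relative-energy window, kJ/mol.
#' @param pyranosyl_cutoff window used when `pyranosyl = TRUE`, kJ/mol.
#' @param scale_factor harmonic frequency scaling factor.
#' @param broaden_width Gaussian broadening width, cm^-1.
#' @param width_is_fwhm interpret `broaden_width` as FWHM (default) or sigma.
#' @param temperature Kelvin, for Boltzmann weighting and Gibbs energies.
#' @param seed integer seed making the whole pipeline reproducible.
#' @param grid trace wavenumber grid (default 1 cm^-1 over 700-1850).
#' @return list of class `ir_config`.
#' @export
ir_config <- function(n_conformers = 500, max_selected = 40,
                      energy_cutoff = 40, pyranosyl_cutoff = 80,
                      scale_factor = 0.975, broaden_width = 20,
                      width_is_fwhm = TRUE, temperature = 298, seed = 1,
                      grid = seq(700, 1850, by = 1)) {
  stopifnot(n_conformers > 0, max_selected > 0, energy_cutoff > 0,
            pyranosyl_cutoff > 0, broaden_width > 0, temperature > 0,
            scale_factor > 0, scale_factor <= 1.2)
  structure(list(n_conformers = as.integer(n_conformers),
                 max_selected = as.integer(max_selected),
                 energy_cutoff = energy_cutoff,
                 pyranosyl_cutoff = pyranosyl_cutoff,
                 scale_factor = scale_factor, broaden_width = broaden_width,
                 width_is_fwhm = width_is_fwhm, temperature = temperature,
                 seed = as.integer(seed), grid = grid),
            class = "ir_config")
}

#' @rdname ir_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
ir_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ir_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(ir_config, vals)
}

## ---- distance-geometry embedding -------------------------------------------

# distance-bounds matrix from the bond graph: exact 1-2 (equilibrium bond
# lengths) and 1-3 (law of cosines with the equilibrium angle), otherwise
# lower = 0.8 * vdW sum and upper = shortest bonded path length
dg_bounds <- function(mol, par = ff_params(mol)) {
  n <- n_atoms(mol)
  W <- matrix(Inf, n, n); diag(W) <- 0
  b <- par$bonds
  for (k in seq_len(nrow(b))) W[b$a[k], b$b[k]] <- W[b$b[k], b$a[k]] <- b$r0[k]
  for (via in seq_len(n)) W <- pmin(W, outer(W[, via], W[via, ], `+`))
  lo <- 0.8 * outer(.vdw_radius[mol$elements], .vdw_radius[mol$elements], `+`)
  hi <- W
  a <- par$angles
  for (k in seq_len(nrow(a))) {
    r1 <- W[a$i[k], a$j[k]]; r2 <- W[a$j[k], a$k[k]]
    d13 <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(a$theta0[k]))
    lo[a$i[k], a$k[k]] <- lo[a$k[k], a$i[k]] <- d13
    hi[a$i[k], a$k[k]] <- hi[a$k[k], a$i[k]] <- d13
  }
  for (k in seq_len(nrow(b))) {
    lo[b$a[k], b$b[k]] <- lo[b$b[k], b$a[k]] <- b$r0[k]
    hi[b$a[k], b$b[k]] <- hi[b$b[k], b$a[k]] <- b$r0[k]
  }
  lo <- pmin(lo, hi)
  diag(lo) <- diag(hi) <- 0
  list(lo = lo, hi = hi)
}

# one random metric-matrix embedding: distances drawn uniformly within
# bounds, classical MDS via the top three eigenvectors
dg_embed <- function(mol, bounds) {
  n <- n_atoms(mol)
  D <- bounds$lo + matrix(stats::runif(n * n), n, n) * (bounds$hi - bounds$lo)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  D2 <- D^2
  d0 <- rowMeans(D2) - sum(D2) / (2 * n^2)
  G <- (outer(d0, d0, `+`) - D2) / 2
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values[1:3], 1e-8)
  X <- eg$vectors[, 1:3] %*% diag(sqrt(lam))
  out <- mol
  out$coords <- X
  out
}

#' Stochastic conformer search
#'
#' Generates `n_conformers` random 3D conformations by distance-geometry
#' embedding (random distances within graph-derived bounds, metric-matrix
#' projection) and minimizes each with the classical valence forcefield.
#' Fully reproducible under the configuration seed. Embeddings whose
#' minimization fails to converge are kept with status `"failed"` and
#' reported, not dropped silently.
#'
#' @param input a SMILES string or a [mol3d] object.
#' @param config an [ir_config].
#' @param maxit forcefield minimizer iteration cap per conformer.
#' @return list of [conformer_record] with forcefield energies (kJ/mol).
#' @export
conformer_search <- function(input, config = ir_config(), maxit = 300) {
  mol <- if (is.character(input)) smiles_to_mol3d(input) else input
  if (!inherits(mol, "mol3d")) stop("input must be a SMILES string or mol3d")
  par <- ff_params(mol)
  bounds <- dg_bounds(mol, par)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_conformers)
  records <- vector("list", config$n_conformers)
  for (i in seq_len(config$n_conformers)) {
    set.seed(seeds[i])
    emb <- dg_embed(mol, bounds)
    opt <- ff_minimize(emb, par = par, maxit = maxit)
    records[[i]] <- conformer_record(
      opt, energy = attr(opt, "energy"),
      status = if (attr(opt, "converged")) "ok" else "failed",
      source = list(method = "distance-geometry", index = i))
  }
  records
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
}

#' Diversity selection by greedy max-min RMSD
#'
#' Keeps at most `max_selected` conformers: the lowest-energy record is
#' taken first, then the record maximizing the minimum heavy-atom RMSD
#' (after optimal superposition) to everything already selected, repeatedly.
#' Near-duplicates of an already-selected structure (below `dedup_tol`) are
#' never added.
#'
#' @param records list of [conformer_record]; failed records are ignored.
#' @param config an [ir_config] (uses `max_selected`).
#' @param dedup_tol RMSD below which a candidate counts as a duplicate, A.
#' @return the selected records, in selection order.
#' @export
diversity_select <- function(records, config = ir_config(), dedup_tol = 0.01) {
  records <- Filter(function(r) r$status == "ok", records)
  if (!length(records)) return(records)
  en <- vapply(records, function(r) r$energy, 0)
  el <- records[[1]]$structure$elements
  sel <- which.min(en)
  cand <- setdiff(seq_along(records), sel)
  mind <- vapply(cand, function(i)
    kabsch_rmsd(records[[i]]$structure$coords, records[[sel]]$structure$coords,
                heavy_only = TRUE, elements = el), 0)
  while (length(cand) && length(sel) < config$max_selected) {
    best <- which.max(mind)
    if (mind[best] < dedup_tol) break
    pick <- cand[best]
    sel <- c(sel, pick)
    cand <- cand[-best]; mind <- mind[-best]
    if (length(cand))
      mind <- pmin(mind, vapply(cand, function(i)
        kabsch_rmsd(records[[i]]$structure$coords, records[[pick]]$structure$coords,
                    heavy_only = TRUE, elements = el), 0))
  }
  records[sel]
}

#' Relative-energy filter
#'
#' Retains records within the energy window above the ensemble minimum:
#' `energy_cutoff` (default 40 kJ/mol), or `pyranosyl_cutoff` (default
#' 80 kJ/mol) when `pyranosyl = TRUE`. The minimum-energy record always
#' survives.
#'
#' @param records list of [conformer_record] with energies.
#' @param config an [ir_config].
#' @param pyranosyl use the wider pyranosyl-cation window.
#' @return the retained records.
#' @export
filter_by_energy <- function(records, config = ir_config(), pyranosyl = FALSE) {
  if (!length(records)) return(records)
  cut <- if (pyranosyl) config$pyranosyl_cutoff else config$energy_cutoff
  en <- vapply(records, function(r) r$energy, 0)
  records[en - min(en) <= cut]
}

#' Run the full IR simulation pipeline
#'
#' Executes all stages on one ion: conformer search, diversity selection,
#' energy filtering, geometry refinement with harmonic frequencies and
#' intensities from the backend, removal of saddle points (imaginary
#' modes), Gibbs free energies, frequency scaling, Gaussian broadening,
#' Boltzmann ensemble averaging, and diagnostic-band classification of the
#' composite trace.
#'
#' @param input SMILES string or [mol3d].
#' @param config an [ir_config].
#' @param pyranosyl logical, selects the wider energy window.
#' @param backend an `energy_backend` with optimize + frequencies
#'   capabilities (default the valence forcefield).
#' @return list of class `ir_result`: `records` (final ensemble with
#'   spectra and Gibbs energies), `spectrum` (composite trace),
#'   `assignment` (from [classify_ion_type]), `stages` (data.frame of
#'   per-stage counts), `config`.
#' @export
run_ir_pipeline <- function(input, config = ir_config(), pyranosyl = FALSE,
                            backend = forcefield_backend()) {
  searched <- conformer_search(input, config)
  selected <- diversity_select(searched, config)
  filtered <- filter_by_energy(selected, config, pyranosyl)
  refined <- lapply(filtered, function(r) {
    opt <- if ("optimize" %in% backend$capabilities)
      backend$optimize(r$structure) else r$structure
    fr <- backend$frequencies(opt)
    e <- backend$energy(opt)
    rec <- conformer_record(opt, energy = e, frequencies = fr$frequencies,
                            intensities = fr$intensities, status = r$status,
                            source = r$source)
    if (!rec$has_imaginary) {
      th <- thermo_corrections(fr$frequencies, T = config$temperature,
                               electronic = e, structure = opt)
      rec$gibbs <- th$gibbs
    }
    rec
  })
  minima <- Filter(function(r) !r$has_imaginary, refined)
  if (!length(minima)) stop("no true minima survived the pipeline")
  traces <- lapply(minima, function(r) {
    keep <- r$frequencies > 0
    lines <- spectrum_ir(r$frequencies[keep], r$intensities[keep],
                         kind = "lines",
                         range = range(config$grid))
    broaden(scale_frequencies(lines, config$scale_factor),
            width = config$broaden_width, grid = config$grid,
            width_is_fwhm = config$width_is_fwhm)
  })
  gibbs <- vapply(minima, function(r) r$gibbs, 0)
  comp <- ensemble_spectrum(traces, gibbs = gibbs, T = config$temperature)
  assignment <- tryCatch(classify_ion_type(comp), error = function(e) NULL)
  stages <- data.frame(
    stage = c("generated", "selected", "filtered", "minima"),
    n = c(length(searched), length(selected), length(filtered), length(minima)))
  structure(list(records = minima, traces = traces, spectrum = comp,
                 assignment = assignment, stages = stages, config = config),
            class = "ir_result")
}

#' @export
print.ir_result <- function(x, ...) {
  cat("IR pipeline result\n")
  for (r in seq_len(nrow(x$stages)))
    cat(sprintf("  %-10s %d\n", x$stages$stage[r], x$stages$n[r]))
  if (!is.null(x$assignment)) cat("  assignment:", x$assignment$label, "\n")
  invisible(x)
}
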