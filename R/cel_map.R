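# CEL maps: binned relative free-energy surfaces over the Cremer-Pople
# sphere. The sphere is sliced into one cell per canonical conformer
# region: polar caps for the two chairs, a 12-cell northern and southern
# tier for the half-chairs/envelopes, and a 12-cell equatorial belt for the
# boats/skew-boats (phi bins 30 degrees wide, centred on the canonical
# positions) - 38 cells that partition the sphere exhaustively.

.sphere_band_edges <- function() {
  canon <- canonical_conformers()
  t_tier <- mean(canon$theta_ref[canon$family %in% c("half-chair", "envelope") &
                                   canon$theta_ref < 90])
  b1 <- t_tier / 2
  b2 <- (t_tier + 90) / 2
  c(0, b1, b2, 180 - b2, 180 - b1, 180)
}

#' The sphere-slice cells of a CEL map
#'
#' @return data.frame, one row per cell: `cell` (id string), `band` (1-5,
#'   north pole to south pole), `bin` (0-11 within non-polar bands, NA at
#'   the caps), `theta_lo`, `theta_hi`, `phi_center`, and `label` (the
#'   canonical conformer whose reference position falls in the cell).
#' @export
sphere_cells <- function() {
  if (!is.null(.celiris_env$cells)) return(.celiris_env$cells)
  edges <- .sphere_band_edges()
  canon <- canonical_conformers()
  rows <- list()
  for (band in 1:5) {
    if (band %in% c(1, 5)) {
      lab <- if (band == 1) "4C1" else "1C4"
      rows[[length(rows) + 1]] <- data.frame(
        cell = lab, band = band, bin = NA_integer_,
        theta_lo = edges[band], theta_hi = edges[band + 1],
        phi_center = NA_real_, label = lab)
    } else {
      for (bin in 0:11) {
        phi_c <- 30 * bin
        inside <- canon$theta_ref >= edges[band] & canon$theta_ref < edges[band + 1] &
          abs(angle_diff(canon$phi_ref, phi_c)) < 15
        lab <- canon$name[inside]
        stopifnot(length(lab) == 1)
        rows[[length(rows) + 1]] <- data.frame(
          cell = lab, band = band, bin = bin,
          theta_lo = edges[band], theta_hi = edges[band + 1],
          phi_center = phi_c, label = lab)
      }
    }
  }
  cells <- do.call(rbind, rows)
  .celiris_env$cells <- cells
  cells
}

# map (theta, phi) in degrees to a cell row index; exhaustive and disjoint
assign_cell <- function(theta, phi) {
  cells <- sphere_cells()
  edges <- .sphere_band_edges()
  band <- findInterval(theta, edges, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1), 5)
  bin <- floor(((phi + 15) %% 360) / 30)
  out <- integer(length(theta))
  for (i in seq_along(theta)) {
    out[i] <- if (band[i] %in% c(1, 5)) which(cells$band == band[i])
    else which(cells$band == band[i] & cells$bin == bin[i])
  }
  out
}

#' Collapse duplicate conformers
#'
#' Constrained optimizations frequently converge to the same structure from
#' different grid points; records within `rmsd_tol` heavy-atom RMSD (after
#' optimal superposition) and `e_tol` energy of an earlier record are
#' dropped.
#'
#' @param records list of [conformer_record].
#' @param rmsd_tol Angstrom (default 0.1).
#' @param e_tol kJ/mol (default 0.1).
#' @return the de-duplicated record list.
#' @export
collapse_duplicates <- function(records, rmsd_tol = 0.1, e_tol = 0.1) {
  n <- length(records)
  if (n <= 1) return(records)
  el <- records[[1]]$structure$elements
  heavy <- el != "H"
  # cheap invariants screen candidate pairs before the Kabsch superposition:
  # energies within e_tol, and sorted heavy-atom distance spectra within a
  # conservative bound (pair distances change by at most 2*sqrt(m)*RMSD)
  sig <- lapply(records, function(r)
    sort(stats::dist(r$structure$coords[heavy, , drop = FALSE])))
  sig_bound <- 2 * sqrt(sum(heavy)) * rmsd_tol
  en <- vapply(records, function(r) r$energy, 0)
  keep <- logical(n); kept_idx <- integer()
  for (i in seq_len(n)) {
    dup <- FALSE
    for (k in kept_idx) {
      if (abs(en[i] - en[k]) > e_tol) next
      if (max(abs(sig[[i]] - sig[[k]])) > sig_bound) next
      if (kabsch_rmsd(records[[i]]$structure$coords,
                      records[[k]]$structure$coords,
                      heavy_only = TRUE, elements = el) <= rmsd_tol) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
    if (!dup) kept_idx <- c(kept_idx, i)
  }
  records[keep]
}

#' Build a CEL map from an optimized grid ensemble
#'
#' Assigns every successful conformer to its sphere-slice cell through
#' [cp_coordinates] and keeps the lowest-energy member per cell. Cell
#' energies are expressed relative to `reference_energy` (kJ/mol); by
#' default the ensemble minimum, so the map's own minimum sits at zero. To
#' compare two rotamer maps on one scale, pass the global minimum across
#' both ensembles as the common reference.
#'
#' @param records list of [conformer_record] carrying coordinates and
#'   energies (Gibbs energies are used when present, electronic otherwise).
#' @param rotamer label all records must share; taken from the records when
#'   omitted.
#' @param reference_energy energy zero in kJ/mol, or `NULL` for the
#'   ensemble minimum.
#' @param contour_kcal contour interval carried to exports, kcal/mol
#'   (default 0.5).
#' @param collapse drop duplicate structures first (see
#'   [collapse_duplicates]).
#' @return object of class `cel_map`: `rotamer`, `cells` (data.frame with
#'   cell, label, band, bin, dG_kjmol, dG_kcal, n_members, record index),
#'   `records`, `reference_energy`, `contour_kcal`, `missing_cells`,
#'   `n_skipped`.
#' @export
build_map <- function(records, rotamer = NULL, reference_energy = NULL,
                      contour_kcal = 0.5, collapse = TRUE) {
  if (!length(records)) stop("empty ensemble")
  if (contour_kcal <= 0) stop("contour interval must be > 0")
  rots <- unique(stats::na.omit(vapply(records, function(r) r$rotamer, "")))
  if (is.null(rotamer)) rotamer <- if (length(rots)) rots[1] else NA_character_
  if (length(rots) > 1) stop("records carry mixed rotamer labels")
  ok <- vapply(records, function(r) r$status == "ok", TRUE)
  en <- vapply(records, function(r) if (is.na(r$gibbs)) r$energy else r$gibbs, 0)
  usable <- ok & is.finite(en)
  n_skipped <- sum(!usable)
  records_ok <- records[usable]
  if (!length(records_ok)) stop("no usable records (all failed or unenergied)")
  if (collapse) records_ok <- collapse_duplicates(records_ok)
  en <- vapply(records_ok, function(r) if (is.na(r$gibbs)) r$energy else r$gibbs, 0)
  if (is.null(reference_energy)) reference_energy <- min(en)
  cp <- lapply(records_ok, function(r)
    cp_coordinates(r$structure, ring_idx = attr(r$structure, "ring")))
  nonplanar <- !vapply(cp, function(p) p$planar, TRUE)
  records_ok <- records_ok[nonplanar]; cp <- cp[nonplanar]; en <- en[nonplanar]
  idx <- assign_cell(vapply(cp, function(p) p$theta, 0),
                     vapply(cp, function(p) p$phi, 0))
  cells <- sphere_cells()
  cells$dG_kjmol <- NA_real_; cells$n_members <- 0L; cells$record <- NA_integer_
  for (ci in unique(idx)) {
    members <- which(idx == ci)
    best <- members[which.min(en[members])]    # ties: lowest record index
    cells$dG_kjmol[ci] <- en[best] - reference_energy
    cells$n_members[ci] <- length(members)
    cells$record[ci] <- best
  }
  cells$dG_kcal <- kjmol_to_kcalmol(cells$dG_kjmol)
  structure(list(rotamer = rotamer, cells = cells, records = records_ok,
                 reference_energy = reference_energy,
                 contour_kcal = contour_kcal,
                 missing_cells = cells$cell[cells$n_members == 0L],
                 n_skipped = n_skipped),
            class = "cel_map")
}

#' @export
print.cel_map <- function(x, ...) {
  occ <- sum(x$cells$n_members > 0)
  cat(sprintf("CEL map (%s): %d/%d cells occupied, %d conformers, min cell %s\n",
              x$rotamer, occ, nrow(x$cells), length(x$records),
              x$cells$label[which.min(x$cells$dG_kjmol)]))
  invisible(x)
}

# neighbor structure of the sphere cells: same band +-1 bin (periodic),
# adjacent band same/adjacent bin; the polar caps touch every cell of the
# neighboring tier
.cell_neighbors <- function() {
  if (!is.null(.celiris_env$cell_nb)) return(.celiris_env$cell_nb)
  cells <- sphere_cells()
  n <- nrow(cells)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    bi <- cells$band[i]
    for (j in seq_len(n)) {
      if (i == j) next
      bj <- cells$band[j]
      if (abs(bi - bj) > 1) next
      if (bi %in% c(1, 5) || bj %in% c(1, 5)) { nb[[i]] <- c(nb[[i]], j); next }
      dbin <- min((cells$bin[i] - cells$bin[j]) %% 12,
                  (cells$bin[j] - cells$bin[i]) %% 12)
      if (dbin <= 1) nb[[i]] <- c(nb[[i]], j)
    }
  }
  .celiris_env$cell_nb <- nb
  nb
}

#' Local minima of a CEL map
#'
#' Occupied cells whose relative energy is less than or equal to that of
#' every occupied neighboring cell (neighborhood: adjacent theta band and
#' phi bin, phi periodic; the polar caps neighbor their whole adjacent
#' tier). On a flat surface every occupied cell qualifies. Results are
#' sorted by energy.
#'
#' @param map a `cel_map`.
#' @return data.frame: `cell`, `label`, `dG_kjmol`, `dG_kcal`, `record`.
#' @export
find_local_minima <- function(map) {
  cells <- map$cells
  nb <- .cell_neighbors()
  occ <- which(cells$n_members > 0)
  is_min <- vapply(occ, function(i) {
    nbo <- intersect(nb[[i]], occ)
    all(cells$dG_kjmol[i] <= cells$dG_kjmol[nbo] + 1e-9)
  }, TRUE)
  out <- cells[occ[is_min], c("cell", "label", "dG_kjmol", "dG_kcal", "record")]
  out <- out[order(out$dG_kjmol), ]
  rownames(out) <- NULL
  out
}

#' Compare the R1 and R2 rotamer maps
#'
#' Evaluates whether long-range participation (LRP) is energetically
#' favorable: the best (lowest) cell of the participation-capable rotamer
#' map (R1) against the best cell of the free-oxocarbenium rotamer map
#' (R2), both referenced to one energy zero. Verdict: `"LRP-favorable"`
#' when R1 lies below R2 by more than `threshold` kcal/mol,
#' `"LRP-unfavorable"` when above by more than the threshold, otherwise
#' `"indeterminate"`.
#'
#' @param map_r1,map_r2 `cel_map` objects built with a common
#'   `reference_energy`.
#' @param threshold significance threshold in kcal/mol (default 0.5).
#' @return list of class `rotamer_comparison`: best conformer name and
#'   relative energy per rotamer (kcal/mol), `ddG_kcal` = G(R1) - G(R2),
#'   `threshold`, `verdict`.
#' @export
compare_rotamers <- function(map_r1, map_r2, threshold = 0.5) {
  if (abs(map_r1$reference_energy - map_r2$reference_energy) > 1e-6)
    stop("maps use inconsistent reference energies; rebuild with a common zero")
  b1 <- which.min(map_r1$cells$dG_kjmol)
  b2 <- which.min(map_r2$cells$dG_kjmol)
  g1 <- map_r1$cells$dG_kcal[b1]; g2 <- map_r2$cells$dG_kcal[b2]
  ddg <- g1 - g2
  verdict <- if (ddg < -threshold) "LRP-favorable"
  else if (ddg > threshold) "LRP-unfavorable"
  else "indeterminate"
  structure(list(best_r1 = map_r1$cells$label[b1], dG_r1_kcal = g1,
                 best_r2 = map_r2$cells$label[b2], dG_r2_kcal = g2,
                 ddG_kcal = ddg, threshold = threshold, verdict = verdict),
            class = "rotamer_comparison")
}

#' @export
print.rotamer_comparison <- function(x, ...) {
  cat(sprintf("R1 best %s (%.2f kcal/mol) vs R2 best %s (%.2f kcal/mol)\n",
              x$best_r1, x$dG_r1_kcal, x$best_r2, x$dG_r2_kcal))
  cat(sprintf("ddG(R1-R2) = %.2f kcal/mol (threshold %.2f) -> %s\n",
              x$ddG_kcal, x$threshold, x$verdict))
  invisible(x)
}

#' Export a CEL map as a heat-map figure and a CSV table
#'
#' The CSV holds one row per occupied cell (theta band, phi bin, canonical
#' label, relative energy in kJ/mol and kcal/mol) with fixed formatting, so
#' re-exporting the same map is byte-identical. The figure shades each
#' sphere-slice cell on a phi-theta rectangle with fills stepped at the
#' map's contour interval (default 0.5 kcal/mol).
#'
#' @param map a `cel_map`.
#' @param csv_path path for the table, or `NULL` to skip.
#' @param png_path path for the figure, or `NULL` to skip.
#' @param width,height figure size in pixels.
#' @return data.frame of the exported table, invisibly.
#' @export
export_heatmap <- function(map, csv_path = NULL, png_path = NULL,
                           width = 900, height = 600) {
  cells <- map$cells[map$cells$n_members > 0, ]
  cells <- cells[order(cells$band, ifelse(is.na(cells$bin), -1, cells$bin)), ]
  tab <- data.frame(band = cells$band,
                    bin = ifelse(is.na(cells$bin), "", cells$bin),
                    conformer = cells$label,
                    dG_kjmol = sprintf("%.6f", cells$dG_kjmol),
                    dG_kcal = sprintf("%.6f", cells$dG_kcal),
                    n_members = cells$n_members)
  if (!is.null(csv_path)) {
    if (!dir.exists(dirname(csv_path)))
      stop("cannot open '", csv_path, "': No such directory")
    con <- file(csv_path, open = "wb")    # binary mode: stable line endings
    on.exit(close(con))
    writeLines(c(paste(names(tab), collapse = ","),
                 apply(tab, 1, paste, collapse = ",")), con)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    .plot_cel_map(map)
  }
  invisible(tab)
}

#' @rdname export_heatmap
#' @param ... passed to [graphics::title].
#' @export
plot.cel_map <- function(x, ...) .plot_cel_map(x, ...)

.plot_cel_map <- function(map, ...) {
  cells <- map$cells
  edges <- .sphere_band_edges()
  step <- map$contour_kcal
  finite <- cells$dG_kcal[is.finite(cells$dG_kcal)]
  nlev <- max(1, ceiling(max(finite) / step))
  pal <- grDevices::hcl.colors(nlev + 1, "YlOrRd", rev = TRUE)
  lev <- function(g) pmin(floor(g / step), nlev) + 1
  graphics::plot(NULL, xlim = c(-15, 345), ylim = c(180, 0),
                 xlab = expression(phi ~ "(deg)"),
                 ylab = expression(theta ~ "(deg)"),
                 xaxs = "i", yaxs = "i")
  for (i in seq_len(nrow(cells))) {
    col <- if (cells$n_members[i] == 0) "grey85" else pal[lev(cells$dG_kcal[i])]
    if (cells$band[i] %in% c(1, 5)) {
      graphics::rect(-15, cells$theta_hi[i], 345, cells$theta_lo[i],
                     col = col, border = "white")
      graphics::text(165, mean(c(cells$theta_lo[i], cells$theta_hi[i])),
                     cells$label[i], cex = 0.8)
    } else {
      x0 <- cells$phi_center[i] - 15
      graphics::rect(x0, cells$theta_hi[i], x0 + 30, cells$theta_lo[i],
                     col = col, border = "white")
      graphics::text(x0 + 15, mean(c(cells$theta_lo[i], cells$theta_hi[i])),
                     cells$label[i], cex = 0.6)
    }
  }
  graphics::title(main = sprintf(
    "CEL map (%s), contours %.1f kcal/mol steps", map$rotamer, step), ...)
}
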