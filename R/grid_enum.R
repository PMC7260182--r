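# Prefixed dihedral-grid enumeration and constrained embedding.
#
# The conformational space of the six-membered ring is surveyed by fixing
# the three alternating endocyclic dihedrals C1-C2-C3-C4, C3-C4-C5-O5, and
# C5-O5-C1-C2 on a regular grid while every other internal coordinate
# relaxes. The default grid, -60 to +60 degrees in 15-degree steps, gives
# 9^3 = 729 prefixed conformations per acyl rotamer and spans the whole
# puckering sphere.

#' Dihedral grid specification
#'
#' @param lo,hi grid range in degrees (defaults -60, 60).
#' @param step grid step in degrees (default 15); `(hi - lo)` must be an
#'   exact multiple.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(lo = -60, hi = 60, step = 15) {
  if (step <= 0) stop("configuration error: step must be > 0")
  if (hi <= lo) stop("configuration error: hi must exceed lo")
  if (abs((hi - lo) / step - round((hi - lo) / step)) > 1e-9)
    stop("configuration error: (hi - lo) must be divisible by step")
  structure(list(lo = lo, hi = hi, step = step), class = "grid_spec")
}

#' Enumerate the prefixed conformational grid
#'
#' Cartesian product of the three constrained ring dihedrals over the grid,
#' in deterministic lexicographic order (d1 slowest, d3 fastest), labelled
#' with one acyl rotamer. The default specification yields 729 points.
#'
#' @param spec a [grid_spec].
#' @param rotamer rotamer label attached to every point, `"R1"` or `"R2"`.
#' @return data.frame with columns `d1` (C1-C2-C3-C4), `d2` (C3-C4-C5-O5),
#'   `d3` (C5-O5-C1-C2) in degrees, and `rotamer`.
#' @examples
#' nrow(generate_grid())   # 729
#' @export
generate_grid <- function(spec = grid_spec(), rotamer = c("R1", "R2")) {
  rotamer <- match.arg(rotamer)
  vals <- seq(spec$lo, spec$hi, by = spec$step)
  g <- expand.grid(d3 = vals, d2 = vals, d1 = vals,
                   KEEP.OUT.ATTRS = FALSE)[, c("d1", "d2", "d3")]
  g$rotamer <- rotamer
  rownames(g) <- NULL
  g
}

# the three constrained dihedral quadruples in absolute atom indices,
# given the ordered ring (O5, C1, C2, C3, C4, C5)
ring_dihedral_atoms <- function(ring) {
  list(d1 = ring[c(2, 3, 4, 5)],   # C1-C2-C3-C4
       d2 = ring[c(4, 5, 6, 1)],   # C3-C4-C5-O5
       d3 = ring[c(6, 1, 2, 3)])   # C5-O5-C1-C2
}

#' Locate the acyl rotamer torsion
#'
#' Finds the ester linkage (ring carbon - ester oxygen - carbonyl carbon)
#' and defines the rotamer torsion as ring-neighbor-C - ring-C - O(ester) -
#' C(carbonyl). The two targets place the acetyl carbonyl pointing toward
#' C1 (R1, participation-capable) or away from it (R2): candidate target
#' angles 180 degrees apart are scored by rigidly rotating the acyl group
#' about the C-O bond and measuring the carbonyl-carbon to C1 distance, and
#' the closer approach is labelled R1.
#'
#' @param mol a [mol3d] with bonds.
#' @param ring ordered ring indices from [find_pyranose_ring].
#' @return list(`atoms` = 4 indices, `targets` = c(R1 = deg, R2 = deg)), or
#'   `NULL` when the molecule carries no acyl ester.
#' @export
find_rotamer_torsion <- function(mol, ring = NULL) {
  ring <- find_pyranose_ring(mol, ring = ring)
  nb <- bond_neighbors(mol); el <- mol$elements
  for (pos in 2:6) {
    rc <- ring[pos]
    for (o in setdiff(nb[[rc]], ring)) {
      if (el[o] != "O") next
      for (cc in setdiff(nb[[o]], rc)) {
        if (el[cc] != "C") next
        is_carbonyl <- any(el[setdiff(nb[[cc]], o)] == "O" &
                             vapply(setdiff(nb[[cc]], o), function(x) {
                               k <- mol$bonds$order[(mol$bonds$a == cc & mol$bonds$b == x) |
                                                      (mol$bonds$b == cc & mol$bonds$a == x)]
                               any(k >= 2)
                             }, TRUE))
        if (!is_carbonyl) next
        prev <- ring[pos - 1]          # preceding ring atom anchors the torsion
        atoms <- c(prev, rc, o, cc)
        cur <- dihedral_angle(mol$coords, atoms[1], atoms[2], atoms[3], atoms[4])
        cands <- c(cur, cur + 180)
        d_to_c1 <- vapply(cands, function(tgt) {
          m2 <- rotate_torsion(mol, atoms, tgt)
          sqrt(sum((m2$coords[cc, ] - m2$coords[ring[2], ])^2))
        }, 0)
        tg <- if (d_to_c1[1] <= d_to_c1[2]) cands else rev(cands)
        tg <- ((tg + 180) %% 360) - 180
        return(list(atoms = atoms, targets = c(R1 = tg[1], R2 = tg[2])))
      }
    }
  }
  NULL
}

# rigidly rotate the subtree on the k-side of bond j-k about that bond so
# the i-j-k-l torsion equals target (degrees)
rotate_torsion <- function(mol, atoms, target) {
  i <- atoms[1]; j <- atoms[2]; k <- atoms[3]; l <- atoms[4]
  nb <- bond_neighbors(mol)
  side <- k; frontier <- k; seen <- c(j, k)
  while (length(frontier)) {
    nxt <- setdiff(unlist(nb[frontier]), seen)
    side <- c(side, nxt); seen <- c(seen, nxt); frontier <- nxt
  }
  cur <- dihedral_angle(mol$coords, i, j, k, l)
  ang <- deg2rad(target - cur)
  axis <- mol$coords[k, ] - mol$coords[j, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  out <- mol
  sub <- setdiff(side, k)
  if (length(sub)) {
    rel <- sweep(mol$coords[sub, , drop = FALSE], 2, mol$coords[k, ])
    out$coords[sub, ] <- sweep(rel %*% t(R), 2, mol$coords[k, ], `+`)
  }
  out
}

#' Embed one grid point as a dihedral-constrained optimized structure
#'
#' Relaxes the molecule under the valence scaffold with strong harmonic
#' restraints holding the three ring dihedrals at the grid values (and,
#' when an acyl ester is present, the rotamer torsion at its R1/R2 target).
#' When the input geometry cannot reach the requested dihedrals, a second
#' start from its reflection through the ring mean plane (the opposite ring
#' chirality) is tried and the result with the smaller residual dihedral
#' violation (then lower energy) wins. The recorded energy comes from the
#' supplied backend; points whose achieved dihedrals miss the request by
#' more than `tol` are returned flagged `"failed"` rather than raising.
#'
#' @param mol a [mol3d] with a perceivable pyranose-like ring.
#' @param point one row of [generate_grid()] (or list with `d1`, `d2`,
#'   `d3`, `rotamer`).
#' @param backend an `energy_backend`; used for the final energy, and for
#'   the relaxation itself when it declares the `optimize` capability.
#' @param ring optional explicit ring indices.
#' @param tol acceptance tolerance on each constrained dihedral, degrees.
#' @param k_res restraint force constant, kJ/mol/rad^2.
#' @param rotamer_torsion optional pre-computed [find_rotamer_torsion]
#'   result (saves re-detection across 729 calls).
#' @return a [conformer_record]; `source` carries the grid point and the
#'   achieved dihedrals.
#' @export
embed_constrained <- function(mol, point, backend = forcefield_backend(),
                              ring = NULL, tol = 1.0, k_res = 3000,
                              rotamer_torsion = NULL) {
  ring <- find_pyranose_ring(mol, ring = ring)
  dih <- ring_dihedral_atoms(ring)
  tgt <- c(point$d1, point$d2, point$d3)
  restr <- data.frame(i = c(dih$d1[1], dih$d2[1], dih$d3[1]),
                      j = c(dih$d1[2], dih$d2[2], dih$d3[2]),
                      k = c(dih$d1[3], dih$d2[3], dih$d3[3]),
                      l = c(dih$d1[4], dih$d2[4], dih$d3[4]),
                      target_deg = tgt, k_res = k_res)
  if (is.null(rotamer_torsion)) rotamer_torsion <- find_rotamer_torsion(mol, ring)
  if (!is.null(rotamer_torsion)) {
    rt <- rotamer_torsion
    restr <- rbind(restr, data.frame(
      i = rt$atoms[1], j = rt$atoms[2], k = rt$atoms[3], l = rt$atoms[4],
      target_deg = unname(rt$targets[point$rotamer]), k_res = k_res))
    mol <- rotate_torsion(mol, rt$atoms,
                          unname(rt$targets[point$rotamer]))
  }
  relax <- function(m) {
    if ("optimize" %in% backend$capabilities) backend$optimize(m, restr)
    else ff_minimize(m, restraints = restr)
  }
  try_start <- function(s) {
    opt <- relax(s)
    ach <- vapply(seq_len(nrow(restr)), function(r)
      dihedral_angle(opt$coords, restr$i[r], restr$j[r], restr$k[r], restr$l[r]), 0)
    viol <- max(abs(angle_diff(ach, restr$target_deg)))
    list(opt = opt, ach = ach, viol = viol, e = backend$energy(opt))
  }
  best <- try_start(mol)
  if (best$viol > tol) {      # the opposite ring chirality may satisfy it
    alt <- try_start(.mirror_through_ring_plane(mol, ring))
    if (alt$viol < best$viol - 1e-6 ||
        (alt$viol < best$viol + 1e-6 && alt$e < best$e)) best <- alt
  }
  status <- if (best$viol <= tol) "ok" else "failed"
  out <- best$opt
  attr(out, "ring") <- ring
  conformer_record(out, energy = best$e, rotamer = point$rotamer,
                   status = status,
                   source = list(grid_point = tgt,
                                 achieved = best$ach[1:3],
                                 violation_deg = best$viol))
}

.mirror_through_ring_plane <- function(mol, ring) {
  X <- mol$coords[ring, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  j <- 0:5
  nrm <- vcross(colSums(Xc * sin(2 * pi * j / 6)),
                colSums(Xc * cos(2 * pi * j / 6)))
  nrm <- nrm / sqrt(sum(nrm^2))
  out <- mol
  d <- sweep(mol$coords, 2, ctr) %*% nrm
  out$coords <- mol$coords - 2 * d %*% t(nrm)
  out
}

#' Run the full constrained grid for one rotamer
#'
#' Maps [embed_constrained] over every point of the grid, returning the
#' ensemble and a one-row-per-point manifest (dihedrals, rotamer, status,
#' energy). Failed embeddings are retained with their failure flag so that
#' map completeness can be accounted for.
#'
#' @inheritParams embed_constrained
#' @param spec a [grid_spec].
#' @param rotamer `"R1"` or `"R2"`.
#' @param progress print a dot every 50 points.
#' @return list with `records` (list of [conformer_record]) and `manifest`
#'   (data.frame).
#' @export
run_grid <- function(mol, spec = grid_spec(), rotamer = "R1",
                     backend = forcefield_backend(), ring = NULL, tol = 1.0,
                     progress = FALSE) {
  ring <- find_pyranose_ring(mol, ring = ring)
  rt <- find_rotamer_torsion(mol, ring)
  grid <- generate_grid(spec, rotamer)
  records <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    records[[g]] <- embed_constrained(mol, grid[g, ], backend = backend,
                                      ring = ring, tol = tol,
                                      rotamer_torsion = rt)
    if (progress && g %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  man <- cbind(grid, records_manifest(records)[c("status", "energy_kjmol")])
  man$violation_deg <- vapply(records, function(r) r$source$violation_deg, 0)
  list(records = records, manifest = man)
}
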