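#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the puckering amplitude Q (Angstrom) and the spherical angles
#' theta (0-180 degrees) and phi (0-360 degrees) that place a six-membered
#' ring conformation on the Cremer-Pople sphere. Out-of-plane displacements
#' are taken relative to the Cremer-Pople mean plane (unit normal from the
#' two trigonometrically weighted position sums), so they sum to zero by
#' construction.
#'
#' The ring must be ordered O5, C1, C2, C3, C4, C5 (see
#' [find_pyranose_ring]); with that ordering and the phase convention used
#' here, theta = 0 is the 4C1 chair of D-pyranoses and theta = 180 is 1C4.
#'
#' @param ring a 6 x 3 coordinate matrix in ring order, or a [mol3d] object.
#' @param ring_idx for a `mol3d` input, six ordered atom indices; perceived
#'   with [find_pyranose_ring] when omitted.
#' @return an object of class `pucker_coords`: list with `Q` (Angstrom),
#'   `theta`, `phi` (degrees), the component amplitudes `q2`, `q3`, the
#'   out-of-plane displacements `z`, and `planar` (TRUE when Q is numerically
#'   zero, in which case `theta`/`phi` are `NA`).
#' @examples
#' hexagon <- ideal_ring_geometry("planar", amplitude = 0)
#' cp_coordinates(hexagon)$Q            # 0: no puckering
#' chair <- ideal_ring_geometry("4C1", amplitude = 0.55)
#' cp_coordinates(chair)$theta          # ~0 degrees
#' @export
cp_coordinates <- function(ring, ring_idx = NULL) {
  if (inherits(ring, "mol3d")) {
    idx <- find_pyranose_ring(ring, ring = ring_idx)
    X <- ring$coords[idx, , drop = FALSE]
  } else {
    X <- as.matrix(ring)
  }
  if (!is.numeric(X) || any(dim(X) != c(6, 3)) || !all(is.finite(X)))
    stop("ring must provide six finite 3D positions")
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] < 1e-6))
    stop("invalid geometry: coincident ring atoms")
  X <- sweep(X, 2, colMeans(X))
  j <- 0:5
  Rp <- colSums(X * sin(2 * pi * j / 6))
  Rpp <- colSums(X * cos(2 * pi * j / 6))
  nrm <- vcross(Rp, Rpp)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-10) stop("invalid geometry: ring atoms are collinear")
  nrm <- nrm / nn
  z <- drop(X %*% nrm)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  planar <- Q < 1e-8
  theta <- if (planar) NA_real_ else rad2deg(acos(max(-1, min(1, q3 / Q))))
  phi <- if (planar || q2 < 1e-10) {
    if (planar) NA_real_ else 0
  } else rad2deg(atan2(q2s, q2c)) %% 360
  structure(list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3,
                 z = z, planar = planar),
            class = "pucker_coords")
}

#' @export
print.pucker_coords <- function(x, ...) {
  if (x$planar) cat(sprintf("pucker: planar (Q = %.4f A)\n", x$Q))
  else cat(sprintf("pucker: Q = %.4f A, theta = %.2f, phi = %.2f deg\n",
                   x$Q, x$theta, x$phi))
  invisible(x)
}

## ---- canonical conformer reference table ----------------------------------

.celiris_env <- new.env(parent = emptyenv())

# locants in ring order j = 1..6
.locants <- c("O", "1", "2", "3", "4", "5")

# displacement pattern (sign per ring atom) for each canonical form
.canonical_patterns <- function() {
  pat <- list()
  add <- function(name, family, up = integer(), down = integer()) {
    z <- numeric(6); z[up] <- 1; z[down] <- -1
    pat[[length(pat) + 1]] <<- list(name = name, family = family, z = z)
  }
  add("4C1", "chair", up = c(1, 3, 5), down = c(2, 4, 6))
  add("1C4", "chair", up = c(2, 4, 6), down = c(1, 3, 5))
  for (k in 1:3) {                          # boats: para pair same side
    x <- k; y <- k + 3
    nm <- paste0(.locants[x], ",", .locants[y])
    add(paste0(nm, "B"), "boat", up = c(x, y))
    add(paste0("B", nm), "boat", down = c(x, y))
  }
  skews <- list(c("1", "3"), c("3", "1"), c("5", "1"),
                c("1", "5"), c("2", "O"), c("O", "2"))
  for (s in skews) {                        # skew-boats: meta pair, opposed
    x <- match(s[1], .locants); y <- match(s[2], .locants)
    add(paste0(s[1], "S", s[2]), "skew", up = x, down = y)
  }
  for (k in 1:6) {                          # half-chairs: adjacent, opposed
    k2 <- if (k == 6) 1 else k + 1
    add(paste0(.locants[k], "H", .locants[k2]), "half-chair", up = k, down = k2)
    add(paste0(.locants[k2], "H", .locants[k]), "half-chair", up = k2, down = k)
  }
  for (k in 1:6) {                          # envelopes: one atom displaced
    add(paste0(.locants[k], "E"), "envelope", up = k)
    add(paste0("E", .locants[k]), "envelope", down = k)
  }
  pat
}

#' Canonical pyranose conformer reference positions
#'
#' The 38 canonical six-membered-ring conformers (2 chairs, 6 boats, 6
#' skew-boats, 12 half-chairs, 12 envelopes) with their reference positions
#' on the Cremer-Pople sphere. Positions are derived, once per session, by
#' building the idealized displacement pattern of each form on a regular
#' hexagon and running it through [cp_coordinates], so the table is exactly
#' consistent with this package's phase convention (theta = 0 at 4C1).
#'
#' @return data.frame with columns `name`, `family`, `theta_ref`, `phi_ref`
#'   (degrees).
#' @examples
#' head(canonical_conformers())
#' @export
canonical_conformers <- function() {
  if (!is.null(.celiris_env$canon)) return(.celiris_env$canon)
  hex_xy <- .hexagon_xy(1.466)
  rows <- lapply(.canonical_patterns(), function(p) {
    cp <- cp_coordinates(cbind(hex_xy, 0.25 * p$z))
    data.frame(name = p$name, family = p$family,
               theta_ref = cp$theta, phi_ref = cp$phi,
               stringsAsFactors = FALSE)
  })
  canon <- do.call(rbind, rows)
  canon$phi_ref <- round(canon$phi_ref, 6) %% 360
  .celiris_env$canon <- canon
  canon
}

# Clockwise traversal viewed from +z, so the Cremer-Pople mean-plane normal
# (R' x R'') points along +z and out-of-plane displacements keep their sign.
.hexagon_xy <- function(r) {
  j <- 0:5
  cbind(r * cos(2 * pi * j / 6), -r * sin(2 * pi * j / 6))
}

# great-circle distance between (theta, phi) points, degrees
gc_distance <- function(t1, p1, t2, p2) {
  t1 <- deg2rad(t1); p1 <- deg2rad(p1); t2 <- deg2rad(t2); p2 <- deg2rad(p2)
  x <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(p1 - p2)
  rad2deg(acos(pmax(-1, pmin(1, x))))
}

#' Classify a puckered ring as its nearest canonical conformer
#'
#' Assigns a Cremer-Pople position to the canonical conformer whose
#' reference point lies at minimum great-circle distance on the puckering
#' sphere. Rings with amplitude Q below the planarity threshold are reported
#' as `"planar"` rather than forced onto a canonical name; ties (only
#' possible exactly midway between reference points) go to the earlier row
#' of [canonical_conformers()].
#'
#' @param p a `pucker_coords` object, or a numeric vector `c(theta, phi)` in
#'   degrees (Q then assumed above threshold).
#' @param planarity_threshold amplitude (Angstrom) below which the ring is
#'   called planar; default 0.1.
#' @return list with `name`, `family`, `theta_ref`, `phi_ref`, and
#'   `distance` (great-circle degrees to the reference point).
#' @examples
#' classify_conformer(c(0, 0))$name        # "4C1"
#' classify_conformer(c(180, 0))$name      # "1C4"
#' @export
classify_conformer <- function(p, planarity_threshold = 0.1) {
  if (inherits(p, "pucker_coords")) {
    if (p$planar || p$Q < planarity_threshold)
      return(list(name = "planar", family = "planar",
                  theta_ref = NA_real_, phi_ref = NA_real_,
                  distance = NA_real_))
    theta <- p$theta; phi <- p$phi
  } else {
    theta <- p[1]; phi <- p[2]
  }
  canon <- canonical_conformers()
  d <- gc_distance(theta, phi, canon$theta_ref, canon$phi_ref)
  i <- which.min(d)                      # which.min takes the first tie
  list(name = canon$name[i], family = canon$family[i],
       theta_ref = canon$theta_ref[i], phi_ref = canon$phi_ref[i],
       distance = d[i])
}

#' Ideal ring geometry for a target conformation
#'
#' Builds six ring-atom positions (ordered O5, C1, ..., C5) whose
#' Cremer-Pople coordinates round-trip to the requested target. Used as the
#' fixture generator for the test suite and to seed constrained embeddings.
#' The in-plane projection is a regular hexagon (radius 1.466 Angstrom,
#' close to a pyranose ring); the out-of-plane displacements are the inverse
#' Cremer-Pople transform of the target (Q, theta, phi).
#'
#' @param target one of: a canonical conformer name from
#'   [canonical_conformers()] (e.g. `"4C1"`, `"1S5"`), the string
#'   `"planar"`, a `pucker_coords` object, or a numeric `c(theta, phi)` in
#'   degrees.
#' @param amplitude puckering amplitude Q in Angstrom (> 0 unless planar);
#'   default 0.55, a typical pyranose value.
#' @return a [mol3d] object of six atoms (O, C x 5) with ring bonds, carrying
#'   the ring indices 1:6 in attribute `"ring"`.
#' @examples
#' ring <- ideal_ring_geometry("1C4", 0.55)
#' classify_conformer(cp_coordinates(ring))$name   # "1C4"
#' @export
ideal_ring_geometry <- function(target, amplitude = 0.55) {
  if (inherits(target, "pucker_coords")) {
    theta <- target$theta; phi <- target$phi
    if (target$planar) theta <- NA_real_
    name <- "ring"
  } else if (is.character(target)) {
    if (identical(target, "planar")) { theta <- NA_real_; phi <- 0; name <- "planar" }
    else {
      canon <- canonical_conformers()
      i <- match(target, canon$name)
      if (is.na(i)) stop("unknown canonical conformer: ", target)
      theta <- canon$theta_ref[i]; phi <- canon$phi_ref[i]; name <- target
    }
  } else {
    theta <- target[1]; phi <- target[2]; name <- "ring"
  }
  planar <- is.na(theta) || amplitude == 0
  if (!planar && amplitude <= 0) stop("amplitude must be > 0 for puckered targets")
  z <- if (planar) numeric(6) else .cp_inverse_z(amplitude, theta, phi)
  X <- cbind(.hexagon_xy(1.466), z)
  bonds <- data.frame(a = 1:6, b = c(2:6, 1), order = 1L)
  mol <- mol3d(c("O", rep("C", 5)), X, bonds, charge = 0L, name = name)
  attr(mol, "ring") <- 1:6
  mol
}

# inverse Cremer-Pople transform: displacements for (Q, theta, phi)
.cp_inverse_z <- function(Q, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  q2 <- Q * sin(th); q3 <- Q * cos(th)
  j <- 0:5
  sqrt(1 / 3) * q2 * cos(ph + 4 * pi * j / 6) + q3 / sqrt(6) * (-1)^j
}
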