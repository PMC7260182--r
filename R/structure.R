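#' Molecular structure container
#'
#' A light S3 container for one 3D structure: element symbols, Cartesian
#' coordinates in Angstrom, a bond list with orders, and the total charge.
#' All toolkit operations (puckering analysis, constrained embedding, the
#' forcefield backend, the IR pipeline) consume and return `mol3d` objects.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param bonds data.frame with integer columns `a`, `b` (1-based atom
#'   indices) and `order` (1, 2, 3); may have zero rows.
#' @param charge integer total charge.
#' @param name optional label carried through manifests.
#' @return an object of class `mol3d`.
#' @export
mol3d <- function(elements, coords, bonds = NULL, charge = 0L, name = "mol") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(elements))
    stop("coords must be an n x 3 matrix matching 'elements'")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(bonds))
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  bonds$a <- as.integer(bonds$a); bonds$b <- as.integer(bonds$b)
  if (is.null(bonds$order)) bonds$order <- rep(1L, nrow(bonds))
  structure(list(elements = as.character(elements), coords = coords,
                 bonds = bonds, charge = as.integer(charge), name = name),
            class = "mol3d")
}

#' @export
print.mol3d <- function(x, ...) {
  cat(sprintf("mol3d '%s': %d atoms (%s), %d bonds, charge %+d\n",
              x$name, length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ""),
              nrow(x$bonds), x$charge))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

# adjacency list from the bond table
bond_neighbors <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

# graph (bond-count) distance matrix by BFS; n is small everywhere we call this
graph_distances <- function(mol) {
  n <- n_atoms(mol); nb <- bond_neighbors(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
    }
    D[s, ] <- d
  }
  D
}

## ---- geometric measures ----------------------------------------------------

vcross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

#' Bond angle and torsion measures
#'
#' `bond_angle` returns the i-j-k angle in degrees; `dihedral_angle` the
#' signed i-j-k-l torsion in degrees in (-180, 180], IUPAC sign convention.
#'
#' @param coords n x 3 coordinate matrix.
#' @param i,j,k,l 1-based atom indices.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' @rdname dihedral_angle
#' @export
bond_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]; v <- coords[k, ] - coords[j, ]
  rad2deg(acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))))
}

# smallest signed angular difference a-b in degrees, in (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## ---- superposition ---------------------------------------------------------

#' Optimal-superposition RMSD (Kabsch)
#'
#' Root-mean-squared deviation between two conformations of the same atom
#' list after centroid removal and optimal rotation. Used for duplicate
#' collapse and for the diversity selection of the IR pipeline.
#'
#' @param xa,xb n x 3 coordinate matrices over the same atoms in the same
#'   order.
#' @param heavy_only logical; with `elements` supplied, drop hydrogens first.
#' @param elements element symbols, required when `heavy_only = TRUE`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(xa, xb, heavy_only = FALSE, elements = NULL) {
  if (heavy_only) {
    if (is.null(elements)) stop("heavy_only needs 'elements'")
    keep <- elements != "H"
    xa <- xa[keep, , drop = FALSE]; xb <- xb[keep, , drop = FALSE]
  }
  if (nrow(xa) != nrow(xb)) stop("coordinate sets differ in size")
  A <- sweep(xa, 2, colMeans(xa)); B <- sweep(xb, 2, colMeans(xb))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

## ---- input: SMILES / SDF / XYZ --------------------------------------------

sdf_text_to_mol <- function(txt, name = "mol") {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
  at <- lines[4 + seq_len(na)]
  coords <- cbind(as.numeric(substr(at, 1, 10)),
                  as.numeric(substr(at, 11, 20)),
                  as.numeric(substr(at, 21, 30)))
  elements <- trimws(substr(at, 31, 33))
  bl <- lines[4 + na + seq_len(nb)]
  bonds <- data.frame(a = as.integer(substr(bl, 1, 3)),
                      b = as.integer(substr(bl, 4, 6)),
                      order = as.integer(substr(bl, 7, 9)))
  chg <- 0L
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    chg <- chg + sum(f[seq(3, length(f), by = 2)])
  }
  mol3d(elements, coords, bonds, charge = chg, name = name)
}

#' Build a 3D structure from a SMILES string
#'
#' Parses the SMILES with Open Babel (through ChemmineOB), generates one 3D
#' conformation, and returns it with the perceived bond graph and formal
#' charge. This seeds the distance-geometry conformer search of the IR
#' pipeline; cations are written with explicit charges in the SMILES (e.g.
#' `"C1=[O+]CCCC1"` for the tetrahydropyranyl oxocarbenium ion).
#'
#' @param smiles a single SMILES string.
#' @param name label for the resulting structure.
#' @return a [mol3d] object with 3D coordinates.
#' @export
smiles_to_mol3d <- function(smiles, name = "mol") {
  stopifnot(is.character(smiles), length(smiles) == 1)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " ", name, "\n"),
                              options = data.frame(names = "gen3d", args = "")),
    error = function(e) stop("could not parse SMILES '", smiles, "': ",
                             conditionMessage(e)))
  if (length(strsplit(txt, "\n", fixed = TRUE)[[1]]) < 5)
    stop("could not parse SMILES '", smiles, "'")
  mol <- tryCatch(sdf_text_to_mol(txt, name = name),
                  error = function(e) stop("could not parse SMILES '",
                                           smiles, "'"))
  if (n_atoms(mol) == 0) stop("could not parse SMILES '", smiles, "'")
  mol
}

#' Read structures from SDF or XYZ files
#'
#' SDF records are parsed with ChemmineR (bond orders and formal charges
#' kept); XYZ files carry no bond graph, so bonds are perceived from
#' covalent-radius distance criteria.
#'
#' @param path file path; format from the extension (`.sdf`/`.mol`, `.xyz`).
#' @param charge total charge for XYZ input (XYZ stores none).
#' @return a [mol3d] object (first record for multi-record SDF).
#' @export
read_mol3d <- function(path, charge = 0L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    set <- ChemmineR::read.SDFset(path)
    sdf <- set[[1]]
    ab <- ChemmineR::atomblock(sdf); bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    chg <- 0L
    if (ncol(ab) >= 5) chg <- sum(.sdf_charge_code(ab[, 5]))
    mol3d(elements, ab[, 1:3], bonds, charge = chg,
          name = tools::file_path_sans_ext(basename(path)))
  } else if (ext == "xyz") {
    lines <- readLines(path)
    na <- as.integer(trimws(lines[1]))
    toks <- strsplit(trimws(lines[2 + seq_len(na)]), "\\s+")
    elements <- vapply(toks, `[`, "", 1)
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    mol <- mol3d(elements, coords, charge = charge,
                 name = tools::file_path_sans_ext(basename(path)))
    mol$bonds <- perceive_bonds(mol)
    mol
  } else stop("unsupported structure format: ", ext)
}

# ctab charge column codes: 0 none, 1 -> +3, 2 -> +2, 3 -> +1, 5 -> -1, ...
.sdf_charge_code <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  unname(map[as.character(code)])
}

#' @rdname read_mol3d
#' @param mol a [mol3d] object lacking bonds.
#' @export
perceive_bonds <- function(mol) {
  n <- n_atoms(mol); X <- mol$coords
  rc <- .cov_radius[mol$elements]
  a <- integer(); b <- integer()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d < 1.25 * (rc[i] + rc[j])) { a <- c(a, i); b <- c(b, j) }
  }
  data.frame(a = a, b = b, order = rep(1L, length(a)))
}

#' Write a structure as XYZ text
#'
#' @param mol a [mol3d] object.
#' @param path output path; with `NULL` the text is returned invisibly.
#' @return the XYZ text, invisibly.
#' @export
write_xyz <- function(mol, path = NULL) {
  body <- sprintf("%-2s %14.8f %14.8f %14.8f", mol$elements,
                  mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  txt <- c(as.character(n_atoms(mol)), mol$name, body)
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

## ---- ring perception -------------------------------------------------------

# all simple cycles of length 6 through DFS; molecules here are small
.six_cycles <- function(nb) {
  n <- length(nb); out <- list()
  path <- integer(6)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    if (depth == 6) {
      if (start %in% nb[[v]] && path[1] == min(path)) out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in nb[[v]]) if (w > 0 && !(w %in% path[seq_len(depth)]) && w >= start)
      dfs(start, w, depth + 1)
  }
  for (s in seq_len(n)) dfs(s, s, 1)
  unique(lapply(out, function(p) {
    # canonical orientation so each undirected cycle appears once
    i0 <- which.min(p); p <- c(p[i0:6], p[seq_len(i0 - 1)])
    if (p[2] > p[6]) p <- c(p[1], rev(p[2:6]))
    p
  }))
}

#' Locate and orient the pyranose-like ring
#'
#' Finds the six-membered ring containing exactly one oxygen and five
#' carbons and returns the atom indices ordered O5, C1, C2, C3, C4, C5.
#' C1 (the anomeric carbon) is taken as the ring oxygen's neighbor that is
#' doubly bonded to it when such a bond exists (the oxocarbenium C1=O5+),
#' otherwise the neighbor carrying more non-hydrogen substituents; remaining
#' ties fall to the lower atom index. Supplying `ring` (six ordered indices)
#' bypasses perception.
#'
#' @param mol a [mol3d] object with bonds.
#' @param ring optional integer vector of six ordered ring-atom indices
#'   (O5, C1, ..., C5); returned unchanged after validation.
#' @return integer vector of six atom indices ordered O5, C1, ..., C5.
#' @export
find_pyranose_ring <- function(mol, ring = NULL) {
  nb <- bond_neighbors(mol)
  if (!is.null(ring)) {
    ring <- as.integer(ring)
    if (length(ring) != 6) stop("'ring' must list six atom indices")
    for (k in 1:6) {
      nxt <- ring[if (k == 6) 1 else k + 1]
      if (nrow(mol$bonds) && !(nxt %in% nb[[ring[k]]]))
        stop("supplied ring atoms are not consecutively bonded")
    }
    return(ring)
  }
  if (!nrow(mol$bonds)) stop("bond graph required for ring perception")
  cycles <- .six_cycles(nb)
  keep <- Filter(function(p) {
    el <- mol$elements[p]; sum(el == "O") == 1 && sum(el == "C") == 5
  }, cycles)
  if (!length(keep)) stop("no six-membered C5O ring found")
  p <- keep[[1]]
  o <- p[which(mol$elements[p] == "O")]
  i0 <- which(p == o)
  p <- c(p[i0:6], p[seq_len(i0 - 1)])           # start at the ring oxygen
  cand <- c(p[2], p[6])                         # its two ring-carbon neighbors
  ord2 <- function(ci) {
    k <- mol$bonds$order[(mol$bonds$a == o & mol$bonds$b == ci) |
                           (mol$bonds$b == o & mol$bonds$a == ci)]
    if (length(k)) max(k) else 1L
  }
  heavy_deg <- vapply(cand, function(ci)
    sum(mol$elements[nb[[ci]]] != "H"), numeric(1))
  score <- 10 * vapply(cand, ord2, numeric(1)) + heavy_deg - 1e-6 * cand
  if (score[2] > score[1]) p <- c(p[1], rev(p[2:6]))
  p
}
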