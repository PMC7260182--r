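# Generic valence forcefield
#
# A small classical forcefield over the bond graph: harmonic bonds and
# angles, cosine torsions, and a 12-6 nonbonded term (1-4 pairs scaled by
# 0.5). It is deliberately simple — its job is to produce sane, reproducible
# geometries, relative conformer energies, and harmonic frequency patterns
# for the desk-scale backends, not to rival MMFF-class accuracy.

.bond_r0_table <- c("C-C" = 1.53, "C=C" = 1.34, "C-O" = 1.42, "C=O" = 1.24,
                    "C-H" = 1.09, "O-H" = 0.96, "C-N" = 1.47, "N-H" = 1.01)

.bond_r0 <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2)), collapse = if (order >= 2) "=" else "-")
  if (!is.na(.bond_r0_table[key])) return(unname(.bond_r0_table[key]))
  f <- if (order >= 2) 0.87 else 1
  f * (.cov_radius[e1] + .cov_radius[e2])
}

# internal-coordinate term lists for one molecule; computed once, reused
# across every energy/gradient call on that topology
ff_params <- function(mol) {
  n <- n_atoms(mol); el <- mol$elements; B <- mol$bonds
  nb <- bond_neighbors(mol)
  has_double <- rep(FALSE, n)
  for (k in seq_len(nrow(B))) if (B$order[k] >= 2)
    has_double[c(B$a[k], B$b[k])] <- TRUE

  bonds <- data.frame(a = B$a, b = B$b,
                      r0 = mapply(function(a, b, o) .bond_r0(el[a], el[b], o),
                                  B$a, B$b, B$order),
                      k = ifelse(B$order >= 2, 4200, 2600))

  ai <- integer(); aj <- integer(); ak <- integer()
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2, ])
    }
  }
  th0 <- ifelse(has_double[aj], 120,
                ifelse(el[aj] == "O", 111, ifelse(el[aj] == "C", 109.47, 107)))
  angles <- data.frame(i = ai, j = aj, k = ak, theta0 = deg2rad(th0), k_th = 380)

  ti <- integer(); tj <- integer(); tk <- integer(); tl <- integer()
  tv <- numeric(); tn <- integer(); td <- numeric()
  for (e in seq_len(nrow(B))) {
    j <- B$a[e]; k <- B$b[e]
    for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], c(j, i))) {
      ti <- c(ti, i); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, l)
      if (B$order[e] >= 2 || (has_double[j] && has_double[k])) {
        tv <- c(tv, 20); tn <- c(tn, 2L); td <- c(td, pi)    # planar 2-fold
      } else {
        tv <- c(tv, 3.3); tn <- c(tn, 3L); td <- c(td, 0)    # staggered 3-fold
      }
    }
  }
  torsions <- data.frame(i = ti, j = tj, k = tk, l = tl, V = tv, n = tn, delta = td)

  D <- graph_distances(mol)
  pr <- which(upper.tri(D) & D >= 3, arr.ind = TRUE)
  nbp <- data.frame(i = pr[, 1], j = pr[, 2],
                    rm = 0.9 * (.vdw_radius[el[pr[, 1]]] + .vdw_radius[el[pr[, 2]]]),
                    eps = 0.35,
                    scale = ifelse(D[pr] == 3, 0.5, 1))

  list(bonds = bonds, angles = angles, torsions = torsions, nonbonded = nbp,
       masses = .atomic_mass[el], charges = .bond_increment_charges(mol))
}

# electronegativity bond-increment partial charges; the molecular formal
# charge is spread over the heavy atoms. Drives the dipole-derivative
# (intensity) model only — the forcefield energy has no Coulomb term.
.bond_increment_charges <- function(mol) {
  q <- numeric(n_atoms(mol)); el <- mol$elements
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    d <- 0.16 * (.electroneg[el[b]] - .electroneg[el[a]])
    q[a] <- q[a] + d; q[b] <- q[b] - d
  }
  heavy <- which(el != "H")
  q[heavy] <- q[heavy] + (mol$charge - sum(q)) / length(heavy)
  unname(q)
}

# wrapped angular deviation in radians, result in (-pi, pi]
.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

# torsion restraint list: data.frame(i, j, k, l, target_deg, k_res)
ff_energy_gradient <- function(X, par, restraints = NULL) {
  E <- 0; G <- matrix(0, nrow(X), 3)
  acc <- function(idx, contrib) {
    s <- rowsum(contrib, idx)
    G[as.integer(rownames(s)), ] <<- G[as.integer(rownames(s)), ] + s
  }
  b <- par$bonds
  if (nrow(b)) {
    dv <- X[b$b, , drop = FALSE] - X[b$a, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    E <- E + sum(b$k * (r - b$r0)^2)
    f <- 2 * b$k * (r - b$r0) / r
    acc(b$a, -f * dv); acc(b$b, f * dv)
  }
  a <- par$angles
  if (nrow(a)) {
    u <- X[a$i, , drop = FALSE] - X[a$j, , drop = FALSE]
    v <- X[a$k, , drop = FALSE] - X[a$j, , drop = FALSE]
    ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
    cth <- pmax(-1, pmin(1, rowSums(u * v) / (ru * rv)))
    th <- acos(cth)
    sth <- pmax(sqrt(1 - cth^2), 1e-8)
    E <- E + sum(a$k_th * (th - a$theta0)^2)
    dEdth <- 2 * a$k_th * (th - a$theta0)
    uh <- u / ru; vh <- v / rv
    dthi <- (uh * cth - vh) / (ru * sth)
    dthk <- (vh * cth - uh) / (rv * sth)
    acc(a$i, dEdth * dthi); acc(a$k, dEdth * dthk)
    acc(a$j, -dEdth * (dthi + dthk))
  }
  tor_block <- function(tt, energy_fn) {
    b1 <- X[tt$j, , drop = FALSE] - X[tt$i, , drop = FALSE]
    b2 <- X[tt$k, , drop = FALSE] - X[tt$j, , drop = FALSE]
    b3 <- X[tt$l, , drop = FALSE] - X[tt$k, , drop = FALSE]
    n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
                b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
                b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
    n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
                b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
                b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
    rb2 <- sqrt(rowSums(b2^2))
    m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
                n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
                n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1]) / rb2
    phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
    ev <- energy_fn(phi)                     # list(E = total, dEdphi = vec)
    E <<- E + ev$E
    n1sq <- pmax(rowSums(n1^2), 1e-12); n2sq <- pmax(rowSums(n2^2), 1e-12)
    dpi_ <- (rb2 / n1sq) * n1
    dpl <- -(rb2 / n2sq) * n2
    c1 <- rowSums(b1 * b2) / (n1sq * rb2); c2 <- rowSums(b3 * b2) / (n2sq * rb2)
    dpj <- -dpi_ - c1 * n1 - c2 * n2
    dpk <- c1 * n1 + c2 * n2 - dpl
    acc(tt$i, ev$dEdphi * dpi_); acc(tt$j, ev$dEdphi * dpj)
    acc(tt$k, ev$dEdphi * dpk); acc(tt$l, ev$dEdphi * dpl)
  }
  tt <- par$torsions
  if (!is.null(tt) && nrow(tt))
    tor_block(tt, function(phi) list(
      E = sum(tt$V / 2 * (1 + cos(tt$n * phi - tt$delta))),
      dEdphi = -tt$V / 2 * tt$n * sin(tt$n * phi - tt$delta)))
  if (!is.null(restraints) && nrow(restraints))
    tor_block(restraints, function(phi) {
      dd <- .wrap_pi(phi - deg2rad(restraints$target_deg))
      list(E = sum(restraints$k_res * dd^2), dEdphi = 2 * restraints$k_res * dd)
    })
  p <- par$nonbonded
  if (nrow(p)) {
    dv <- X[p$j, , drop = FALSE] - X[p$i, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv^2)), 0.3)
    s6 <- (p$rm / r)^6
    E <- E + sum(p$scale * p$eps * (s6^2 - 2 * s6))
    f <- p$scale * p$eps * 12 * (s6 - s6^2) / r   # dE/dr
    acc(p$i, -f * dv / r); acc(p$j, f * dv / r)
  }
  list(E = E, G = G)
}

# L-BFGS minimization of the forcefield (plus optional torsion restraints)
ff_minimize <- function(mol, par = NULL, restraints = NULL,
                        maxit = 400, factr = 1e5) {
  if (is.null(par)) par <- ff_params(mol)
  n <- n_atoms(mol)
  # L-BFGS-B asks for fn and gr at the same point back to back; evaluate
  # energy and gradient together once and serve both from a one-slot cache
  last_x <- NULL; last <- NULL
  eval_at <- function(x) {
    if (is.null(last_x) || !identical(x, last_x)) {
      last <<- ff_energy_gradient(matrix(x, n, 3), par, restraints)
      last_x <<- x
    }
    last
  }
  fn <- function(x) eval_at(x)$E
  gr <- function(x) as.vector(eval_at(x)$G)
  res <- stats::optim(as.vector(mol$coords), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = factr))
  out <- mol
  out$coords <- matrix(res$par, n, 3)
  attr(out, "energy") <- ff_energy_gradient(out$coords, par, NULL)$E
  attr(out, "restrained_energy") <- res$value
  attr(out, "converged") <- res$convergence == 0
  out
}

## ---- harmonic analysis -----------------------------------------------------

# numeric Hessian (central differences of the analytic gradient), then
# mass-weighted normal modes. Returns frequencies in cm^-1 (negative =
# imaginary) and intensities from a fixed-charge dipole-derivative model.
ff_frequencies <- function(mol, par = NULL, step = 1e-4) {
  if (is.null(par)) par <- ff_params(mol)
  n <- n_atoms(mol); x0 <- as.vector(mol$coords); m <- 3 * n
  H <- matrix(0, m, m)
  for (c in seq_len(m)) {
    xp <- x0; xp[c] <- xp[c] + step
    xm <- x0; xm[c] <- xm[c] - step
    gp <- as.vector(ff_energy_gradient(matrix(xp, n, 3), par)$G)
    gm <- as.vector(ff_energy_gradient(matrix(xm, n, 3), par)$G)
    H[, c] <- (gp - gm) / (2 * step)
  }
  H <- (H + t(H)) / 2
  mass3 <- rep(par$masses, 3)        # coords flatten column-major: x.., y.., z..
  Hmw <- H / sqrt(outer(mass3, mass3))
  eig <- eigen(Hmw, symmetric = TRUE)
  # kJ/mol/(A^2 u) -> s^-2
  conv <- (1000 / .NA) / (1e-20 * 1.66053906660e-27)
  om2 <- eig$values * conv
  nu <- sign(om2) * sqrt(abs(om2)) / (2 * pi * .c_cm)
  keep <- order(abs(eig$values))[-(1:6)]            # drop 6 rigid-body modes
  keep <- keep[order(nu[keep])]
  modes <- eig$vectors[, keep, drop = FALSE]
  q <- par$charges
  dmu <- vapply(seq_len(ncol(modes)), function(k) {
    cart <- modes[, k] / sqrt(mass3)                # Cartesian displacement
    mu_d <- c(sum(q * cart[seq_len(n)]),
              sum(q * cart[n + seq_len(n)]),
              sum(q * cart[2 * n + seq_len(n)]))
    sum(mu_d^2)
  }, numeric(1))
  list(frequencies = nu[keep], intensities = 100 * dmu,
       n_imaginary = sum(nu[keep] < 0))
}
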