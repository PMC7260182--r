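# Cremer-Pople puckering mathematics

test_that("planar hexagon has zero amplitude and undefined angles", {
  cp <- cp_coordinates(hexagon_with_z(rep(0, 6)))
  expect_equal(cp$Q, 0, tolerance = 1e-12)
  expect_true(cp$planar)
  expect_true(is.na(cp$theta) && is.na(cp$phi))
})

test_that("pure chair displacement pattern gives a pole and Q = c*sqrt(6)", {
  for (c0 in c(0.1, 0.2, 0.35)) {
    up <- cp_coordinates(hexagon_with_z(c0 * (-1)^(0:5)))
    expect_equal(up$Q, c0 * sqrt(6), tolerance = 1e-10)
    expect_equal(up$theta, 0, tolerance = 1e-6)
    down <- cp_coordinates(hexagon_with_z(-c0 * (-1)^(0:5)))
    expect_equal(down$Q, c0 * sqrt(6), tolerance = 1e-10)
    expect_equal(down$theta, 180, tolerance = 1e-6)
  }
})

test_that("puckering coordinates are invariant under rigid motions", {
  set.seed(11)
  targets <- c("4C1", "4H3", "1S5", "B1,4", "E3", "OS2")
  for (tg in targets) {
    ring <- ideal_ring_geometry(tg, 0.55)
    ref <- cp_coordinates(ring)
    for (rep in 1:5) {
      R <- random_rotation()
      moved <- ring$coords %*% R + matrix(stats::rnorm(3, sd = 5), 6, 3,
                                          byrow = TRUE)
      cp <- cp_coordinates(moved)
      expect_equal(cp$Q, ref$Q, tolerance = 1e-6)
      expect_equal(cp$theta, ref$theta, tolerance = 1e-4)
      expect_equal(angle_dist <- abs(((cp$phi - ref$phi + 180) %% 360) - 180),
                   0, tolerance = 1e-4)
    }
  }
})

test_that("out-of-plane displacements sum to zero after mean-plane projection", {
  set.seed(4)
  for (rep in 1:20) {
    z <- stats::rnorm(6, sd = 0.3)
    cp <- cp_coordinates(hexagon_with_z(z))
    expect_lt(abs(sum(cp$z)), 1e-10)
  }
})

test_that("degenerate geometries raise invalid-geometry errors", {
  X <- hexagon_with_z(rep(0, 6))
  X[2, ] <- X[1, ]
  expect_error(cp_coordinates(X), "coincident")
  expect_error(cp_coordinates(cbind(1:6, 2 * (1:6), 3 * (1:6))), "collinear|coincident")
  expect_error(cp_coordinates(matrix(1, 5, 3)), "six")
})

test_that("all 38 canonical reference points classify as themselves", {
  canon <- canonical_conformers()
  expect_equal(nrow(canon), 38)
  expect_equal(as.vector(table(canon$family)[c("chair", "boat", "skew",
                                               "half-chair", "envelope")]),
               c(2, 6, 6, 12, 12))
  # reference positions pairwise distinct
  d <- outer(seq_len(38), seq_len(38), function(i, j)
    gc_dist <- celiris:::gc_distance(canon$theta_ref[i], canon$phi_ref[i],
                                     canon$theta_ref[j], canon$phi_ref[j]))
  expect_true(all(d[upper.tri(d)] > 1))
  for (i in seq_len(38)) {
    cc <- classify_conformer(c(canon$theta_ref[i], canon$phi_ref[i]))
    expect_identical(cc$name, canon$name[i])
  }
})

test_that("poles classify as the two chairs", {
  expect_identical(classify_conformer(c(0, 123))$name, "4C1")
  expect_identical(classify_conformer(c(180, 17))$name, "1C4")
})

test_that("ideal geometries round-trip through cp_coordinates within 1 degree", {
  canon <- canonical_conformers()
  for (Q in c(0.3, 0.55, 0.8)) {
    for (nm in c("4C1", "1C4", "4H3", "E2", "3E", "B1,4", "1S5", "5S1", "2SO")) {
      ring <- ideal_ring_geometry(nm, Q)
      cp <- cp_coordinates(ring)
      i <- match(nm, canon$name)
      expect_equal(cp$Q, Q, tolerance = 1e-6)
      expect_lt(celiris:::gc_distance(cp$theta, cp$phi,
                                      canon$theta_ref[i], canon$phi_ref[i]), 1)
      expect_identical(classify_conformer(cp)$name, nm)
    }
  }
})

test_that("classification partitions the sphere and respects planarity", {
  canon <- canonical_conformers()
  for (th in seq(5, 175, by = 17)) for (ph in seq(0, 350, by = 23)) {
    cc <- classify_conformer(c(th, ph))
    expect_true(cc$name %in% canon$name)
  }
  flat <- cp_coordinates(hexagon_with_z(0.01 * (-1)^(0:5)))  # Q ~ 0.024 A
  expect_identical(classify_conformer(flat)$name, "planar")
  expect_identical(classify_conformer(flat, planarity_threshold = 0.01)$name,
                   "4C1")
})

test_that("amplitude zero builds a planar hexagon", {
  ring <- ideal_ring_geometry("planar", amplitude = 0)
  expect_equal(cp_coordinates(ring)$Q, 0, tolerance = 1e-12)
  expect_error(ideal_ring_geometry("4C1", amplitude = -0.2), "amplitude")
})
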