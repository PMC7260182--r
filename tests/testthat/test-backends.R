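# backend contract: toy potential, forcefield, QC dialect, interchange

test_that("toy single well makes the designed conformer the grid minimum", {
  # independent oracle: dense evaluation of the analytic well over the
  # canonical positions - by construction the minimum is the planted cell
  canon <- canonical_conformers()
  well <- canon[canon$name == "1C4", ]
  tb <- toy_backend(data.frame(theta = well$theta_ref, phi = well$phi_ref,
                               depth = 25, width = 35))
  energies <- vapply(seq_len(nrow(canon)), function(i) {
    tb$energy(ideal_ring_geometry(canon$name[i], 0.55))
  }, 0)
  expect_identical(canon$name[which.min(energies)], "1C4")
  expect_equal(min(energies), -25, tolerance = 1e-6)
})

test_that("constant and symmetric double-well toy potentials behave", {
  tb0 <- toy_backend(data.frame(theta = 0, phi = 0, depth = 0, width = 30),
                     base = 7)
  e <- vapply(c("4C1", "1C4", "B1,4", "E3"), function(nm)
    tb0$energy(ideal_ring_geometry(nm, 0.5)), 0)
  expect_true(all(abs(e - 7) < 1e-12))
  tb2 <- toy_backend(data.frame(theta = c(0, 180), phi = c(0, 0),
                                depth = c(20, 20), width = c(30, 30)))
  e1 <- tb2$energy(ideal_ring_geometry("4C1", 0.55))
  e2 <- tb2$energy(ideal_ring_geometry("1C4", 0.55))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("energy unit conversions round-trip at 1e-10 relative", {
  x <- c(-497.2, 0.001, 1, 152.7)
  expect_equal(kjmol_to_hartree(hartree_to_kjmol(x)), x, tolerance = 1e-10)
  expect_equal(kcalmol_to_kjmol(kjmol_to_kcalmol(x)), x, tolerance = 1e-12)
  expect_equal(hartree_to_kjmol(1), 2625.4996, tolerance = 1e-7)
})

test_that("forcefield backend honors its declared capabilities", {
  fb <- forcefield_backend()
  expect_setequal(fb$capabilities,
                  c("energy", "optimize", "frequencies", "intensities"))
  mol <- local_thp()
  e0 <- fb$energy(mol)
  opt <- fb$optimize(mol)
  expect_lt(attr(opt, "energy"), e0 + 1e-9)
  fr <- fb$frequencies(opt)
  expect_length(fr$intensities, length(fr$frequencies))
  expect_equal(fr$n_imaginary, sum(fr$frequencies < 0))
  expect_length(fr$frequencies, 3 * length(mol$elements) - 6)
})

test_that("QC input decks carry charge, solvent, constraints, and are byte-stable", {
  mol <- local_thp()
  deck <- write_qc_input(mol, job = "opt+freq", solvent = "dichloromethane")
  expect_match(deck, "\n1 1\n")                        # cation, singlet
  expect_match(deck, "SCRF=\\(PCM,Solvent=dichloromethane\\)")
  expect_match(deck, "Freq")
  expect_identical(deck, write_qc_input(mol, job = "opt+freq",
                                        solvent = "dichloromethane"))
  cons <- data.frame(i = 2, j = 3, k = 4, l = 5, target_deg = 15)
  deck2 <- write_qc_input(mol, job = "opt", constraints = cons)
  expect_match(deck2, "Opt=ModRedundant")
  expect_match(deck2, "D 2 3 4 5 =15.0000 F")
  expect_error(write_qc_input(mol, job = "sp", constraints = cons),
               "configuration error")
})

test_that("QC log parsing extracts energy, geometry, and imaginary modes", {
  res <- parse_qc_output(gaussian_log_fixture())
  expect_equal(res$energy_hartree, -497.123456789, tolerance = 1e-12)
  expect_equal(res$energy_kjmol, hartree_to_kjmol(-497.123456789))
  expect_identical(res$elements, c("O", "C"))
  expect_equal(res$coords[2, 1], 1.2)
  expect_equal(res$n_imaginary, 1L)
  expect_true(res$has_imaginary)
  expect_length(res$frequencies, 3)
  expect_equal(res$intensities, c(10, 50, 100))
})

test_that("QC parsing reports which section is missing", {
  expect_error(parse_qc_output(gaussian_log_fixture(with_freq_block = FALSE)),
               "frequency section")
  expect_error(parse_qc_output("no content here"), "SCF Done")
})

test_that("interchange files round-trip conformer ensembles", {
  mol <- local_thp()
  recs <- list(
    conformer_record(mol, energy = -12.5, gibbs = 410.2,
                     frequencies = c(300.1, 1500.2),
                     intensities = c(1, 2), rotamer = "R1"),
    conformer_record(mol, energy = 3.25, status = "failed"))
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_interchange(recs, path)
  expect_length(readLines(path), 2)
  back <- read_interchange(path)
  expect_equal(back[[1]]$energy, -12.5)
  expect_equal(back[[1]]$gibbs, 410.2)
  expect_equal(back[[1]]$frequencies, c(300.1, 1500.2))
  expect_identical(back[[1]]$rotamer, "R1")
  expect_identical(back[[2]]$status, "failed")
  expect_equal(back[[1]]$structure$coords, mol$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("records reject mismatched frequency/intensity lengths", {
  expect_error(conformer_record(local_thp(), frequencies = c(1, 2),
                                intensities = 1), "equal length")
})
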