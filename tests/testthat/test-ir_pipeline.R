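# staged IR pipeline: conformer search, selection, filtering, spectra

small_cfg <- function(n = 12, seed = 42) ir_config(n_conformers = n, seed = seed)

test_that("conformer search is seeded, reproducible, and graph-preserving", {
  cfg <- small_cfg()
  recs1 <- conformer_search(thp_cation_smiles, cfg)
  recs2 <- conformer_search(thp_cation_smiles, cfg)
  expect_length(recs1, cfg$n_conformers)
  expect_equal(recs1[[5]]$structure$coords, recs2[[5]]$structure$coords,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(vapply(recs1, function(r) r$energy, 0),
               vapply(recs2, function(r) r$energy, 0))
  mol <- local_thp()
  for (r in recs1[1:3]) {
    expect_identical(r$structure$elements, mol$elements)
    expect_identical(r$structure$bonds, mol$bonds)
  }
  # a different seed gives different coordinates
  recs3 <- conformer_search(thp_cation_smiles, small_cfg(seed = 7))
  expect_gt(max(abs(recs1[[1]]$structure$coords - recs3[[1]]$structure$coords)),
            1e-6)
})

test_that("embedded conformers have chemically sane bond lengths", {
  recs <- conformer_search(thp_cation_smiles, small_cfg(n = 5))
  mol <- local_thp()
  for (r in recs) {
    if (r$status != "ok") next
    X <- r$structure$coords
    d <- sqrt(rowSums((X[mol$bonds$a, ] - X[mol$bonds$b, ])^2))
    expect_true(all(d > 0.85 & d < 1.75))
  }
})

test_that("diversity selection caps, keeps the minimum, and de-duplicates", {
  cfg <- small_cfg(n = 25)
  recs <- conformer_search(thp_cation_smiles, cfg)
  sel <- diversity_select(recs, ir_config(max_selected = 5))
  expect_lte(length(sel), 5)
  en <- vapply(Filter(function(r) r$status == "ok", recs),
               function(r) r$energy, 0)
  expect_equal(sel[[1]]$energy, min(en))
  # below the cap everything distinct is retained
  sel_all <- diversity_select(recs[1:4], ir_config(max_selected = 40))
  expect_length(sel_all, sum(vapply(recs[1:4],
                                    function(r) r$status == "ok", TRUE)))
  # exact duplicates never enter twice
  dup <- diversity_select(c(recs[1], recs[1], recs[1]),
                          ir_config(max_selected = 40))
  expect_length(dup, 1)
})

test_that("energy filter applies the pyranosyl-dependent windows", {
  mol <- local_thp()
  mk <- function(e) conformer_record(mol, energy = e)
  recs <- lapply(c(0, 30, 50), mk)
  expect_length(filter_by_energy(recs, ir_config(), pyranosyl = FALSE), 2)
  expect_length(filter_by_energy(recs, ir_config(), pyranosyl = TRUE), 3)
  expect_length(filter_by_energy(lapply(c(0, 70), mk), ir_config(),
                                 pyranosyl = TRUE), 2)
  expect_length(filter_by_energy(lapply(c(0, 70), mk), ir_config(),
                                 pyranosyl = FALSE), 1)
  expect_length(filter_by_energy(list(mk(123)), ir_config()), 1)
  # relative, not absolute: a shifted ensemble filters identically
  shifted <- lapply(c(1000, 1030, 1050), mk)
  expect_length(filter_by_energy(shifted, ir_config()), 2)
})

test_that("frequency scaling multiplies positions only", {
  lines <- spectrum_ir(c(800, 1000, 1600), c(1, 2, 3), kind = "lines")
  sc <- scale_frequencies(lines, 0.975)
  expect_equal(sc$positions, c(780, 975, 1560))
  expect_equal(sc$positions / lines$positions, rep(0.975, 3))
  expect_equal(sc$intensities, lines$intensities)
  expect_equal(scale_frequencies(lines, 1)$positions, lines$positions)
  expect_false(is.unsorted(sc$positions))
  expect_error(scale_frequencies(broaden(lines), 0.975), "line list")
})

test_that("Gaussian broadening peaks at lines and conserves intensity", {
  lines <- spectrum_ir(1000, 2.5, kind = "lines")
  tr <- broaden(lines, width = 20)
  expect_identical(tr$kind, "trace")
  expect_equal(tr$positions[which.max(tr$intensities)], 1000)
  expect_equal(sum(tr$intensities) * 1, 2.5, tolerance = 1e-6)  # 1 cm^-1 grid
  # multi-line intensity conservation within grid truncation
  multi <- spectrum_ir(c(900, 1200, 1500), c(1, 2, 3), kind = "lines")
  trm <- broaden(multi, width = 20)
  expect_equal(sum(trm$intensities), 6, tolerance = 1e-6)
  # linearity: coincident duplicate lines double the trace
  twice <- broaden(spectrum_ir(c(1000, 1000), c(2.5, 2.5), kind = "lines"),
                   width = 20)
  expect_equal(twice$intensities, 2 * tr$intensities, tolerance = 1e-12)
  # FWHM interpretation: half maximum at position +- width/2
  half <- tr$intensities[tr$positions == 1010]
  expect_equal(half / max(tr$intensities), 0.5, tolerance = 1e-3)
})

test_that("ensemble spectra weight traces by Boltzmann factors or fractions", {
  a <- synthetic_band_trace(1000)
  b <- synthetic_band_trace(1400)
  expect_equal(ensemble_spectrum(list(a), gibbs = 0)$intensities,
               a$intensities)
  eq <- ensemble_spectrum(list(a, b), gibbs = c(10, 10))
  expect_equal(eq$intensities, (a$intensities + b$intensities) / 2,
               tolerance = 1e-12)
  mix <- ensemble_spectrum(list(a, b), fractions = c(1, 1))
  expect_equal(mix$intensities, eq$intensities, tolerance = 1e-12)
  skew <- ensemble_spectrum(list(a, b), fractions = c(3, 1))
  expect_equal(skew$intensities, 0.75 * a$intensities + 0.25 * b$intensities,
               tolerance = 1e-12)
})

test_that("match score is normalized, symmetric, and scale-invariant", {
  a <- synthetic_band_trace(c(1000, 1500), c(1, 0.5))
  expect_equal(match_score(a, a), 1, tolerance = 1e-12)
  scaled <- a; scaled$intensities <- a$intensities * 10
  expect_equal(match_score(a, scaled), 1, tolerance = 1e-9)
  b <- synthetic_band_trace(c(800, 1750), c(1, 1))
  expect_lt(match_score(a, b), 0.12)
  expect_equal(match_score(a, b), match_score(b, a), tolerance = 1e-12)
  expect_error(match_score(a, b, range = c(100, 200)), "overlap")
  expect_gte(match_score(a, b, method = "pearson"), -1)
})

test_that("diagnostic-band rules recover all three ion classes", {
  oxo <- synthetic_band_trace(c(1600, 1800))
  expect_identical(classify_ion_type(oxo)$label, "oxocarbenium")
  dioxo <- synthetic_band_trace(c(1550, 1500))
  expect_identical(classify_ion_type(dioxo)$label, "dioxolenium")
  opened <- synthetic_band_trace(c(1550, 1500, 1745))
  expect_identical(classify_ion_type(opened)$label, "ring-opened")
  lone <- synthetic_band_trace(1600)
  expect_identical(classify_ion_type(lone)$label, "mixed/indeterminate")
  ev <- classify_ion_type(oxo)$evidence
  expect_true(ev$present[ev$band == "oxocarbenium_1600"])
  expect_equal(ev$position[ev$band == "oxocarbenium_1600"], 1600,
               tolerance = 2)
  narrow <- spectrum_ir(seq(1400, 1600), rep(1, 201), kind = "trace")
  expect_error(classify_ion_type(narrow), "cover")
})

test_that("band recovery holds for amplitudes well above the threshold", {
  # each rule row, diagnostic bands at >= 3x the 5% detection threshold
  # riding on a busy background
  bg_pos <- c(750, 900, 1100, 1300)
  bg_amp <- rep(1, 4)
  rows <- list(
    list(bands = c(1600, 1800), label = "oxocarbenium"),
    list(bands = c(1550, 1500), label = "dioxolenium"),
    list(bands = c(1550, 1500, 1780), label = "ring-opened"))
  for (row in rows) {
    tr <- synthetic_band_trace(c(bg_pos, row$bands),
                               c(0.15 * bg_amp, rep(1, length(row$bands))))
    expect_identical(classify_ion_type(tr)$label, row$label)
  }
})

test_that("spectrum files round-trip through TSV", {
  lines <- spectrum_ir(c(1000.5, 1500.25), c(1, 2), kind = "lines")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(lines, path)
  back <- read_spectrum(path)
  expect_identical(back$kind, "lines")
  expect_equal(back$positions, lines$positions)
  expect_equal(back$intensities, lines$intensities)
  tr <- broaden(lines)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(tr, path2)
  expect_identical(read_spectrum(path2)$kind, "trace")
})

test_that("pipeline stages are monotone and the result is classified", {
  cfg <- small_cfg(n = 20)
  res <- run_ir_pipeline(thp_cation_smiles, cfg, pyranosyl = TRUE)
  n <- res$stages$n
  expect_true(all(diff(n) <= 0))              # generated >= selected >= ...
  expect_identical(res$stages$stage[1], "generated")
  expect_equal(n[1], 20)
  expect_s3_class(res$spectrum, "spectrum_ir")
  expect_true(all(vapply(res$records, function(r) !r$has_imaginary, TRUE)))
  expect_true(all(vapply(res$records, function(r) is.finite(r$gibbs), TRUE)))
  expect_false(is.null(res$assignment))
})

test_that("configuration validates and loads from YAML", {
  expect_error(ir_config(n_conformers = 0))
  expect_error(ir_config(scale_factor = 1.5))
  cfg <- ir_config()
  expect_equal(cfg$n_conformers, 500L)
  expect_equal(cfg$max_selected, 40L)
  expect_equal(cfg$energy_cutoff, 40)
  expect_equal(cfg$pyranosyl_cutoff, 80)
  expect_equal(cfg$scale_factor, 0.975)
  expect_equal(cfg$broaden_width, 20)
  expect_equal(cfg$temperature, 298)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_conformers: 25", "seed: 99", "broaden_width: 15"), path)
  cfg2 <- ir_config_from_yaml(path)
  expect_equal(cfg2$n_conformers, 25L)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$broaden_width, 15)
  expect_equal(cfg2$scale_factor, 0.975)
  writeLines("nonsense_key: 1", path)
  expect_error(ir_config_from_yaml(path), "unknown configuration")
})
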