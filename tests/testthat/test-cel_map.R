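# sphere-slice CEL maps, local minima, rotamer comparison, export

# small helper: run the toy pipeline (coarse grid is enough for the unit
# tests; the acceptance suite runs the full 729)
toy_cel_run <- function(wells, spec = grid_spec(-60, 60, 30), rotamer = "R1") {
  tb <- toy_backend(wells)
  run_grid(ideal_ring_geometry("4C1", 0.55), spec, rotamer = rotamer,
           backend = tb)
}

test_that("sphere cells partition every direction exactly once", {
  cells <- sphere_cells()
  expect_equal(nrow(cells), 38)
  expect_setequal(cells$label, canonical_conformers()$name)
  for (th in seq(0.5, 179.5, by = 13)) for (ph in seq(0, 359, by = 31)) {
    idx <- celiris:::assign_cell(th, ph)
    expect_length(idx, 1)
    expect_true(idx >= 1 && idx <= 38)
  }
  # each canonical reference point lands in its own cell
  canon <- canonical_conformers()
  for (i in seq_len(38)) {
    idx <- celiris:::assign_cell(canon$theta_ref[i], canon$phi_ref[i])
    expect_identical(cells$label[idx], canon$name[i])
  }
})

test_that("single-well toy surface maps to one minimum at the planted cell", {
  run <- toy_cel_run(data.frame(theta = 0, phi = 0, depth = 25, width = 30))
  map <- build_map(run$records)
  expect_s3_class(map, "cel_map")
  expect_equal(min(map$cells$dG_kjmol, na.rm = TRUE), 0)
  expect_identical(map$cells$label[which.min(map$cells$dG_kjmol)], "4C1")
  minima <- find_local_minima(map)
  expect_identical(minima$label[1], "4C1")
  expect_equal(minima$dG_kjmol[1], 0)
})

test_that("two symmetric wells give two equal local minima", {
  run <- toy_cel_run(data.frame(theta = c(0, 180), phi = c(0, 0),
                                depth = c(25, 25), width = c(25, 25)))
  map <- build_map(run$records)
  minima <- find_local_minima(map)
  expect_true(all(c("4C1", "1C4") %in% minima$label))
  top2 <- minima[minima$label %in% c("4C1", "1C4"), ]
  expect_equal(diff(range(top2$dG_kjmol)), 0, tolerance = 0.05)
})

test_that("flat toy surface returns every occupied cell as a minimum", {
  run <- toy_cel_run(data.frame(theta = 0, phi = 0, depth = 0, width = 30))
  map <- build_map(run$records, collapse = FALSE)
  occupied <- sum(map$cells$n_members > 0)
  expect_equal(nrow(find_local_minima(map)), occupied)
})

test_that("ensemble of one conformer occupies exactly one cell", {
  tb <- toy_backend(data.frame(theta = 0, phi = 0, depth = 5, width = 30))
  rec <- embed_constrained(ideal_ring_geometry("4C1", 0.55),
                           list(d1 = 54, d2 = 54, d3 = 54, rotamer = "R1"),
                           backend = tb)
  map <- build_map(list(rec))
  expect_equal(sum(map$cells$n_members > 0), 1)
  expect_equal(min(map$cells$dG_kjmol, na.rm = TRUE), 0)
})

test_that("empty or unusable ensembles raise errors", {
  expect_error(build_map(list()), "empty ensemble")
  bad <- conformer_record(ideal_ring_geometry("4C1", 0.55), status = "failed")
  expect_error(build_map(list(bad)), "no usable")
})

test_that("duplicate conformers collapse to one record", {
  tb <- toy_backend(data.frame(theta = 0, phi = 0, depth = 5, width = 30))
  rec <- embed_constrained(ideal_ring_geometry("4C1", 0.55),
                           list(d1 = 54, d2 = 54, d3 = 54, rotamer = "R1"),
                           backend = tb)
  expect_length(collapse_duplicates(list(rec, rec, rec)), 1)
  shifted <- rec
  shifted$energy <- rec$energy + 5
  expect_length(collapse_duplicates(list(rec, shifted)), 2)
})

test_that("rotamer comparison verdicts follow the threshold rule", {
  deep <- toy_cel_run(data.frame(theta = 0, phi = 0, depth = 30, width = 30),
                      rotamer = "R1")
  shallow <- toy_cel_run(data.frame(theta = 0, phi = 0,
                                    depth = 30 - kcalmol_to_kjmol(2.5),
                                    width = 30), rotamer = "R2")
  all_en <- vapply(c(deep$records, shallow$records),
                   function(r) r$energy, 0)
  ref <- min(all_en[vapply(c(deep$records, shallow$records),
                           function(r) r$status == "ok", TRUE)])
  m1 <- build_map(deep$records, reference_energy = ref)
  m2 <- build_map(shallow$records, reference_energy = ref)
  cmp <- compare_rotamers(m1, m2, threshold = 0.5)
  expect_identical(cmp$verdict, "LRP-favorable")
  expect_equal(cmp$ddG_kcal, -2.5, tolerance = 0.1)
  # sign reversal
  cmp_rev <- compare_rotamers(m2, m1, threshold = 0.5)
  expect_identical(cmp_rev$verdict, "LRP-unfavorable")
  # equal maps are indeterminate
  cmp_eq <- compare_rotamers(m1, m1, threshold = 0.5)
  expect_identical(cmp_eq$verdict, "indeterminate")
  expect_equal(cmp_eq$ddG_kcal, 0)
  # inconsistent zeros are refused
  m2b <- build_map(shallow$records)   # self-referenced
  expect_error(compare_rotamers(m1, m2b), "reference")
})

test_that("heat-map export writes a deterministic CSV and a figure", {
  run <- toy_cel_run(data.frame(theta = 0, phi = 0, depth = 25, width = 30))
  map <- build_map(run$records)
  csv <- withr::local_tempfile(fileext = ".csv")
  png <- withr::local_tempfile(fileext = ".png")
  tab <- export_heatmap(map, csv_path = csv, png_path = png)
  expect_equal(nrow(tab), sum(map$cells$n_members > 0))
  expect_true(file.exists(png) && file.size(png) > 0)
  lines1 <- readLines(csv)
  expect_equal(length(lines1), nrow(tab) + 1)
  # global minimum row shows dG = 0
  expect_true(any(grepl(",0.000000,0.000000,", lines1)))
  csv2 <- withr::local_tempfile(fileext = ".csv")
  export_heatmap(map, csv_path = csv2)
  expect_identical(readLines(csv2), lines1)
  expect_error(export_heatmap(map, csv_path = "/nonexistent-dir/x.csv"),
               "cannot open|No such")
})
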