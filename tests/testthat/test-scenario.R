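# A small, fast configuration used by most runner tests
tiny_scenario <- function(variants = list(), fields = NULL, grid_n = 6) {
  scenario(
    name = "tiny",
    geometry = list(kind = "shell", refinement_level = 1,
                    layers_bone = 1, layers_lining = 1, calibrate = TRUE),
    materials = material_preset(),
    grid = list(n = grid_n, f_min = 100, f_max = 10000),
    fields = fields,
    variants = variants)
}

test_that("scenario validation names the offending pieces", {
  expect_error(scenario(materials = list(bone = list(E1 = 1e9, nu = 0.3,
                                                     rho = 1000))),
               "polyurethane")
  expect_error(
    tiny_scenario(variants = list(list(name = "v", region = "muscle",
                                       scale = list(E1 = 2)))),
    "muscle")
  expect_error(
    tiny_scenario(variants = list(list(name = "v", region = "bone",
                                       set = list(colour = 1)))),
    "colour")
  expect_error(
    tiny_scenario(variants = list(list(region = "bone",
                                       scale = list(E1 = 2)))),
    "without a name")
})

test_that("variant overrides rebuild the targeted material only", {
  mats <- material_preset()
  v1 <- apply_variant(mats, list(name = "stiff", region = "polyurethane",
                                 scale = list(E1 = 100)))
  expect_equal(v1$polyurethane$E1, 1e8)
  expect_identical(v1$bone, mats$bone)

  v2 <- apply_variant(mats, list(name = "damped", region = "polyurethane",
                                 scale = list(eta = 100)))
  expect_equal(loss_factor(v2$polyurethane$loss, 1000), 10)

  v3 <- apply_variant(mats, list(name = "const", region = "polyurethane",
                                 set = list(eta0 = 1)))
  expect_equal(loss_factor(v3$polyurethane$loss, c(100, 9000)), c(1, 1))

  v4 <- apply_variant(mats, list(name = "heavy", region = "polyurethane",
                                 set = list(rho = 8800)))
  expect_equal(v4$polyurethane$rho, 8800)
})

test_that("scenario YAML configs round-trip", {
  sc <- scenario_preset(refinement_level = 2, grid_n = 12)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(sc2$materials, sc$materials, tolerance = 1e-12)
  expect_equal(sc2$geometry, sc$geometry)
  expect_equal(length(sc2$variants), 7L)
  expect_equal(do.call(frequency_grid, sc2$grid),
               do.call(frequency_grid, sc$grid))
})

test_that("the preset campaign produces the full output inventory", {
  sc <- scenario_preset(refinement_level = 2, grid_n = 10)
  outdir <- withr::local_tempdir()
  res <- run_scenario(sc, outdir, quiet = TRUE)

  # 1 baseline + 7 variants: 4 modulus, 2 density, 1 heavy-head
  expect_equal(nrow(res), 8L)
  expect_setequal(res$run, c("baseline", "re_x100", "re_d100", "im_x100",
                             "im_d100", "rho_low", "rho_x10", "heavy_head"))
  expect_true(all(res$status == "ok"))
  expect_identical(attr(res, "status"), 0L)

  for (rn in res$run) {
    files <- list.files(file.path(outdir, rn))
    expect_true(all(c("impedance.csv", "accel_ipsi.csv", "accel_contra.csv",
                      "extrema.txt", "manifest.yaml") %in% files),
                info = rn)
  }
  # baseline exports displacement fields at the default 100/600 Hz, 0/180 deg
  base_files <- list.files(file.path(outdir, "baseline"))
  expect_setequal(grep("^fields_", base_files, value = TRUE),
                  c("fields_f100_ph000.vtk", "fields_f100_ph180.vtk",
                    "fields_f600_ph000.vtk", "fields_f600_ph180.vtk"))

  # manifests carry the resolved masses
  man <- yaml::read_yaml(file.path(outdir, "baseline", "manifest.yaml"))
  expect_equal(man$region_mass_kg$bone, 0.470, tolerance = 0.01)
  expect_equal(man$region_mass_kg$polyurethane, 0.340, tolerance = 0.01)
  man_h <- yaml::read_yaml(file.path(outdir, "heavy_head", "manifest.yaml"))
  expect_equal(man_h$total_mass_kg, 3.47, tolerance = 0.02)
})

test_that("density variants hit the published component masses", {
  # no sweeps needed: masses come straight from the assembled mass matrix
  sc <- scenario_preset(refinement_level = 2)
  mesh <- vibroskull:::scenario_mesh(sc)$mesh
  base <- vibroskull:::scenario_material_set(sc)

  sys <- assemble_system(mesh, base)
  expect_equal(total_mass(sys), 0.810, tolerance = 0.02)

  heavy <- apply_variant(base, sc$variants[[7]])
  sys_h <- assemble_system(mesh, heavy)
  expect_equal(total_mass(sys_h), 3.47, tolerance = 0.02)

  low <- apply_variant(base, sc$variants[[5]])
  sys_l <- assemble_system(mesh, low)
  expect_equal(total_mass(sys_l, "polyurethane"), 0.034,
               tolerance = 0.02)
})

test_that("identical configs give byte-identical spectra", {
  sc <- tiny_scenario()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_scenario(sc, d1, quiet = TRUE)
  run_scenario(sc, d2, quiet = TRUE)
  for (fn in c("impedance.csv", "accel_ipsi.csv", "accel_contra.csv"))
    expect_identical(readLines(file.path(d1, "baseline", fn)),
                     readLines(file.path(d2, "baseline", fn)), info = fn)
})

test_that("a failing variant is recorded without stopping the campaign", {
  sc <- tiny_scenario(variants = list(
    list(name = "bad", region = "polyurethane", set = list(rho = -5)),
    list(name = "good", region = "polyurethane", scale = list(rho = 2))))
  outdir <- withr::local_tempdir()
  res <- run_scenario(sc, outdir, quiet = TRUE)
  expect_identical(attr(res, "status"), 2L)
  expect_equal(res$status[res$run == "bad"], "error")
  expect_equal(res$status[res$run == "good"], "ok")
  expect_true(file.exists(file.path(outdir, "bad", "error.txt")))
})

test_that("heavy-head derivation needs a calibrated baseline", {
  sc <- scenario_preset(refinement_level = 2)
  hh <- heavy_head_variant(sc)
  expect_equal(hh$materials$polyurethane$rho, 8800)
  expect_length(hh$variants, 0L)

  sc$geometry$calibrate <- FALSE
  expect_error(heavy_head_variant(sc), "calibrated")
})
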