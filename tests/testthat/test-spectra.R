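test_that("a free rigid mass shows the j w m impedance line", {
  m <- 0.47
  grid <- frequency_grid(12, 50, 3200)
  sys <- harmonic_system(M = matrix(m), K1 = matrix(0))
  sol <- solve_sweep(sys, dof_load(1), grid)
  imp <- point_impedance(sol)
  Z <- complex(real = imp$re, imaginary = imp$im)
  expect_equal(Z, 1i * 2 * pi * grid * m, tolerance = 1e-10)
  # 6 dB per octave: doubling f adds 20 log10 2
  lv <- 20 * log10(2 * pi * grid * m)
  expect_equal(imp$level_db, lv, tolerance = 1e-10)
  expect_equal(imp$phase_cycles, rep(0.25, length(grid)), tolerance = 1e-12)
  # a monotone line has no extrema
  expect_identical(nrow(find_extrema(imp)), 0L)
})

test_that("a massless spring shows the k / (j w) impedance", {
  k <- 2.2e4
  grid <- c(100, 400, 1600)
  sys <- harmonic_system(M = matrix(0), K1 = matrix(k),
                         K2 = matrix(0))
  sol <- solve_sweep(sys, dof_load(1), grid)
  imp <- point_impedance(sol)
  Z <- complex(real = imp$re, imaginary = imp$im)
  expect_equal(Z, k / (1i * 2 * pi * grid), tolerance = 1e-12)
})

test_that("the dB level convention maps 82 dB to 12589 N s/m", {
  # 10^(82/20) = 12589.25...; the level reference is 1 N s/m
  expect_equal(20 * log10(12589.254117941662), 82, tolerance = 1e-12)
  sys <- harmonic_system(M = matrix(1), K1 = matrix(0))
  f0 <- 12589.254117941662 / (2 * pi)   # |Z| = 2 pi f m = 12589...
  sol <- solve_sweep(sys, dof_load(1), f0)
  imp <- point_impedance(sol)
  expect_equal(imp$level_db, 82, tolerance = 1e-9)
})

test_that("probe acceleration implements a = -w^2 x per unit force", {
  su <- test_surrogate()
  sol <- test_surrogate_sweep()
  drive <- su$load$nodes
  acc <- probe_acceleration(sol, drive)
  ax <- acc[acc$axis == "x", ]
  w2 <- (2 * pi * ax$f_hz)^2
  x_drive <- sol$X[3 * (drive - 1) + 1, ]
  expect_equal(complex(real = ax$re, imaginary = ax$im),
               -w2 * x_drive / su$load$amplitude, tolerance = 1e-12)

  # internal consistency: a = j w v at the drive point links the
  # acceleration spectrum to the impedance spectrum
  imp <- point_impedance(sol)
  Z <- complex(real = imp$re, imaginary = imp$im)
  v <- 1 / Z                                   # velocity per unit force
  a_from_Z <- 1i * 2 * pi * imp$f_hz * v
  expect_equal(complex(real = ax$re, imaginary = ax$im), a_from_Z,
               tolerance = 1e-10)

  expect_error(probe_acceleration(sol, integer(0)), "empty")
  expect_error(probe_acceleration(sol, "cochlea_typo"), "node set")
})

test_that("probes follow the whole-body motion at low frequency", {
  sp <- calibrate_masses(shell_spec(refinement_level = 1, layers_bone = 1,
                                    layers_lining = 1), table1_densities)
  mesh <- generate_shell(sp)
  sys <- assemble_system(mesh, material_preset())
  load <- point_load(mesh, node_set = "stim_site", direction = c(1, 0, 0))
  sol <- solve_sweep(sys, load, 40)
  acc <- probe_acceleration(sol, "ipsi_cochlea")
  ax <- acc[acc$axis == "x", ]
  expect_equal(Mod(complex(real = ax$re, imaginary = ax$im)),
               1 / total_mass(sys), tolerance = 0.01)
  for (axis in c("y", "z")) {
    a <- acc[acc$axis == axis, ]
    expect_lt(Mod(complex(real = a$re, imaginary = a$im)),
              0.05 / total_mass(sys))
  }
})

test_that("patch averaging agrees with its centre below the first mode", {
  su <- test_surrogate()
  sol <- test_surrogate_sweep()
  # a patch of outer-surface nodes around the ipsilateral probe
  centre <- su$mesh$node_sets$ipsi_cochlea[1]
  r <- sqrt(rowSums(su$mesh$nodes^2))
  outer <- which(r > max(r) - 1e-9)
  d <- sqrt(rowSums(sweep(su$mesh$nodes[outer, ], 2L,
                          su$mesh$nodes[centre, ])^2))
  patch <- outer[d < 0.025]
  expect_gt(length(patch), 1L)
  a_patch <- probe_acceleration(sol, patch)
  a_centre <- probe_acceleration(sol, centre)
  low <- a_patch$f_hz < 400   # well below the first elastic resonance
  zp <- complex(real = a_patch$re, imaginary = a_patch$im)[low & a_patch$axis == "x"]
  zc <- complex(real = a_centre$re, imaginary = a_centre$im)[low & a_centre$axis == "x"]
  expect_lt(max(Mod(zp - zc) / Mod(zc)), 0.05)
})

test_that("phase unwrapping restores continuous traces", {
  f <- seq(100, 10000, length.out = 120)
  true_phase <- -3 * f / max(f)            # three cycles of accumulated lag
  wrapped <- true_phase - round(true_phase)
  tr <- unwrap_phase(f, wrapped)
  expect_equal(tr$phase_cycles, true_phase, tolerance = 1e-12)
  expect_equal(tr$phase_cycles[length(f)], -3, tolerance = 1e-12)
  # unwrapped differs from wrapped by whole cycles
  expect_equal(tr$phase_cycles - wrapped, round(tr$phase_cycles - wrapped),
               tolerance = 1e-12)

  const <- unwrap_phase(f, rep(0.2, length(f)))
  expect_equal(const$phase_cycles, rep(0.2, length(f)))
  # first point lands in (-0.5, 0.5]
  shifted <- unwrap_phase(f, rep(2.7, length(f)))
  expect_equal(shifted$phase_cycles[1], -0.3, tolerance = 1e-12)
})

test_that("group delay recovers pure and dispersive delays", {
  f <- seq(200, 5000, length.out = 60)
  tau0 <- 1e-3
  tr <- unwrap_phase(f, rep(0, 60))
  tr$phase_cycles <- -f * tau0             # phi = -2 pi f tau0 radians
  gd <- group_delay(tr)
  expect_equal(gd$group_delay_s, rep(tau0, 60), tolerance = 1e-12)

  tr$phase_cycles <- rep(0.1, 60)
  expect_equal(group_delay(tr)$group_delay_s, rep(0, 60))

  # quadratic phase phi = -a f^2 rad: central differences are exact
  a <- 3e-7
  tr$phase_cycles <- -a * f^2 / (2 * pi)
  gd <- group_delay(tr)$group_delay_s
  inner <- 2:59
  expect_equal(gd[inner], 2 * a * f[inner] / (2 * pi), tolerance = 1e-10)

  expect_error(group_delay(unwrap_phase(c(1, 2), c(0, 0))), "3 points")
})

test_that("group delay is invariant to a constant phase offset", {
  sol <- test_surrogate_sweep()
  acc <- probe_acceleration(sol, "ipsi_cochlea")
  ax <- acc[acc$axis == "x", ]
  tr <- unwrap_phase(ax$f_hz, ax$phase_cycles)
  g1 <- group_delay(tr)$group_delay_s
  tr2 <- tr
  tr2$phase_cycles <- tr$phase_cycles + 0.37
  expect_equal(group_delay(tr2)$group_delay_s, g1, tolerance = 1e-12)
})

test_that("extremum refinement locates a known parabola vertex", {
  # synthetic level trace: parabola in (log f, dB) with vertex at 700 Hz
  f <- frequency_grid(40, 100, 4900)
  lv <- 60 + 25 * (log10(f) - log10(700))^2
  sp <- vibroskull:::new_spectrum(
    tibble::tibble(f_hz = f, re = 1, im = 0, level_db = lv,
                   phase_cycles = 0), "impedance_spectrum")
  ex <- find_extrema(sp)
  expect_identical(nrow(ex), 1L)
  expect_equal(ex$type, "resonance")
  expect_equal(ex$f_hz, 700, tolerance = 1e-6)
  expect_equal(ex$level_db, 60, tolerance = 1e-6)
})

test_that("acceleration extrema labels invert relative to impedance", {
  f <- frequency_grid(30, 100, 8000)
  bump <- 40 - 30 * (log10(f) - log10(1000))^2
  df <- do.call(rbind, lapply(c("x", "y", "z"), function(a)
    data.frame(f_hz = f, axis = a, re = 1, im = 0, level_db = bump,
               phase_cycles = 0)))
  sp <- vibroskull:::new_spectrum(df, "acceleration_spectrum")
  ex <- find_extrema(sp)
  expect_equal(unique(ex$type), "resonance")   # level maximum
  expect_equal(nrow(ex), 3L)
})

test_that("spectrum CSV files round-trip and stay byte-stable", {
  sol <- test_surrogate_sweep()
  imp <- point_impedance(sol)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(imp, f1)
  write_spectrum_csv(imp, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_spectrum_csv(f1)
  expect_equal(names(back)[1:5],
               c("f_hz", "re", "im", "level_db", "phase_cycles"))
  expect_equal(back$re, imp$re, tolerance = 1e-15)

  acc <- probe_acceleration(sol, "ipsi_cochlea")
  write_spectrum_csv(acc, f1)
  back <- read_spectrum_csv(f1)
  expect_equal(names(back)[1:5],
               c("f_hz", "ax_re", "ax_im", "ax_level_db", "ax_phase_cycles"))
  expect_equal(back$az_re, acc[acc$axis == "z", ]$re, tolerance = 1e-15)
})

test_that("tidy, glance and autoplot methods cover the spectrum types", {
  sol <- test_surrogate_sweep()
  imp <- point_impedance(sol)
  td <- tidy(imp)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "impedance_spectrum"))
  gl <- glance(imp)
  expect_true(is.finite(gl$f_resonance))
  expect_gt(gl$n_extrema, 0)
  acc <- probe_acceleration(sol, "contra_cochlea")
  expect_s3_class(glance(acc), "tbl_df")
  expect_s3_class(autoplot(imp), "ggplot")
  expect_s3_class(autoplot(acc), "ggplot")
  tr <- unwrap_phase(imp$f_hz, imp$phase_cycles)
  expect_s3_class(autoplot(tr), "ggplot")
})
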