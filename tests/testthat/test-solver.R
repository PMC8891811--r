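# Solver verification against independent oracles: exact discrete plane
# waves, the Rayleigh integral, the plane-wave transfer matrix, and the
# linearity of the continuous problem.

test_that("discrete operator annihilates an axial plane wave in uniform water", {
  cfg <- column_config()
  dom <- build_domain(cfg)
  sys <- assemble_system(dom)
  kw <- complex_medium(cfg$water, 1e6)$wavenumber
  # radially uniform sampled plane wave
  pw <- exp(-1i * kw * rep(dom$zc, each = dom$Nr))
  res <- band_apply(sys, pw)
  # rows away from the axial absorbers; typical row magnitude ~ |mass term|
  interior <- which(rep(dom$zc, each = dom$Nr) > 0.003 &
                      rep(dom$zc, each = dom$Nr) < cfg$axial_extent_m - 0.003)
  scale_row <- abs(dom$rt_c[1] * dom$h^2 * Mod(kw)^2 / 998)
  expect_lt(max(Mod(res[interior])), 1e-8 * scale_row * max(Mod(pw)))
})

test_that("zero drive amplitude produces an identically zero field", {
  cfg <- mini_bowl_config()
  cfg$transducer$drive_amplitude <- 0
  f <- simulate_field(cfg)
  expect_equal(max(Mod(f$p)), 0)
})

test_that("absorbing boundary reflects less than 1% in a water column", {
  f <- solve_column()
  win <- f$z_m > 0.010 & f$z_m < 0.044
  mag <- Mod(f$p[COLUMN_J, win])
  ripple <- (max(mag) - min(mag)) / mean(mag)
  # standing-wave ripple is ~2 |R|
  expect_lt(ripple / 2, 0.01)
})

test_that("field scales exactly with drive amplitude and superposes", {
  cfg <- mini_bowl_config()
  f1 <- simulate_field(cfg)
  cfg2 <- cfg
  cfg2$transducer$drive_amplitude <- 2
  f2 <- simulate_field(cfg2)
  expect_equal(f2$p, 2 * f1$p, tolerance = 1e-12)

  # superposition of two right-hand sides on one operator
  dom <- build_domain(cfg)
  sys <- assemble_system(dom)
  rhs_a <- sys$rhs
  rhs_b <- rev(rhs_a)
  fa <- solve_field(sys, rhs = rhs_a)
  fb <- solve_field(sys, rhs = rhs_b)
  fab <- solve_field(sys, rhs = rhs_a + rhs_b)
  expect_equal(fab$p, fa$p + fb$p, tolerance = 1e-10)
})

test_that("repeated solves are bit-identical (direct factorization, no randomness)", {
  f1 <- simulate_field(mini_bowl_config())
  f2 <- simulate_field(mini_bowl_config())
  expect_identical(f1$p, f2$p)
})

test_that("free-water axial peak sits within a wavelength of the Rayleigh oracle", {
  cfg <- mini_bowl_config()
  f <- simulate_field(cfg)
  pk <- peak_pressure(f, z_min_m = peak_search_start(f$domain))
  z <- seq(0.008, cfg$axial_extent_m, by = 1e-4)
  oracle <- Mod(rayleigh_axis_pressure(z, cfg$transducer))
  z_oracle <- z[which.max(oracle)]
  lambda_w <- 1482 / 1e6
  expect_lt(abs(pk$z_m - z_oracle), lambda_w)
  expect_lt(pk$r_m, 1e-3) # on axis
})

test_that("quasi-1-D transmission matches the transfer-matrix oracle within 5%", {
  fw <- solve_column()
  fs <- solve_column(layer_stack(layer("skull", 0.005)))
  snapped <- fs$domain$layers$realized_thickness_m[1]
  iobs <- which.min(abs(fw$z_m - 0.045))
  t_num <- Mod(fs$p[COLUMN_J, iobs]) / Mod(fw$p[COLUMN_J, iobs])
  t_ref <- transfer_matrix_1d(layer_stack(layer("skull", snapped)), 1e6)$transmission_abs
  expect_lt(abs(t_num - t_ref) / t_ref, 0.05)

  # a second, lossless resonant layer
  lossless <- medium("fast_lossless", 4080, 1658, 0)
  fr <- solve_column(layer_stack(layer(lossless, 0.00204)))
  snapped_r <- fr$domain$layers$realized_thickness_m[1]
  t_num_r <- Mod(fr$p[COLUMN_J, iobs]) / Mod(fw$p[COLUMN_J, iobs])
  t_ref_r <- transfer_matrix_1d(layer_stack(layer(lossless, snapped_r)), 1e6)$transmission_abs
  expect_lt(abs(t_num_r - t_ref_r) / t_ref_r, 0.05)
})

test_that("on-axis decay in a lossy medium follows exp(-alpha z) within 5%", {
  f <- solve_column(layer_stack(layer("brain", 0.036)), h = 0.185e-3,
                    standoff_m = 0.008)
  # brain occupies 8-44 mm; fit log-amplitude over an interior window
  win <- which(f$z_m > 0.015 & f$z_m < 0.040)
  slope <- unname(coef(lm(log(Mod(f$p[COLUMN_J, win])) ~ f$z_m[win]))[2])
  alpha <- db_to_np(85)
  expect_lt(abs(-slope - alpha) / alpha, 0.05)
})

test_that("transcranial peak is monotone in skull thickness and absorption", {
  cfg <- mini_bowl_config()
  wr <- tfusatt:::.water_reference(cfg)
  peaks <- vapply(c(2, 4, 6), function(zmm) {
    run_single_layer("skull", zmm, cfg, water_reference = wr)$peak
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))

  soft_skull <- medium("skull_lowloss", 4080, 1658, 1000)
  p_soft <- run_single_layer(soft_skull, 4, cfg, water_reference = wr)$peak
  expect_gt(p_soft, peaks[2])
})

test_that("lossless layers attenuate only through impedance mismatch, less than lossy", {
  cfg <- mini_bowl_config()
  wr <- tfusatt:::.water_reference(cfg)
  lossless <- medium("skull_lossless", 4080, 1658, 0)
  att_lossless <- run_single_layer(lossless, 4, cfg, water_reference = wr)$attenuation_percent
  att_lossy <- run_single_layer("skull", 4, cfg, water_reference = wr)$attenuation_percent
  expect_gt(att_lossless, 0)
  expect_lt(att_lossless, att_lossy)
})

test_that("focal metrics recover the widths of a synthetic Gaussian field", {
  dom <- build_domain(mini_bowl_config())
  sz <- 2e-3; sr <- 1.2e-3; z0 <- 0.020
  p <- outer(
    exp(-dom$rc^2 / (2 * sr^2)),
    exp(-(dom$zc - z0)^2 / (2 * sz^2))
  )
  field <- structure(
    list(p = p + 0i, r_m = dom$rc, z_m = dom$zc, frequency_hz = 1e6, domain = dom),
    class = "pressure_field"
  )
  fm <- focal_metrics(field)
  expect_lt(abs(fm$z_peak_m - z0), dom$h)
  expect_lt(abs(fm$fwhm_axial_m - 2.3548 * sz), dom$h)
  expect_lt(abs(fm$fwhm_lateral_m - 2.3548 * sr), dom$h)
  expect_false(fm$axial_truncated)
  expect_false(fm$lateral_truncated)
  # lateral profile is symmetric about the axis by construction of the grid
  expect_equal(fm$r_peak_m, dom$rc[1])
})

test_that("peak search regions behave and empty regions error", {
  f <- simulate_field(mini_bowl_config())
  full <- peak_pressure(f, z_min_m = 0.005)
  away <- peak_pressure(f, z_min_m = full$z_m + 0.004)
  expect_lt(away$peak, full$peak)
  expect_error(peak_pressure(f, z_min_m = 1), "empty search region")
})

test_that("source calibration hits the target free-water pressure on re-solve", {
  cfg <- mini_bowl_config()
  cal <- calibrate_source(cfg, 2.276e6)
  f <- simulate_field(cal)
  pk <- peak_pressure(f, z_min_m = peak_search_start(f$domain))
  expect_equal(pk$peak, 2.276e6, tolerance = 1e-9)
  # linear behaviour of the calibration itself
  cal2 <- calibrate_source(cfg, 2 * 2.276e6)
  expect_equal(cal2$transducer$drive_amplitude,
               2 * cal$transducer$drive_amplitude, tolerance = 1e-12)
  cal0 <- calibrate_source(cfg, 0)
  expect_equal(cal0$transducer$drive_amplitude, 0)
})

test_that("field export writes the long-form CSV and metrics sidecar", {
  f <- simulate_field(mini_bowl_config())
  out <- write_field(f, tempdir(), stem = "unit_field", z_min_m = 0.005)
  expect_true(all(file.exists(out)))
  tb <- utils::read.csv(out[1])
  expect_equal(names(tb), c("r", "z", "re", "im"))
  meta <- jsonlite::read_json(out[2])
  expect_true(is.numeric(meta$peak))
  unlink(out)
})
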