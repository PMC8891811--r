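# Experiment drivers on reduced geometries (the full-size defaults are
# exercised in the acceptance suite).

test_that("zero-thickness layers attenuate nothing", {
  cfg <- mini_bowl_config()
  wr <- tfusatt:::.water_reference(cfg)
  res <- run_single_layer("skull", 0, cfg, water_reference = wr)
  expect_equal(res$attenuation_percent, 0)
  expect_equal(res$tau_percent, 100)
})

test_that("tissue ratios reproduce the published phantom comparison", {
  phantom <- load_fixture("single_layer_phantom")
  ratios <- tissue_ratio_report(tibble::tibble(
    tissue = phantom$site, attenuation_percent = phantom$value
  ))
  expect_equal(round(ratios$ratio[ratios$denominator == "brain"], 2), 4.70)
  expect_equal(round(ratios$ratio[ratios$denominator == "scalp"], 2), 7.06)
})

test_that("tissue ratios from the printed simulation values differ from the phantom headline", {
  sim <- load_fixture("single_layer_sim_mixed_thickness")
  ratios <- tissue_ratio_report(tibble::tibble(
    tissue = sim$site, attenuation_percent = sim$value
  ))
  expect_equal(ratios$ratio[ratios$denominator == "brain"], 83.22 / 34.49)
  expect_equal(round(ratios$ratio[ratios$denominator == "brain"], 2), 2.41)
  expect_equal(ratios$ratio[ratios$denominator == "scalp"], 83.22 / 3.21)
  expect_equal(ratios$ratio[ratios$denominator == "scalp"], 25.92, tolerance = 1e-3)
})

test_that("tissue ratio bookkeeping handles edge cases", {
  eq <- tissue_ratio_report(tibble::tibble(
    tissue = c("scalp", "skull", "brain"), attenuation_percent = c(5, 5, 5)
  ))
  expect_equal(eq$ratio, c(1, 1))
  expect_error(
    tissue_ratio_report(tibble::tibble(
      tissue = c("scalp", "skull", "brain"), attenuation_percent = c(0, 5, 5)
    )),
    "zero"
  )
  expect_error(tissue_ratio_report(tibble::tibble(x = 1)), "columns")
})

test_that("single-layer attenuation orders scalp < brain < skull at matched thickness", {
  cfg <- mini_bowl_config()
  wr <- tfusatt:::.water_reference(cfg)
  att <- vapply(c("scalp", "brain", "skull"), function(m) {
    run_single_layer(m, 5, cfg, water_reference = wr)$attenuation_percent
  }, numeric(1))
  expect_lt(att[["scalp"]], att[["brain"]])
  expect_lt(att[["brain"]], att[["skull"]])
})

test_that("a reduced multilayer attenuates more than its skull layer alone and pulls the focus in", {
  stack_cfg <- mini_bowl_config()
  stack_cfg$standoff_m <- 0.006
  stack_cfg$layers <- layer_stack(
    layer("scalp", 0.002), layer("skull", 0.003), layer("brain", 0.015)
  )
  ml <- run_multilayer(stack_cfg)
  # skull-only comparator at the identical slab position (8-11 mm)
  skull_cfg <- mini_bowl_config()
  skull_cfg$standoff_m <- 0.008
  wr <- tfusatt:::.water_reference(skull_cfg)
  skull_only <- run_single_layer("skull", 3, skull_cfg, water_reference = wr)
  expect_gt(ml$attenuation_percent, skull_only$attenuation_percent)
  expect_lt(ml$head_metrics$z_peak_m, ml$water_metrics$z_peak_m)
})

test_that("a reduced thickness sweep identifies a physically sensible decay", {
  cfg <- mini_bowl_config()
  sw <- run_thickness_sweep(c(2, 3.5, 5, 6.5), config = cfg)
  expect_false(sw$degenerate)
  expect_equal(nrow(sw$samples), 4L)
  expect_false(is.unsorted(sw$samples$thickness_mm))
  expect_true(all(sw$samples$tau_percent > 0 & sw$samples$tau_percent < 100))
  expect_true(is.finite(sw$fit$r_squared))
  # decay near the Np/mm absorption coefficient of bone (0.23/mm)
  expect_gt(sw$fit$b, 0.1)
  expect_lt(sw$fit$b, 0.5)
  expect_match(sw$config_digest, "h=")
})

test_that("a sweep through water-equivalent layers is flagged as degenerate", {
  cfg <- mini_bowl_config()
  waterlike <- medium("waterlike", 1482, 998, 0)
  expect_warning(
    sw <- run_thickness_sweep(c(2, 3.5, 5), config = cfg, material = waterlike),
    "degenerate"
  )
  expect_true(sw$degenerate)
  expect_null(sw$fit)
  expect_equal(sw$samples$tau_percent, rep(100, 3), tolerance = 1e-9)
})

test_that("validation against packaged fixtures reproduces the published error bookkeeping", {
  rep <- validate_fixtures()
  phantom <- rep$per_site[rep$per_site$series == "skull14_phantom", ]
  expect_equal(phantom$site, c("S1", "S2", "S3", "S4"))
  expect_equal(round(phantom$relative_error_percent[1], 2), 6.64)
  expect_equal(round(phantom$relative_error_percent[2], 2), 4.30)
  expect_equal(phantom$relative_error_percent[3], 0.245, tolerance = 0.02)
  expect_equal(round(phantom$relative_error_percent[4], 2), 1.94)
  expect_equal(phantom$site[which.max(phantom$relative_error_percent)], "S1")

  sim <- rep$per_site[rep$per_site$series == "skull14_sim", ]
  expect_equal(round(max(sim$relative_error_percent), 2), 1.30)
  expect_equal(round(min(sim$relative_error_percent), 2), 0.13)

  # site-by-site correlations across excitation levels are exact in the
  # noise-free linear model
  expect_true(all(rep$correlations$correlation_percent > 99.99))
})

test_that("validation summary is recomputable from its per-site records", {
  rep <- validate_fixtures()
  for (s in unique(rep$summary$series)) {
    rows <- rep$per_site[rep$per_site$series == s, ]
    summ <- rep$summary[rep$summary$series == s, ]
    expect_equal(summ$max_error_percent, max(rows$relative_error_percent))
    expect_equal(summ$min_error_percent, min(rows$relative_error_percent))
    expect_equal(summ$mean_error_percent, mean(rows$relative_error_percent))
    expect_equal(summ$n_sites, nrow(rows))
  }
})

test_that("validating the model against itself gives zero error and unit correlation", {
  fit <- reference_attenuation_fit()
  model_att <- 100 - tau_model(c(3.5, 4.5, 5, 6.5), fit)
  expect_equal(relative_error(model_att, model_att), rep(0, 4))
  p <- c(0.862, 1.931, 2.138, 2.276) * tau_model(5, fit) / 100
  expect_equal(correlation(p, p), 1)
})

test_that("validation reports are byte-identical across repeated runs", {
  r1 <- validate_fixtures()
  r2 <- validate_fixtures()
  expect_identical(r1$per_site, r2$per_site)
  expect_identical(r1$summary, r2$summary)
})

test_that("skull 49 rows are informational with the published error figures", {
  rep <- validate_fixtures()
  sk49 <- rep$per_site[rep$per_site$series == "skull49_published_error", ]
  expect_equal(sk49$relative_error_percent, c(1.99, 2.44))
  expect_true(all(is.na(sk49$reference_attenuation_percent)))
  expect_equal(round(sk49$model_attenuation_percent, 2), rep(89.79, 2))
})
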