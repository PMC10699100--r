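test_that("Langmuir occupancy matches its defining values and dilution behavior", {
  expect_equal(primary_occupancy(0, 10), 0)
  expect_equal(primary_occupancy(76.9, 76.9), 0.5)
  expect_equal(primary_occupancy(5, 5), 0.5)
  # a 100-fold dilution from 5000 ng/mL with K_p = 76.9 costs 60% of signal
  drop_pct <- 100 * (1 - primary_occupancy(50, 76.9) /
                       primary_occupancy(5000, 76.9))
  expect_equal(round(drop_pct), 60)
  expect_error(primary_occupancy(-1, 10), "non-negative")
  expect_error(primary_occupancy(10, 0), "positive")
})

test_that("occupancy is monotone in concentration and affinity with range in [0,1)", {
  concs <- c(0, 1, 10, 50, 100, 1000, 5000, 1e6)
  for (K in c(5, 76.9, 500, 5000)) {
    theta <- primary_occupancy(concs, K)
    expect_true(all(diff(theta) > 0))
    expect_true(all(theta >= 0 & theta < 1))
  }
  # decreasing in K_p at fixed concentration
  Ks <- c(1, 10, 100, 1000)
  expect_true(all(diff(primary_occupancy(50, Ks)) < 0))
})

test_that("secondary detection is proportional to the secondary dilution", {
  expect_equal(secondary_response(1), 1)
  expect_equal(secondary_response(0.5), 0.5)
  expect_equal(secondary_response(0), 0)
  expect_error(secondary_response(1.2), "\\[0, 1\\]")
  expect_error(secondary_response(-0.1), "\\[0, 1\\]")
})

test_that("dilution series reproduces proportional secondary and Langmuir primary behavior", {
  ab <- antibody_model("hafull", rho = 1, K_p = 76.9)
  # 10-fold secondary dilutions give 10-fold signal steps
  tab <- simulate_dilution_series(ab, primary_concs = 5000,
                                  secondary_scales = c(1, 0.1, 0.01, 0.001))
  expect_equal(tab$signal / tab$signal[1], c(1, 0.1, 0.01, 0.001))
  # 100-fold primary dilution only loses ~60%
  tab2 <- simulate_dilution_series(ab, primary_concs = c(5000, 50),
                                   secondary_scales = 1)
  expect_equal(tab2$signal[tab2$primary_conc == 50] /
                 tab2$signal[tab2$primary_conc == 5000], 0.4,
               tolerance = 1e-3)
  # single condition at reference settings is S_max * theta
  cfg <- simulation_config()
  one <- simulate_dilution_series(ab, 5000, 1, cfg)
  expect_equal(one$signal, cfg$s_max * primary_occupancy(5000, ab$K_p))
  expect_error(simulate_dilution_series(ab, numeric(0), 1), "non-empty")
})

test_that("antibody and config constructors enforce their invariants", {
  expect_error(antibody_model("a", rho = -0.1), "non-negative")
  expect_error(antibody_model("a", rho = 1, K_p = 0), "positive")
  expect_warning(antibody_model("c", rho = 0.5, is_control = TRUE),
                 "forcing rho = 0")
  ctrl <- suppressWarnings(antibody_model("c", rho = 0.5, is_control = TRUE))
  expect_equal(ctrl$rho, 0)
  expect_error(simulation_config(transfected_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(gain_ref = -1), ">= 0")
  expect_error(simulation_config(noise_factor = -1), ">= 0")
})

test_that("noise-free symmetric channels are pixel-identical", {
  # rho = 1, equal gains, equal backgrounds, identical detection in both
  # channels: the tag image must equal the reference image everywhere
  cfg <- simulation_config(width = 128L, height = 128L, n_cells = 4L,
                           ring_radius_range = c(10, 14),
                           gain_ref = 2000, gain_tag = 2000,
                           background_ref = 100, background_tag = 100,
                           noise_factor = 0, transfected_fraction = 1,
                           primary_conc = 5000, seed = 11L)
  ab <- antibody_model("sym", rho = 1, K_p = cfg$ref_K_p)
  sim <- simulate_image_pair(cfg, ab)
  expect_identical(sim$pair$ref, sim$pair$tag)
})

test_that("noise-free images equal the affine prediction from ground truth pixelwise", {
  cfg <- simulation_config(width = 160L, height = 160L, n_cells = 5L,
                           ring_radius_range = c(10, 16), noise_factor = 0,
                           transfected_fraction = 1, seed = 21L)
  ab <- antibody_model("aff", rho = 0.37)
  sim <- simulate_image_pair(cfg, ab)
  mu <- tagquant:::expected_mean_images(sim$truth, cfg$width, cfg$height)
  expect_identical(sim$pair$ref, matrix(as.integer(round(mu$ref)),
                                        nrow = cfg$height))
  expect_identical(sim$pair$tag, matrix(as.integer(round(mu$tag)),
                                        nrow = cfg$height))
  # and the two expected fields obey the slope relation exactly
  ratio <- sim$truth$rho * (sim$truth$gain_tag * sim$truth$d_tag) /
    (sim$truth$gain_ref * sim$truth$d_ref)
  expect_equal(mu$tag,
               cfg$background_tag + ratio * (mu$ref - cfg$background_ref),
               tolerance = 1e-12)
})

test_that("a control antibody's membrane signal is indistinguishable from background", {
  cfg <- small_config(noise_factor = 4, transfected_fraction = 1, seed = 31L)
  ab <- suppressWarnings(antibody_model("ctrl", 0, is_control = TRUE))
  sim <- simulate_image_pair(cfg, ab)
  px <- unlist(sim$truth$masks[sim$truth$cells$transfected])
  vals <- sim$pair$tag[px]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - cfg$background_tag), 3 * se)
})

test_that("the same seed reproduces a bit-identical image pair", {
  cfg <- small_config(seed = 99L)
  ab <- antibody_model("det", rho = 0.8)
  a <- simulate_image_pair(cfg, ab)
  b <- simulate_image_pair(cfg, ab)
  expect_identical(a$pair$ref, b$pair$ref)
  expect_identical(a$pair$tag, b$pair$tag)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("cells that cannot fit the image raise a configuration error", {
  cfg <- simulation_config(width = 32L, height = 32L, n_cells = 1L,
                           ring_radius_range = c(20, 30), seed = 1L)
  expect_error(simulate_image_pair(cfg, antibody_model("big", 1)),
               "configuration error")
})

test_that("membrane masks lie within image bounds and ground truth predicts the slope", {
  cfg <- small_config(seed = 5L)
  sim <- simulate_image_pair(cfg, antibody_model("m", 0.5))
  npix <- cfg$width * cfg$height
  for (m in sim$truth$masks) expect_true(all(m >= 1L & m <= npix))
  d_tag <- primary_occupancy(cfg$primary_conc, 76.9) * cfg$secondary_scale
  d_ref <- primary_occupancy(cfg$ref_primary_conc, cfg$ref_K_p)
  expect_equal(expected_slope(sim$truth),
               0.5 * (cfg$gain_tag * d_tag) / (cfg$gain_ref * d_ref))
})

test_that("doubling the tag gain doubles the expected slope", {
  cfg1 <- small_config(seed = 8L)
  cfg2 <- small_config(gain_tag = 2 * cfg1$gain_tag, seed = 8L)
  ab <- antibody_model("g", 0.4)
  s1 <- expected_slope(simulate_image_pair(cfg1, ab)$truth)
  s2 <- expected_slope(simulate_image_pair(cfg2, ab)$truth)
  expect_equal(s2, 2 * s1)
})
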