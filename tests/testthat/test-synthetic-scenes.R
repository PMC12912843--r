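test_that("zero-noise, cloud-free scenes equal their truth field with nominal flags", {
  cfg <- clean_config()
  g <- generate_scene(cfg, "2020-07-15")
  w <- cfg$lake_geometry
  expect_identical(g$scene$chl[w], g$truth$true_chl[w])
  expect_true(all(g$scene$flags[w] == 0L))
  expect_true(all(is.na(g$scene$chl[!w])))
})

test_that("full cloud cover flags every water cell non-nominal", {
  cfg <- scene_config(grid_shape = c(8, 8), cloud_fraction = 1, seed = 3)
  g <- generate_scene(cfg, "2020-06-10")
  w <- cfg$lake_geometry
  expect_true(all(g$scene$flags[w] != 0L))
  expect_true(all(is.na(g$scene$chl[w])))
})

test_that("scene generation is deterministic and leaves the global RNG alone", {
  cfg <- scene_config(grid_shape = c(10, 10), seed = 99)
  set.seed(1); before <- runif(1)
  a <- generate_scene(cfg, "2021-08-01")
  b <- generate_scene(cfg, "2021-08-01")
  expect_identical(a, b)
  set.seed(1); expect_identical(runif(1), before)
  # different dates differ
  c <- generate_scene(cfg, "2021-08-02")
  expect_false(identical(a$scene$chl, c$scene$chl))
})

test_that("off-season dates are rejected unless explicitly allowed", {
  cfg <- clean_config()
  expect_error(generate_scene(cfg, "2020-01-15"), "off_season")
  expect_s3_class(generate_scene(cfg, "2020-01-15", allow_off_season = TRUE)$scene,
                  "grid_scene")
})

test_that("invalid configurations name the offending field", {
  expect_error(scene_config(chl_base = -1), "chl_base")
  expect_error(scene_config(cloud_fraction = 2), "cloud_fraction")
  expect_error(scene_config(grid_shape = c(0, 5)), "grid_shape")
  expect_error(scene_config(lake_geometry = matrix(FALSE, 20, 20)), "lake_geometry")
})

test_that("shoreline and estuary cells carry higher chlorophyll than the centre", {
  cfg <- clean_config(grid = c(15, 15))
  w <- cfg$lake_geometry
  d <- lakefcc:::shore_distance(w)
  for (date in c("2020-05-10", "2020-07-20", "2020-10-05")) {
    chl <- generate_scene(cfg, date)$truth$true_chl
    shore <- chl[w & d <= 2]
    centre <- chl[w & d >= max(d[w]) - 1]
    expect_gt(mean(shore), mean(centre))
  }
})

test_that("the seasonal chlorophyll cycle peaks in July-August", {
  cfg <- clean_config(grid = c(8, 8))
  doys <- 1:365
  lake_mean <- vapply(doys, function(d)
    mean(lakefcc:::truth_chl_field(cfg, d)[cfg$lake_geometry]), 0)
  peak_month <- as.integer(format(as.Date(which.max(lake_mean) - 1,
                                          origin = "2020-01-01"), "%m"))
  expect_true(peak_month %in% c(7, 8))
})

test_that("surface temperature stays on a smooth 0-25 degC annual curve", {
  ssts <- vapply(1:365, lakefcc:::truth_sst_value, 0)
  expect_gte(min(ssts), 0)
  expect_lte(max(ssts), 25)
  expect_lt(max(abs(diff(ssts))), 0.5)  # smooth day-to-day
})

test_that("a one-month series yields one scene per calendar day with flag tallies", {
  cfg <- scene_config(grid_shape = c(8, 8), cloud_fraction = 0.2, seed = 5)
  s <- generate_series(cfg, 2020, 6)
  expect_length(s$scenes, 30)
  expect_named(s$nominal_days, "2020-06")
  expect_true(all(s$nominal_days[["2020-06"]] <= 30))
  expect_error(generate_series(cfg, integer(0), 6), "non-empty")
  expect_error(generate_series(cfg, 2020, 3), "May-October")
})

test_that("heavy cloud makes most cells fail the five-valid-day rule", {
  cfg <- scene_config(grid_shape = c(8, 8), cloud_fraction = 0.9, seed = 7)
  s <- generate_series(cfg, 2020, 6)
  cnt <- s$nominal_days[["2020-06"]][cfg$lake_geometry]
  # binomial expectation: 30 days x 0.1 = 3 < 5 valid days
  expect_gt(mean(cnt < 5), 0.7)
})

test_that("surveys recover the true biomass: exactly at zero noise, unbiased under noise", {
  cfg <- scene_config(grid_shape = c(10, 10), seed = 21)
  sv0 <- generate_survey(cfg, 2020, true_biomass = 1e5, density_cv = 0)
  expect_equal(survey_fp(sv0)$fp, 1e5, tolerance = 1e-12)
  expect_identical(generate_survey(cfg, 2020, 1e5),
                   generate_survey(cfg, 2020, 1e5))
  expect_error(generate_survey(cfg, 2020, -5), "positive")
  recovered <- vapply(1:500, function(i)
    survey_fp(generate_survey(cfg, 2020, 1e5, seed = i, density_cv = 0.05))$fp, 0)
  expect_lt(abs(mean(recovered) / 1e5 - 1), 0.01)
})

test_that("gill-net lengths are unimodal-positive and weights follow the power law", {
  cfg <- scene_config(grid_shape = c(10, 10), seed = 2)
  sv <- generate_survey(cfg, 2022, 5e4)
  expect_true(all(sv$gillnet$length_cm > 0))
  expect_equal(sv$gillnet$weight_g, 0.01 * sv$gillnet$length_cm^3)
})
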