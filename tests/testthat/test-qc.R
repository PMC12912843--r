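test_that("the unified mask is the minimum water extent with the excluded fraction", {
  w <- matrix(TRUE, 10, 10)
  s1 <- make_scene(matrix(1, 10, 10), water = w)
  w2 <- w; w2[1, ] <- FALSE  # lose a 10-cell fringe out of 100
  s2 <- make_scene(matrix(1, 10, 10), water = w2)
  m <- build_lake_mask(list(s1, s2))
  expect_equal(m$excluded_fraction, 0.10)
  expect_equal(sum(m$water), 90)
  # identical extents exclude nothing
  expect_equal(build_lake_mask(list(s1, s1))$excluded_fraction, 0)
  expect_error(build_lake_mask(list()), "empty")
})

test_that("mask construction is idempotent on already-masked scenes", {
  cfg <- scene_config(grid_shape = c(9, 9), seed = 4)
  scenes <- generate_series(cfg, 2020, 7)$scenes
  m1 <- build_lake_mask(scenes)
  masked <- lapply(scenes, function(s) { s$water <- m1$water; s })
  m2 <- build_lake_mask(masked)
  expect_identical(m1$water, m2$water)
  expect_equal(m2$excluded_fraction, 0)
})

test_that("a shrinking-lake series excludes a few percent of ever-wet pixels", {
  cfg <- scene_config(grid_shape = c(20, 20), seed = 8)
  scenes <- generate_series(cfg, 2020, 8)$scenes
  # intermittently wet fringe: a handful of shoreline cells dry out some days
  fringe <- which(lakefcc:::shore_distance(cfg$lake_geometry) == 1 &
                    cfg$lake_geometry)[1:10]
  for (i in seq(1, length(scenes), by = 2))
    scenes[[i]]$water[fringe] <- FALSE
  frac <- build_lake_mask(scenes)$excluded_fraction
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("quality filters require nominal flag, straylight < 5% and no ice", {
  chl <- matrix(1, 3, 3)
  clean <- apply_quality_filters(make_scene(chl))
  expect_equal(attr(clean, "n_valid"), 9)
  expect_equal(clean$chl, chl)
  sl <- matrix(0, 3, 3); sl[2, 2] <- 6
  f <- apply_quality_filters(make_scene(chl, straylight = sl))
  expect_equal(attr(f, "n_valid"), 8)
  expect_true(is.na(f$chl[2, 2]))
  iced <- apply_quality_filters(make_scene(chl, ice = matrix(1L, 3, 3)))
  expect_equal(attr(iced, "n_valid"), 0)
  broken <- make_scene(chl); broken$ice <- NULL
  expect_error(apply_quality_filters(broken), "ice")
})

test_that("monthly composite enforces the minimum-valid-days rule and averages valid days", {
  w <- matrix(TRUE, 2, 2)
  mask <- build_lake_mask(list(make_scene(matrix(1, 2, 2))))
  vals <- c(1, 2, 3, 4, 6)
  scenes <- lapply(seq_along(vals), function(i) {
    fl <- matrix(0L, 2, 2)
    fl[2, 2] <- if (i == 5) 1L else 0L  # cell (2,2) gets only 4 valid days
    make_scene(matrix(vals[i], 2, 2), flags = fl,
               date = as.Date("2020-07-01") + i - 1)
  })
  cm <- monthly_composite(scenes, mask, min_valid_days = 5)
  expect_equal(cm$chl[1, 1], 3.2)
  expect_true(is.na(cm$chl[2, 2]))
  expect_equal(cm$valid_days[2, 2], 4)
  # identity: single scene at min_valid_days = 1
  one <- monthly_composite(scenes[1], mask, min_valid_days = 1)
  expect_equal(one$chl, scenes[[1]]$chl)
  # scenes from different months are rejected
  bad <- c(scenes[1], list(make_scene(matrix(1, 2, 2), date = as.Date("2020-08-01"))))
  expect_error(monthly_composite(bad, mask), "months")
})

test_that("gap filling interpolates interior gaps and respects the missing-fraction cap", {
  mask_scene <- make_scene(matrix(1, 1, 1))
  mk_comp <- function(chl, year, month) {
    cm <- monthly_composite(list(make_scene(matrix(chl, 1, 1),
                                            date = as.Date(sprintf("%d-%02d-15", year, month)))),
                            build_lake_mask(list(mask_scene)), min_valid_days = 1)
    cm
  }
  blank <- function(year, month) {
    cm <- mk_comp(1, year, month); cm$chl[] <- NA; cm$sst[] <- NA
    cm$par[] <- NA; cm$kd490[] <- NA; cm$valid_days[] <- 0L; cm
  }
  # midpoint: 10, missing, 20 -> 15 (permissive cap so the gap qualifies)
  s <- list(mk_comp(10, 2020, 5), blank(2020, 6), mk_comp(20, 2020, 7))
  filled <- gap_fill(s, max_missing_fraction = 0.5)
  expect_equal(filled[[2]]$chl[1, 1], 15)
  expect_true(filled[[2]]$filled[1, 1])
  # endpoints untouched
  expect_equal(filled[[1]]$chl[1, 1], 10)
  expect_equal(filled[[3]]$chl[1, 1], 20)
  # 2 of 12 months missing (16.7%) >= 10% cap: not filled
  s12 <- lapply(1:12, function(i) mk_comp(i, 2020 + (i - 1) %/% 6, c(5:10, 5:10)[i]))
  s12[[3]] <- blank(2020, 7); s12[[4]] <- blank(2020, 8)
  t_ord <- gap_fill(s12, max_missing_fraction = 0.10)
  expect_true(is.na(t_ord[[3]]$chl[1, 1]))
  expect_equal(attr(t_ord, "n_unfilled_cells"), 1L)
  # no gaps: unchanged
  s3 <- list(mk_comp(1, 2020, 5), mk_comp(2, 2020, 6), mk_comp(3, 2020, 7))
  expect_equal(gap_fill(s3)[[2]]$chl, s3[[2]]$chl)
  # exact for linear trends
  lin <- list(mk_comp(10, 2020, 5), blank(2020, 6), blank(2020, 7), mk_comp(40, 2020, 8))
  lf <- gap_fill(lin, max_missing_fraction = 0.6)
  expect_equal(lf[[2]]$chl[1, 1], 20)
  expect_equal(lf[[3]]$chl[1, 1], 30)
})

test_that("matchup extraction takes the box median and applies the validity rules", {
  chl <- matrix(5, 5, 5)
  sc <- make_scene(chl)
  st <- list(row = 3, col = 3, field_value = 4.8,
             field_time = "2020-07-15 10:00:00", station_id = 1)
  m <- extract_matchup(sc, st)
  expect_equal(m$satellite_value, 5)
  expect_true(m$valid)
  # 13 h offset fails the +/-12 h window
  late <- st; late$field_time <- "2020-07-16 01:00:00"
  expect_false(extract_matchup(sc, late)$valid)
  # heterogeneous 3-value box: median 2, sd/mean ~ 1.65 > 0.2 -> invalid
  chl2 <- matrix(NA_real_, 5, 5); chl2[3, 2:4] <- c(1, 2, 100)
  sc2 <- make_scene(chl2)
  m2 <- extract_matchup(sc2, st, box_half = 1)
  expect_equal(m2$satellite_value, 2)
  expect_equal(m2$box_sd_over_mean, sd(c(1, 2, 100)) / mean(c(1, 2, 100)))
  expect_false(m2$valid)
  expect_error(extract_matchup(sc, list(row = 9, col = 3, field_value = 1,
                                        field_time = "2020-07-15 10:00:00")),
               "outside")
})

test_that("reduced major axis regression recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  ident <- fit_chla_correction(data.frame(satellite_value = x, field_value = x,
                                          valid = TRUE))
  expect_equal(unname(coef(ident)), c(1, 0))
  lin <- fit_chla_correction(data.frame(satellite_value = x,
                                        field_value = 0.5 * x + 1, valid = TRUE))
  expect_equal(lin$slope, 0.5)
  expect_equal(lin$intercept, 1)
  expect_error(fit_chla_correction(data.frame(satellite_value = c(1, 1, 1),
                                              field_value = x[1:3], valid = TRUE)),
               "variance")
  expect_error(fit_chla_correction(data.frame(satellite_value = 1:2,
                                              field_value = 1:2, valid = TRUE)),
               "3 valid")
})

test_that("RMA slope recovery holds within 10% at n = 57 with 5% noise, and is axis-symmetric", {
  set.seed(57)
  sat <- runif(57, 0.5, 5)
  field <- (0.6 * sat + 0.8) * exp(rnorm(57, 0, 0.05))
  m <- fit_chla_correction(data.frame(satellite_value = sat, field_value = field,
                                      valid = TRUE))
  expect_lt(abs(m$slope / 0.6 - 1), 0.10)
  expect_lt(abs(m$intercept / 0.8 - 1), 0.10)
  # symmetry under axis exchange: slope_xy = 1 / slope_yx
  rev <- fit_chla_correction(data.frame(satellite_value = field,
                                        field_value = sat, valid = TRUE))
  expect_equal(m$slope, 1 / rev$slope)
  # applying the correction reduces the average relative error
  are <- function(mod, obs) mean(abs((mod - obs) / obs)) * 100
  expect_lt(are(predict(m, sat), field), are(sat, field))
})

test_that("the chlorophyll correction is affine with clipping at zero", {
  m <- structure(list(slope = 0.5, intercept = 1, n_fit = 5,
                      fit_method = "reduced major axis"),
                 class = "chla_correction")
  expect_equal(predict(m, 4), 3)
  neg <- structure(list(slope = 1, intercept = -10, n_fit = 5,
                        fit_method = "reduced major axis"),
                   class = "chla_correction")
  expect_equal(predict(neg, 4), 0)
  ident <- structure(list(slope = 1, intercept = 0, n_fit = 5,
                          fit_method = "reduced major axis"),
                     class = "chla_correction")
  cm <- monthly_composite(list(make_scene(matrix(2, 2, 2))),
                          build_lake_mask(list(make_scene(matrix(1, 2, 2)))),
                          min_valid_days = 1)
  expect_equal(apply_chla_correction(cm, ident)$chl, cm$chl)
})
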