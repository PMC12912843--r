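test_that("the optimal photosynthetic rate matches the published clamps and polynomial", {
  expect_equal(popt_b(-5), 1.13)
  expect_equal(popt_b(30), 4.00)
  expect_equal(popt_b(-15), 0)
  expect_equal(popt_b(10), oracle_popt(10))
  expect_equal(popt_b(10), 3.9408, tolerance = 1e-6)
  # monotone increase over the 0-15 degC range
  x <- seq(0, 15, by = 0.05)
  expect_true(all(diff(popt_b(x)) > 0))
})

test_that("clamp handoffs agree with the polynomial to within a few percent", {
  # the published constants are near-continuous, not exactly continuous:
  # the clamp values differ from the polynomial endpoint by ~2% (low) and
  # ~0.6% (high)
  expect_lt(abs(popt_b(-1 - 1e-9) - popt_b(-1)) / popt_b(-1), 0.025)
  expect_lt(abs(popt_b(28.5 + 1e-9) - popt_b(28.5)) / popt_b(28.5), 0.025)
})

test_that("KdPAR is monotone in Kd490 and the euphotic depth follows 1% light with a cap", {
  expect_equal(euphotic_depth(0.4605), log(100) / 0.4605)
  expect_equal(euphotic_depth(0.4605), 10, tolerance = 1e-3)
  expect_equal(euphotic_depth(0.05), 20)  # capped at the lakebed
  expect_error(euphotic_depth(-1), "kd_par")
  expect_error(kd_par_from_kd490(0), "kd490")
  kd <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(kd_par_from_kd490(kd)) >= 0))
  # alternative relation is honoured
  expect_equal(kd_par_from_kd490(0.5, relation = function(k) 2 * k), 1)
})

test_that("daylength follows solar geometry", {
  expect_equal(daylength(0, 100), 12, tolerance = 0.2)
  expect_equal(daylength(36.9, 80), 12, tolerance = 0.25)   # equinox
  expect_gt(daylength(36.9, 172), daylength(36.9, 355))     # solstices
  expect_error(daylength(70, 172), "polar")
})

test_that("daily VGPM reproduces a hand evaluation and its structural limits", {
  # chl=1, sst=10, PAR=41, zeu=10, dirr=12:
  # 0.66125 * popt_b(10) * 41/45.1 * 10 * 1 * 12
  expect_equal(vgpm_daily(chl = 1, sst = 10, par = 41, zeu = 10, dirr = 12),
               0.66125 * oracle_popt(10) * (41 / 45.1) * 10 * 1 * 12)
  expect_equal(vgpm_daily(chl = 1, sst = 10, par = 41, zeu = 10, dirr = 12),
               284.275, tolerance = 1e-5)
  expect_equal(vgpm_daily(chl = 0, sst = 10, par = 41, zeu = 10, dirr = 12), 0)
  expect_equal(vgpm_daily(chl = 1, sst = 10, par = 0, zeu = 10, dirr = 12), 0)
  # saturating light: E0 -> Inf approaches the light-unlimited rate
  lim <- 0.66125 * popt_b(10) * 10 * 1 * 12
  expect_equal(vgpm_daily(chl = 1, sst = 10, par = 1e9, zeu = 10, dirr = 12),
               lim, tolerance = 1e-6)
  expect_error(vgpm_daily(chl = -1, sst = 10, par = 41, zeu = 10, dirr = 12), "chl")
})

test_that("daily VGPM is linear in chlorophyll and non-negative", {
  set.seed(42)
  for (i in 1:20) {
    chl <- runif(1, 0, 10); sst <- runif(1, -3, 30)
    par <- runif(1, 0, 60); kd <- runif(1, 0.03, 1); dl <- runif(1, 8, 16)
    base <- vgpm_daily(chl, sst, par, kd490 = kd, dirr = dl)
    expect_gte(base, 0)
    expect_equal(vgpm_daily(3 * chl, sst, par, kd490 = kd, dirr = dl), 3 * base)
  }
})

test_that("monthly PP scales the daily rate by days in month and propagates gaps", {
  mask <- build_lake_mask(list(make_scene(matrix(1, 2, 2))))
  mk <- function(date) monthly_composite(
    list(make_scene(matrix(c(1, 1, 1, NA), 2, 2), date = as.Date(date))),
    mask, min_valid_days = 1)
  pp_jun <- monthly_pp(mk("2020-06-15"))  # 30 days
  pp_jul <- monthly_pp(mk("2020-07-15"))  # 31 days
  expect_equal(pp_jun$pp_monthly[1, 1], pp_jun$pp_daily[1, 1] * 30)
  expect_true(is.na(pp_jun$pp_monthly[2, 2]))
  # same inputs, 31- vs 30-day months: daylength differs, so compare the
  # per-day-normalised fields instead of raw monthlies
  expect_equal(pp_jul$pp_monthly[1, 1] / pp_jul$pp_daily[1, 1], 31)
})

test_that("pipeline monthly PP equals an independent evaluation on zero-noise truth", {
  cfg <- clean_config(grid = c(10, 10), seed = 31)
  s <- generate_series(cfg, 2020, 7)
  mask <- build_lake_mask(s$scenes)
  cm <- monthly_composite(s$scenes, mask, min_valid_days = 5)
  pp <- monthly_pp(cm, latitude_deg = cfg$latitude_deg,
                   depth_cap = cfg$lake_depth_m)
  # oracle: direct formula on the mean truth inputs of the month
  w <- mask$water
  truth_mean <- Reduce(`+`, lapply(s$truths, function(t) t$true_chl)) /
    length(s$truths)
  doys <- vapply(s$scenes, function(x) x$doy, 0L)
  sst_mean <- mean(vapply(doys, lakefcc:::truth_sst_value, 0))
  par_mean <- mean(vapply(doys, lakefcc:::truth_par_value, 0))
  dirr <- daylength(cfg$latitude_deg, as.integer(format(as.Date("2020-07-15"), "%j")))
  expected <- oracle_vgpm(truth_mean, sst_mean, par_mean,
                          0.04 + 0.02 * truth_mean, dirr) * 31
  expect_equal(pp$pp_monthly[w], expected[w], tolerance = 1e-10)
})
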