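#' Generate one synthetic satellite scene and its ground truth
#'
#' Builds a single day's co-registered rasters (chlorophyll-a, surface
#' temperature, PAR, Kd490) over the configured lake, together with the
#' noise-free truth fields.  The chlorophyll truth is a shore-distance ramp
#' plus Gaussian estuary bumps, modulated by a sinusoidal seasonal cycle
#' peaking near day-of-year 200; observed chlorophyll multiplies the truth by
#' mean-one lognormal pixel noise; cloud gaps receive a non-nominal flag.
#' Surface temperature follows a smooth 0-25 degC annual curve with additive
#' Gaussian noise.
#'
#' @param config a [scene_config()].
#' @param date the scene date (`Date` or anything `as.Date()` accepts).
#' @param allow_off_season generate outside the May-October open-water
#'   window (off-season scenes may be ice-flagged)?
#' @return A list with components `scene` (class `grid_scene`: layers `chl`,
#'   `sst`, `par`, `kd490`, matrices; `flags`, `straylight_pct`, `ice`;
#'   logical `water`) and `truth` (class `truth_record`: `true_chl`,
#'   `true_pp` in mg C m-2 day-1, `true_biomass`).
#' @examples
#' cfg <- scene_config(grid_shape = c(10, 10), noise_cv = 0, cloud_fraction = 0,
#'                     straylight_rate = 0, seed = 1)
#' sc <- generate_scene(cfg, "2020-07-15")
#' all(sc$scene$chl[cfg$lake_geometry] == sc$truth$true_chl[cfg$lake_geometry])
#' @export
generate_scene <- function(config, date, allow_off_season = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  date <- as.Date(date)
  mon <- as.integer(format(date, "%m"))
  if (!allow_off_season && (mon < 5 || mon > 10))
    stop("date ", format(date), " is outside the May-October window; ",
         "set allow_off_season = TRUE to generate it")
  doy <- as.integer(format(date, "%j"))
  water <- config$lake_geometry
  n <- length(water)
  truth_chl <- truth_chl_field(config, doy)
  truth_sst <- truth_sst_value(doy)
  truth_par <- truth_par_value(doy)

  with_seed(derive_seed(config$seed, as.integer(date)), {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow(water), ncol(water))
    chl <- truth_chl * noise
    sst <- matrix(truth_sst + rnorm(n, 0, config$sst_sd), nrow(water), ncol(water))
    cloud <- matrix(runif(n) < config$cloud_fraction, nrow(water), ncol(water))
    sl_hit <- matrix(runif(n) < config$straylight_rate, nrow(water), ncol(water))
    straylight <- matrix(runif(n, 0, 4.9), nrow(water), ncol(water))
    straylight[sl_hit] <- runif(sum(sl_hit), 5, 10)
    ice <- matrix(0L, nrow(water), ncol(water))
    if (truth_sst <= 0) ice[] <- 1L
    flags <- matrix(0L, nrow(water), ncol(water))
    flags[cloud] <- 1L
    par_l <- matrix(truth_par, nrow(water), ncol(water))
    kd490 <- kd490_from_chl(chl)
    for (l in c("chl", "sst", "par_l", "kd490", "straylight")) {
      x <- get(l); x[!water] <- NA_real_; assign(l, x)
    }
    flags[!water] <- NA_integer_
    ice[!water] <- NA_integer_
    chl[water & cloud] <- NA_real_
    sst[water & cloud] <- NA_real_
    kd490[water & cloud] <- NA_real_
    scene <- structure(list(
      date = date, doy = doy,
      chl = chl, sst = sst, par = par_l, kd490 = kd490,
      flags = flags, straylight_pct = straylight, ice = ice,
      water = water), class = "grid_scene")
    tchl <- truth_chl; tchl[!water] <- NA_real_
    truth <- structure(list(
      true_chl = tchl,
      true_pp = truth_pp_field(config, tchl, truth_sst, truth_par, doy),
      true_biomass = config$true_biomass), class = "truth_record")
    list(scene = scene, truth = truth)
  })
}

# Spatial x seasonal chlorophyll truth, mg/m3.  Shore proximity decays over
# ~3 cells; each estuary adds a Gaussian bump of 2 x chl_base at its centre.
truth_chl_field <- function(config, doy) {
  water <- config$lake_geometry
  d <- shore_distance(water)
  prox <- exp(-(d - 1) / 3)
  prox[!water] <- 0
  fld <- config$chl_base * (1 + config$chl_shore_gain * prox)
  rows <- matrix(seq_len(nrow(water)), nrow(water), ncol(water))
  cols <- matrix(seq_len(ncol(water)), nrow(water), ncol(water), byrow = TRUE)
  for (e in config$estuary_centres) {
    r2 <- (rows - e[1])^2 + (cols - e[2])^2
    fld <- fld + 2 * config$chl_base * exp(-r2 / (2 * 2^2))
  }
  season <- 1 + config$season_amplitude * cos(2 * pi * (doy - 200) / 365)
  fld * season
}

# Annual surface-temperature cycle, 0 degC (mid-winter) to 25 degC (early
# August), spatially uniform.
truth_sst_value <- function(doy) 12.5 + 12.5 * cos(2 * pi * (doy - 212) / 365)

# Clear-sky daily PAR cycle, mol quanta m-2 day-1, peaking at the solstice.
truth_par_value <- function(doy) 30 + 28 * cos(2 * pi * (doy - 172) / 365)

# Bio-optical tie between chlorophyll and Kd490 used by the generator.
kd490_from_chl <- function(chl) 0.04 + 0.02 * chl

# Daily truth primary production via the same physical forward model the
# pipeline uses (VGPM), from noise-free inputs.
truth_pp_field <- function(config, tchl, tsst, tpar, doy) {
  kd <- kd490_from_chl(tchl)
  zeu <- euphotic_depth(kd_par_from_kd490(kd), depth_cap = config$lake_depth_m)
  dl <- daylength(config$latitude_deg, doy)
  vgpm_daily(chl = tchl, sst = tsst, par = tpar, zeu = zeu, dirr = dl)
}

#' Generate a multi-year, multi-month series of synthetic scenes
#'
#' One scene per calendar day of each requested open-water month.  Also
#' tallies, per cell and month, the number of nominal-flag days so the
#' minimum-valid-days compositing rule can be exercised.
#'
#' @param config a [scene_config()].
#' @param years integer vector of years.
#' @param months integer vector within 5:10 (May-October).
#' @return A list of class `scene_series`: `scenes` and `truths` (parallel
#'   lists), `index` (data.frame of year/month/day/date), and `nominal_days`
#'   (named list, one count matrix per "year-month").
#' @examples
#' s <- generate_series(scene_config(grid_shape = c(8, 8), seed = 2), 2020, 7)
#' length(s$scenes)  # 31 daily scenes
#' @export
generate_series <- function(config, years, months = 5:10) {
  stopifnot(inherits(config, "scene_config"))
  if (length(years) == 0 || length(months) == 0)
    stop("'years' and 'months' must be non-empty")
  if (!all(months %in% 5:10))
    stop("'months' must lie within the May-October open-water window (5:10)")
  scenes <- list(); truths <- list()
  idx <- list()
  nominal <- list()
  k <- 0L
  for (y in sort(unique(years))) for (m in sort(unique(months))) {
    nd <- days_in_month(y, m)
    cnt <- matrix(0L, config$grid_shape[1], config$grid_shape[2])
    for (d in seq_len(nd)) {
      k <- k + 1L
      date <- as.Date(sprintf("%04d-%02d-%02d", y, m, d))
      g <- generate_scene(config, date)
      scenes[[k]] <- g$scene
      truths[[k]] <- g$truth
      idx[[k]] <- data.frame(year = y, month = m, day = d, date = date)
      ok <- g$scene$flags == 0L & !is.na(g$scene$flags)
      cnt <- cnt + ifelse(ok, 1L, 0L)
    }
    nominal[[sprintf("%04d-%02d", y, m)]] <- cnt
  }
  structure(list(scenes = scenes, truths = truths,
                 index = do.call(rbind, idx), nominal_days = nominal),
            class = "scene_series")
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%04d-01-01", year + 1))
         else as.Date(sprintf("%04d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}

#' Generate a synthetic hydroacoustic + gill-net survey
#'
#' Simulates an August lake-wide survey: equal-volume transect segments whose
#' acoustic densities carry mean-one lognormal noise around the density
#' implied by the requested true stock, and a gill-net sample whose lengths
#' are drawn from a unimodal (truncated normal) distribution with weights
#' following a length-weight power law `W = a * L^b`.  In the zero-noise
#' limit the implied biomass (mean density x mean weight x lake volume x
#' 1e-6) equals `true_biomass` exactly.
#'
#' @param config a [scene_config()] (supplies lake area, depth and seed).
#' @param year survey year (used only to key the derived seed).
#' @param true_biomass true stock, tonnes; must be positive.
#' @param seed optional explicit seed overriding the config-derived one.
#' @param n_segments number of transect segments.
#' @param n_fish gill-net sample size.
#' @param density_cv coefficient of variation of segment-density noise.
#' @param length_mean,length_sd parameters (cm) of the length distribution.
#' @param lw_a,lw_b length-weight power-law coefficients (g, cm).
#' @return A list of class `lake_survey`: `acoustic` (data.frame
#'   segment_id, density_ind_per_m3, segment_volume_m3), `gillnet`
#'   (data.frame fish_id, length_cm, weight_g), `lake_volume_m3`, `year`.
#' @examples
#' cfg <- scene_config(grid_shape = c(10, 10), seed = 3)
#' sv <- generate_survey(cfg, 2024, true_biomass = 1e5, density_cv = 0)
#' fish_population(volume_weighted_density(sv$acoustic),
#'                 mean_weight(sv$gillnet), sv$lake_volume_m3)$fp
#' @export
generate_survey <- function(config, year, true_biomass, seed = NULL,
                            n_segments = 40, n_fish = 200,
                            density_cv = 0.05,
                            length_mean = 24, length_sd = 4,
                            lw_a = 0.01, lw_b = 3) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.numeric(true_biomass) || true_biomass <= 0)
    stop("'true_biomass' must be positive (tonnes)")
  seed <- seed %||% derive_seed(config$seed, 37L * as.integer(year) + 5L)
  lake_volume <- sum(config$lake_geometry) * 1e6 * config$lake_depth_m
  with_seed(seed, {
    len <- rnorm(n_fish, length_mean, length_sd)
    while (any(len <= 1)) len[len <= 1] <- rnorm(sum(len <= 1), length_mean, length_sd)
    wt <- lw_a * len^lw_b
    target_density <- true_biomass * 1e6 / (mean(wt) * lake_volume)
    sdlog <- sqrt(log(1 + density_cv^2))
    # mean-one lognormal noise: unbiased per draw, exact when density_cv = 0
    dens <- target_density * rlnorm(n_segments, -sdlog^2 / 2, sdlog)
    structure(list(
      acoustic = data.frame(
        segment_id = seq_len(n_segments),
        density_ind_per_m3 = dens,
        segment_volume_m3 = rep(lake_volume / n_segments, n_segments)),
      gillnet = data.frame(fish_id = seq_len(n_fish),
                           length_cm = len, weight_g = wt),
      lake_volume_m3 = lake_volume,
      year = year), class = "lake_survey")
  })
}
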