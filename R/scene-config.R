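#' Configuration for the synthetic lake-scene generator
#'
#' Bundles everything the scene generator needs: the grid, the lake geometry,
#' the spatial and seasonal structure of the chlorophyll field, the noise and
#' cloud model, and the random seed.  Cells are 1 km x 1 km.
#'
#' The default geometry is an elliptical lake inscribed in the grid with two
#' estuary hotspots on the northwestern shore, mimicking a large
#' tributary-fed alpine lake whose chlorophyll is shore-high / centre-low
#' with a mid-summer seasonal peak.
#'
#' @param grid_shape integer vector `c(rows, cols)`; each cell is 1 km2.
#' @param lake_geometry logical matrix of water cells (`NULL` for the default
#'   inscribed ellipse).
#' @param estuary_centres list of `c(row, col)` estuary hotspot positions
#'   (`NULL` places two on the northwestern shore).
#' @param season_amplitude dimensionless amplitude of the seasonal
#'   chlorophyll cycle (peaking around day-of-year 200).
#' @param chl_base baseline open-water chlorophyll-a, mg/m3.
#' @param chl_shore_gain dimensionless multiplier controlling how much higher
#'   shoreline chlorophyll is than the lake centre.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   pixel noise applied to chlorophyll.
#' @param cloud_fraction per-pixel-per-day probability of a cloud/flag gap.
#' @param straylight_rate fraction of water cells carrying a straylight risk
#'   of at least 5\% on any given day.
#' @param sst_sd standard deviation (deg C) of additive Gaussian noise on
#'   surface temperature.
#' @param latitude_deg latitude used for daylength and PAR geometry.
#' @param lake_depth_m constant lake depth, m; also caps the euphotic depth.
#' @param true_biomass reference fish stock (tonnes) carried through to truth
#'   records, or `NA` when no stock is being simulated.
#' @param seed integer random seed; all generator randomness derives from it.
#'
#' @return An object of class `scene_config` (a validated list).
#' @examples
#' cfg <- scene_config(grid_shape = c(12, 12), seed = 7)
#' sum(cfg$lake_geometry)  # number of water cells
#' @export
scene_config <- function(grid_shape = c(20, 20),
                         lake_geometry = NULL,
                         estuary_centres = NULL,
                         season_amplitude = 0.4,
                         chl_base = 0.8,
                         chl_shore_gain = 1.5,
                         noise_cv = 0.25,
                         cloud_fraction = 0.15,
                         straylight_rate = 0.02,
                         sst_sd = 0.3,
                         latitude_deg = 36.9,
                         lake_depth_m = 20,
                         true_biomass = NA_real_,
                         seed = 1L) {
  if (length(grid_shape) != 2 || any(grid_shape < 1) ||
      any(grid_shape != round(grid_shape)))
    stop("invalid scene_config: 'grid_shape' must be two positive integers")
  grid_shape <- as.integer(grid_shape)
  if (is.null(lake_geometry))
    lake_geometry <- default_lake_geometry(grid_shape)
  if (!is.matrix(lake_geometry) || !is.logical(lake_geometry) ||
      !all(dim(lake_geometry) == grid_shape))
    stop("invalid scene_config: 'lake_geometry' must be a logical matrix of dim grid_shape")
  if (!any(lake_geometry))
    stop("invalid scene_config: 'lake_geometry' has no water cells")
  if (is.null(estuary_centres))
    estuary_centres <- default_estuaries(lake_geometry)
  if (!is.list(estuary_centres) ||
      !all(vapply(estuary_centres, length, 0L) == 2))
    stop("invalid scene_config: 'estuary_centres' must be a list of (row, col) pairs")
  if (!is.numeric(chl_base) || chl_base <= 0)
    stop("invalid scene_config: 'chl_base' must be > 0")
  if (!is.numeric(cloud_fraction) || cloud_fraction < 0 || cloud_fraction > 1)
    stop("invalid scene_config: 'cloud_fraction' must be in [0, 1]")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("invalid scene_config: 'noise_cv' must be >= 0")
  if (!is.numeric(straylight_rate) || straylight_rate < 0 || straylight_rate > 1)
    stop("invalid scene_config: 'straylight_rate' must be in [0, 1]")
  if (!is.numeric(season_amplitude) || season_amplitude < 0 || season_amplitude >= 1)
    stop("invalid scene_config: 'season_amplitude' must be in [0, 1)")
  if (!is.numeric(latitude_deg) || abs(latitude_deg) >= 66.5)
    stop("invalid scene_config: 'latitude_deg' must be sub-polar")
  if (!is.numeric(lake_depth_m) || lake_depth_m <= 0)
    stop("invalid scene_config: 'lake_depth_m' must be > 0")
  structure(list(
    grid_shape = grid_shape,
    lake_geometry = lake_geometry,
    estuary_centres = lapply(estuary_centres, as.integer),
    season_amplitude = season_amplitude,
    chl_base = chl_base,
    chl_shore_gain = chl_shore_gain,
    noise_cv = noise_cv,
    cloud_fraction = cloud_fraction,
    straylight_rate = straylight_rate,
    sst_sd = sst_sd,
    latitude_deg = latitude_deg,
    lake_depth_m = lake_depth_m,
    true_biomass = true_biomass,
    seed = as.integer(seed)
  ), class = "scene_config")
}

# Elliptical lake inscribed in the grid, one dry ring of cells around it.
default_lake_geometry <- function(grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  a <- max(nr / 2 - 1, 0.6); b <- max(nc / 2 - 1, 0.6)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rows - r0) / a)^2 + ((cols - c0) / b)^2 <= 1
}

# Two estuaries on the northwestern (low row / low col) shore.
default_estuaries <- function(water) {
  shore <- which(shore_distance(water) <= 1.5 & water, arr.ind = TRUE)
  if (nrow(shore) == 0) shore <- which(water, arr.ind = TRUE)
  nw <- shore[order(shore[, 1] + shore[, 2]), , drop = FALSE]
  k <- min(2L, nrow(nw))
  lapply(seq_len(k), function(i) as.integer(nw[i, ]))
}

# Distance (in cells) from each cell to the nearest non-water cell or grid
# edge; 0 on land.  Brute-force scan: grids here are small.
shore_distance <- function(water) {
  nr <- nrow(water); nc <- ncol(water)
  land <- which(!water, arr.ind = TRUE)
  # grid border counts as shoreline even if the lake touches it
  d <- matrix(0, nr, nc)
  wi <- which(water, arr.ind = TRUE)
  for (k in seq_len(nrow(wi))) {
    r <- wi[k, 1]; c <- wi[k, 2]
    dedge <- min(r, c, nr + 1 - r, nc + 1 - c)
    if (nrow(land) > 0) {
      dl <- sqrt(min((land[, 1] - r)^2 + (land[, 2] - c)^2))
      d[r, c] <- min(dl, dedge)
    } else d[r, c] <- dedge
  }
  d
}
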