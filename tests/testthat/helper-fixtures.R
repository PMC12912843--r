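# Shared fixtures: small configs and hand-buildable scenes.

# noise-free, gap-free configuration for oracle-equivalence tests
clean_config <- function(grid = c(10, 10), seed = 11, ...) {
  scene_config(grid_shape = grid, noise_cv = 0, cloud_fraction = 0,
               straylight_rate = 0, sst_sd = 0, seed = seed, ...)
}

# build a grid_scene by hand from layer matrices (all-water by default)
make_scene <- function(chl, sst = NULL, par = NULL, kd490 = NULL,
                       flags = NULL, straylight = NULL, ice = NULL,
                       water = NULL, date = as.Date("2020-07-15")) {
  dims <- dim(chl)
  mk <- function(x, fill) if (is.null(x)) matrix(fill, dims[1], dims[2]) else x
  structure(list(
    date = date, doy = as.integer(format(date, "%j")),
    chl = chl, sst = mk(sst, 15), par = mk(par, 45), kd490 = mk(kd490, 0.1),
    flags = mk(flags, 0L), straylight_pct = mk(straylight, 0),
    ice = mk(ice, 0L), water = mk(water, TRUE)), class = "grid_scene")
}

# independent transcription of the optimal-rate polynomial, used as the
# oracle against the package implementation
oracle_popt <- function(t)
  1.2956 + 2.749e-1 * t + 6.17e-2 * t^2 - 2.05e-2 * t^3 + 2.462e-3 * t^4 -
  1.348e-4 * t^5 + 3.4132e-6 * t^6 - 3.27e-8 * t^7

# independent VGPM evaluation for oracle-equivalence tests
oracle_vgpm <- function(chl, sst, par, kd490, dirr, depth = 20) {
  kd_par <- pmax(0.0665 + 0.874 * kd490 - 0.00121 / kd490, 1e-4)
  zeu <- pmin(log(100) / kd_par, depth)
  0.66125 * oracle_popt(sst) * par / (par + 4.1) * zeu * chl * dirr
}

# the published 2002-2024 annual series bundled with the package
annual_series <- function() qinghai_lake_series()
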