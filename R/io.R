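#' The published Qinghai Lake annual assessment series (2002-2024)
#'
#' Annual fish population biomass (hydroacoustic + gill-net, August
#' surveys), gross annual fish potential production and the reported
#' lake-wide mean carrying-capacity index for Qinghai Lake, 2002-2024.
#' Shipped as package data so the index, reporting and sensitivity stages
#' can be driven by a real series without the raster stages ("bypass mode").
#'
#' @return data.frame with columns `year`, `fp_t`, `fpp_t` (tonnes) and
#'   `fcci` (the reported index, 4 decimals).
#' @examples
#' qs <- qinghai_lake_series()
#' range(qs$fp_t)  # 2592 .. 127500 tonnes
#' @export
qinghai_lake_series <- function() {
  read.csv(system.file("extdata", "qinghai_annual_series.csv",
                       package = "lakefcc"))
}

#' Write / read a scene as a long-format CSV table
#'
#' Plain-text interchange for `grid_scene` objects: one row per cell with
#' all layers as columns.  Round-trips exactly at full double precision.
#'
#' @param scene a `grid_scene`.
#' @param path output file.
#' @return `write_scene_csv` invisibly returns `path`; `read_scene_csv`
#'   returns the reconstructed `grid_scene`.
#' @export
write_scene_csv <- function(scene, path) {
  dims <- dim(scene$water)
  df <- data.frame(
    date = format(scene$date), row = as.vector(row(scene$water)),
    col = as.vector(col(scene$water)),
    chl = as.vector(scene$chl), sst = as.vector(scene$sst),
    par = as.vector(scene$par), kd490 = as.vector(scene$kd490),
    flags = as.vector(scene$flags),
    straylight_pct = as.vector(scene$straylight_pct),
    ice = as.vector(scene$ice), water = as.vector(scene$water))
  attr(df, "dims") <- dims
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  df <- read.csv(path)
  nr <- max(df$row); nc <- max(df$col)
  shape <- function(x, mode = "numeric") {
    m <- matrix(vector(mode, nr * nc), nr, nc)
    m[cbind(df$row, df$col)] <- x
    m
  }
  structure(list(
    date = as.Date(df$date[1]),
    doy = as.integer(format(as.Date(df$date[1]), "%j")),
    chl = shape(df$chl), sst = shape(df$sst), par = shape(df$par),
    kd490 = shape(df$kd490), flags = shape(as.integer(df$flags), "integer"),
    straylight_pct = shape(df$straylight_pct),
    ice = shape(as.integer(df$ice), "integer"),
    water = shape(df$water, "logical")), class = "grid_scene")
}

#' Write a survey to a pair of CSV tables
#'
#' @param survey a `lake_survey`.
#' @param dir output directory (created if needed); files
#'   `acoustic_<year>.csv` and `gillnet_<year>.csv`.
#' @return Invisibly, the two paths.
#' @export
write_survey_csv <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, sprintf("acoustic_%s.csv", survey$year))
  pg <- file.path(dir, sprintf("gillnet_%s.csv", survey$year))
  write.csv(survey$acoustic, pa, row.names = FALSE)
  write.csv(survey$gillnet, pg, row.names = FALSE)
  invisible(c(pa, pg))
}

#' Write an assessment table to CSV
#'
#' Columns year, fp_t, fpp_t, fcci (4 decimals), status.
#'
#' @param assessment an [fcci_assessment()].
#' @param path output file.
#' @export
write_assessment_csv <- function(assessment, path) {
  df <- as.data.frame(assessment)
  df$fcci <- round(df$fcci, 4)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
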