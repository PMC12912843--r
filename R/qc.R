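#' Build the unified minimum-extent lake mask
#'
#' A cell counts as water only if it is water in every input scene, so the
#' analysis never includes intermittently wet fringe pixels.  The fraction of
#' ever-wet cells excluded by this conservative rule is reported.
#'
#' @param scenes non-empty list of `grid_scene` objects.
#' @return An object of class `lake_mask`: `water` (logical matrix) and
#'   `excluded_fraction`.
#' @export
build_lake_mask <- function(scenes) {
  if (length(scenes) == 0) stop("'scenes' is empty: cannot build a lake mask")
  waters <- lapply(scenes, function(s) s$water)
  minimum <- Reduce(`&`, waters)
  ever <- Reduce(`|`, waters)
  structure(list(water = minimum,
                 excluded_fraction = 1 - sum(minimum) / sum(ever)),
            class = "lake_mask")
}

#' Apply per-pixel quality filters to a scene
#'
#' A cell is valid only when its retrieval flag is nominal (0), straylight
#' risk is below 5\% and there is no ice.  Data layers on failing cells are
#' set to missing; the count of valid water cells is attached as attribute
#' `n_valid`.
#'
#' @param scene a `grid_scene`.
#' @param straylight_max straylight risk threshold, percent.
#' @return The filtered `grid_scene`.
#' @export
apply_quality_filters <- function(scene, straylight_max = 5) {
  for (l in c("flags", "straylight_pct", "ice"))
    if (is.null(scene[[l]])) stop("scene is missing quality layer '", l, "'")
  ok <- scene$water &
    !is.na(scene$flags) & scene$flags == 0L &
    !is.na(scene$straylight_pct) & scene$straylight_pct < straylight_max &
    !is.na(scene$ice) & scene$ice == 0L
  for (l in c("chl", "sst", "par", "kd490")) scene[[l]][!ok] <- NA_real_
  attr(scene, "n_valid") <- sum(ok)
  scene
}

#' Monthly composite with a minimum-valid-days rule
#'
#' Quality-filters every scene, then averages each cell over its valid days.
#' Cells observed on fewer than `min_valid_days` days in the month are left
#' missing; `valid_days` records the per-cell count.
#'
#' @param scenes list of `grid_scene` objects, all from one calendar month.
#' @param mask a [build_lake_mask()] result.
#' @param min_valid_days minimum number of valid days per cell (default 5).
#' @param stat `"mean"` (default) or `"median"` compositing statistic.
#' @return An object of class `monthly_composite`: `year`, `month`,
#'   layer matrices `chl`/`sst`/`par`/`kd490`, integer `valid_days`,
#'   logical `filled` (all `FALSE` here; see [gap_fill()]).
#' @export
monthly_composite <- function(scenes, mask, min_valid_days = 5, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(scenes) == 0) stop("'scenes' is empty")
  ym <- unique(vapply(scenes, function(s) format(s$date, "%Y-%m"), ""))
  if (length(ym) != 1)
    stop("scenes span several calendar months: ", paste(ym, collapse = ", "))
  water <- mask$water
  filtered <- lapply(scenes, apply_quality_filters)
  agg <- if (stat == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) median(x, na.rm = TRUE)
  layer_stack <- function(l) {
    arr <- vapply(filtered, function(s) s[[l]], water * 1)
    dim(arr) <- c(dim(water), length(filtered))
    arr
  }
  chl_arr <- layer_stack("chl")
  valid_days <- apply(!is.na(chl_arr), c(1, 2), sum)
  valid_days[!water] <- 0L
  keep <- valid_days >= min_valid_days & water
  comp <- list(year = as.integer(substr(ym, 1, 4)),
               month = as.integer(substr(ym, 6, 7)))
  for (l in c("chl", "sst", "par", "kd490")) {
    m <- apply(layer_stack(l), c(1, 2), agg)
    m[!keep] <- NA_real_
    m[is.nan(m)] <- NA_real_
    comp[[l]] <- m
  }
  comp$valid_days <- valid_days
  comp$filled <- matrix(FALSE, nrow(water), ncol(water))
  structure(comp, class = "monthly_composite")
}

#' Fill interior temporal gaps in a composite series by linear interpolation
#'
#' For each cell, months with a missing composite are filled by linear
#' interpolation in time provided the cell's missing-month fraction is below
#' `max_missing_fraction`; cells gappier than that are left missing and
#' counted.  Leading and trailing gaps are never extrapolated.  Filled cells
#' are flagged `filled = TRUE`.
#'
#' @param series time-ordered list of `monthly_composite` objects.
#' @param max_missing_fraction per-cell missing-month fraction above which a
#'   cell is not filled (default 0.10).
#' @return The series with gaps filled; attribute `n_unfilled_cells` counts
#'   cells left gappy.
#' @export
gap_fill <- function(series, max_missing_fraction = 0.10) {
  if (length(series) < 2) return(series)
  t_idx <- vapply(series, function(cm) cm$year * 12 + cm$month, 0)
  if (is.unsorted(t_idx, strictly = TRUE))
    stop("'series' must be strictly time-ordered")
  nt <- length(series)
  dims <- dim(series[[1]]$chl)
  n_unfilled <- 0L
  for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
    obs <- vapply(series, function(cm) cm$chl[r, c], 0)
    miss <- is.na(obs)
    if (!any(miss) || all(miss)) next
    if (mean(miss) >= max_missing_fraction) { n_unfilled <- n_unfilled + 1L; next }
    known <- which(!miss)
    interior <- which(miss & seq_len(nt) > min(known) & seq_len(nt) < max(known))
    if (length(interior) == 0) next
    for (l in c("chl", "sst", "par", "kd490")) {
      y <- vapply(series, function(cm) cm[[l]][r, c], 0)
      ok <- which(!is.na(y))
      if (length(ok) < 2) next
      fill <- approx(t_idx[ok], y[ok], xout = t_idx[interior], rule = 1)$y
      for (i in seq_along(interior))
        series[[interior[i]]][[l]][r, c] <- fill[i]
    }
    for (i in interior) series[[i]]$filled[r, c] <- TRUE
  }
  attr(series, "n_unfilled_cells") <- n_unfilled
  series
}

#' Extract a satellite-field matchup at a station
#'
#' Takes the median of the chosen variable over a pixel box centred on the
#' station and pairs it with the field measurement.  The pair is valid when
#' the satellite-field time offset is within +/-12 h and the box standard
#' deviation is below 20\% of the box mean.
#'
#' @param scene a `grid_scene` (satellite pass assumed at 12:00 local).
#' @param station list with `row`, `col`, `field_value`, `field_time`
#'   (POSIXct or anything `as.POSIXct()` accepts), optional `station_id`.
#' @param variable one of `"chl"`, `"sst"`, `"par"`, `"kd490"`.
#' @param box_half half-width of the pixel box (0 = single 1 km cell,
#'   1 = 3x3).
#' @param max_offset_h,max_sd_over_mean validity thresholds.
#' @return A one-row data.frame of class `matchup_pair` with columns
#'   station_id, variable, satellite_value, field_value, time_offset_h,
#'   box_sd_over_mean, valid.
#' @export
extract_matchup <- function(scene, station, variable = "chl", box_half = 0,
                            max_offset_h = 12, max_sd_over_mean = 0.20) {
  stopifnot(variable %in% c("chl", "sst", "par", "kd490"))
  r <- station$row; c <- station$col
  dims <- dim(scene$water)
  if (r < 1 || c < 1 || r > dims[1] || c > dims[2])
    stop("station (", r, ",", c, ") lies outside the ", dims[1], "x", dims[2], " grid")
  rows <- max(1, r - box_half):min(dims[1], r + box_half)
  cols <- max(1, c - box_half):min(dims[2], c + box_half)
  box <- scene[[variable]][rows, cols]
  box <- box[!is.na(box)]
  sat <- if (length(box)) median(box) else NA_real_
  sdm <- if (length(box) > 1) sd(box) / mean(box) else 0
  pass_time <- as.POSIXct(paste(format(scene$date), "12:00:00"), tz = "UTC")
  offset <- as.numeric(difftime(as.POSIXct(station$field_time, tz = "UTC"),
                                pass_time, units = "hours"))
  out <- data.frame(
    station_id = station$station_id %||% NA_integer_,
    variable = variable,
    satellite_value = sat,
    field_value = station$field_value,
    time_offset_h = offset,
    box_sd_over_mean = sdm,
    valid = !is.na(sat) && abs(offset) <= max_offset_h && sdm < max_sd_over_mean)
  class(out) <- c("matchup_pair", class(out))
  out
}

#' Fit a type II (reduced major axis) chlorophyll correction
#'
#' Regresses field chlorophyll on satellite chlorophyll by reduced major
#' axis, the symmetric line fit appropriate when both coordinates carry
#' error: slope = sign(r) * sd(field) / sd(satellite), intercept through the
#' means.  Only matchups flagged valid enter the fit.
#'
#' @param matchups data.frame with columns `satellite_value`, `field_value`
#'   and `valid` (e.g. rbind-ed [extract_matchup()] rows).
#' @return An object of class `chla_correction` with `slope`, `intercept`,
#'   `n_fit`, `fit_method`; supports [coef()] and [predict()].
#' @export
fit_chla_correction <- function(matchups) {
  m <- matchups[matchups$valid & !is.na(matchups$satellite_value) &
                  !is.na(matchups$field_value), , drop = FALSE]
  if (nrow(m) < 3) stop("need >= 3 valid matchups, got ", nrow(m))
  x <- m$satellite_value; y <- m$field_value
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in matchup values: RMA slope undefined")
  slope <- sign(cor(x, y)) * sd(y) / sd(x)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 n_fit = nrow(m),
                 fit_method = "reduced major axis"),
            class = "chla_correction")
}

#' @export
coef.chla_correction <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' @export
predict.chla_correction <- function(object, newdata, ...) {
  out <- object$slope * newdata + object$intercept
  out[!is.na(out) & out < 0] <- 0
  out
}

#' @export
print.chla_correction <- function(x, ...) {
  cat("Chlorophyll-a correction (", x$fit_method, ", n = ", x$n_fit, ")\n",
      sep = "")
  cat(sprintf("  chl' = %.4f * chl + %.4f (clipped at 0)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Apply a fitted chlorophyll correction
#'
#' @param composite a `monthly_composite`, matrix or numeric vector.
#' @param model a [fit_chla_correction()] result.
#' @return Same shape as `composite`, with chlorophyll mapped through
#'   `slope * chl + intercept` and clipped at zero.
#' @export
apply_chla_correction <- function(composite, model) {
  stopifnot(inherits(model, "chla_correction"))
  if (inherits(composite, "monthly_composite")) {
    composite$chl <- predict(model, composite$chl)
    composite
  } else predict(model, composite)
}
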