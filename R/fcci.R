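#' Management thresholds for the carrying-capacity index
#'
#' The strictly increasing ladder used to classify FCCI values:
#' below `underutilised` (0.3) the food base is underused; above
#' `high_pressure` (0.5) food demand pressure is high; `benchmark` (0.6) is
#' the level above which fisheries have frequently become overexploited;
#' `max_sustainable` (1.0) is the theoretical maximum sustainable yield.
#' Comparisons are strict in the direction printed (`> 0.5`, `< 0.3`), so a
#' boundary value falls to the lower-severity class.
#'
#' @param underutilised,high_pressure,benchmark,max_sustainable thresholds.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(underutilised = 0.3, high_pressure = 0.5,
                             benchmark = 0.6, max_sustainable = 1.0) {
  v <- c(underutilised, high_pressure, benchmark, max_sustainable)
  if (any(diff(v) <= 0)) stop("thresholds must be strictly increasing")
  structure(list(underutilised = underutilised, high_pressure = high_pressure,
                 benchmark = benchmark, max_sustainable = max_sustainable),
            class = "threshold_config")
}

# Zone label for an FCCI value (vectorised); strict inequalities so exact
# boundary values take the lower-severity label.
fcci_zone <- function(fcci, thresholds = threshold_config()) {
  t <- thresholds
  out <- rep(NA_character_, length(fcci))
  out[!is.na(fcci)] <- "moderate"
  out[fcci < t$underutilised] <- "underutilised"
  out[fcci > t$high_pressure] <- "high_pressure"
  out[fcci > t$benchmark] <- "over_benchmark"
  out[fcci > t$max_sustainable] <- "overexploited"
  out
}

fcci_zone_levels <- c("underutilised", "moderate", "high_pressure",
                      "over_benchmark", "overexploited")

#' Annual fish carrying capacity index
#'
#' `FCCI = FP / Gross Annual FPP`: the ratio of the observed fish stock to
#' the fish production the year's primary production could sustain.  A value
#' at or below 1 means the food energy supply exceeds the stock's demand.
#'
#' @param fp fish population biomass, tonnes (>= 0).
#' @param gross_annual_fpp gross annual fish potential production, tonnes
#'   (> 0; the index is undefined at zero).
#' @param year optional year label.
#' @param thresholds a [threshold_config()].
#' @return An object of class `fcci_record`: `year`, `fp`,
#'   `gross_annual_fpp`, `fcci`, `status`.
#' @examples
#' fcci_annual(2592, 173957)$fcci  # 0.0149
#' @export
fcci_annual <- function(fp, gross_annual_fpp, year = NA_integer_,
                        thresholds = threshold_config()) {
  if (gross_annual_fpp <= 0)
    stop("'gross_annual_fpp' must be > 0: FCCI undefined")
  if (fp < 0) stop("'fp' must be >= 0")
  fcci <- fp / gross_annual_fpp
  status <- if (fcci == thresholds$max_sustainable) "at_theoretical_maximum"
            else fcci_zone(fcci, thresholds)
  structure(list(year = year, fp = fp, gross_annual_fpp = gross_annual_fpp,
                 fcci = fcci, status = status), class = "fcci_record")
}

#' @export
print.fcci_record <- function(x, ...) {
  cat(sprintf("FCCI%s = %.4f (FP %.0f t / FPP %.0f t) [%s]\n",
              if (is.na(x$year)) "" else paste0(" ", x$year),
              x$fcci, x$fp, x$gross_annual_fpp, x$status))
  invisible(x)
}

#' Multi-year carrying-capacity assessment
#'
#' Builds the annual assessment table (year, FP, gross annual FPP, FCCI,
#' status) from parallel series.  This is also the "bypass" entry point: an
#' externally supplied FP/FPP table (e.g. a published series) can be
#' assessed without the raster stages.
#'
#' @param fp fish population biomass, tonnes (vector).
#' @param gross_annual_fpp gross annual FPP, tonnes (vector, same length).
#' @param years year labels (defaults to 1..n).
#' @param thresholds a [threshold_config()].
#' @return An object of class `fcci_assessment`: a data.frame with columns
#'   `year`, `fp_t`, `fpp_t`, `fcci`, `status`, with the thresholds attached
#'   as an attribute.
#' @examples
#' a <- fcci_assessment(c(2592, 127500), c(173957, 244581), c(2002, 2024))
#' a$fcci
#' @export
fcci_assessment <- function(fp, gross_annual_fpp, years = seq_along(fp),
                            thresholds = threshold_config()) {
  if (length(fp) != length(gross_annual_fpp) || length(fp) != length(years))
    stop("'fp', 'gross_annual_fpp' and 'years' must have equal length")
  if (length(fp) == 0) stop("empty series")
  if (any(gross_annual_fpp <= 0)) stop("'gross_annual_fpp' must be > 0")
  if (any(fp < 0)) stop("'fp' must be >= 0")
  fcci <- fp / gross_annual_fpp
  out <- data.frame(year = years, fp_t = fp, fpp_t = gross_annual_fpp,
                    fcci = fcci, status = fcci_zone(fcci, thresholds))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("fcci_assessment", "data.frame")
  out
}

#' @export
print.fcci_assessment <- function(x, digits = 4, ...) {
  cat("Fish carrying-capacity assessment (", nrow(x), " years)\n", sep = "")
  df <- as.data.frame(x)
  df$fcci <- sprintf(paste0("%.", digits, "f"), df$fcci)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise an assessment: maxima, threshold exceedances, trend
#'
#' @param object an [fcci_assessment()].
#' @param ... unused.
#' @return A list of class `summary.fcci_assessment` with `max_fcci`,
#'   `max_year`, `years_over` (counts over each threshold) and `trend`
#'   (`"increasing"`, `"decreasing"`, `"flat"` or `"n/a"`).
#' @export
summary.fcci_assessment <- function(object, ...) {
  t <- attr(object, "thresholds")
  trend <- if (nrow(object) < 2) "n/a"
  else if (max(object$fcci) - min(object$fcci) < 1e-12) "flat"
  else {
    sl <- coef(stats::lm(fcci ~ year, data = object))[2]
    if (sl > 0) "increasing" else if (sl < 0) "decreasing" else "flat"
  }
  out <- list(
    n_years = nrow(object),
    max_fcci = max(object$fcci),
    max_year = object$year[which.max(object$fcci)],
    years_over = vapply(unclass(t), function(th) sum(object$fcci > th), 0L),
    trend = trend,
    thresholds = t)
  class(out) <- "summary.fcci_assessment"
  out
}

#' @export
print.summary.fcci_assessment <- function(x, ...) {
  cat(sprintf("Lake-wide FCCI over %d years: max %.4f in %s; trend %s\n",
              x$n_years, x$max_fcci, x$max_year, x$trend))
  for (nm in names(x$years_over))
    cat(sprintf("  years with FCCI > %.1f (%s): %d\n",
                x$thresholds[[nm]], nm, x$years_over[[nm]]))
  below <- x$max_fcci <= x$thresholds$benchmark
  cat(if (below)
    "  all years below the benchmark: restocking headroom remains\n"
    else "  benchmark exceeded in at least one year\n")
  invisible(x)
}

#' @export
plot.fcci_assessment <- function(x, ...) {
  op <- par(mar = c(4, 4, 2, 4)); on.exit(par(op))
  plot(x$year, x$fpp_t / 1e3, type = "b", pch = 1, xlab = "year",
       ylab = "biomass (kt)", ylim = range(0, x$fpp_t / 1e3), ...)
  lines(x$year, x$fp_t / 1e3, type = "b", pch = 16)
  par(new = TRUE)
  plot(x$year, x$fcci, type = "l", lty = 2, axes = FALSE, xlab = "", ylab = "",
       ylim = c(0, max(1, x$fcci)))
  axis(4); mtext("FCCI", side = 4, line = 2.5)
  abline(h = attr(x, "thresholds")$benchmark, lty = 3)
  legend("topleft", c("FPP", "FP", "FCCI"), lty = c(1, 1, 2),
         pch = c(1, 16, NA), bty = "n")
  invisible(x)
}

#' Allocate a lake-wide stock over the grid
#'
#' Distributes total biomass over water cells proportionally to a weight
#' surface (e.g. an acoustic density field); with no weights the allocation
#' is uniform.  Both allocation rules are assumptions, not observations.
#'
#' @param fp_total lake-wide biomass, tonnes.
#' @param water logical water-cell matrix.
#' @param weights optional non-negative weight matrix (NA treated as 0).
#' @return Matrix of tonnes per cell, summing to `fp_total` over water.
#' @export
allocate_fp <- function(fp_total, water, weights = NULL) {
  if (fp_total < 0) stop("'fp_total' must be >= 0")
  w <- if (is.null(weights)) ifelse(water, 1, 0)
       else { x <- weights; x[is.na(x) | !water] <- 0; x }
  if (sum(w) == 0) stop("no positive weights on water cells")
  out <- fp_total * w / sum(w)
  out[!water] <- NA_real_
  out
}

#' Per-cell carrying-capacity map
#'
#' Ratio of per-cell stock to per-cell annual fish potential production,
#' both in tonnes per cell.  Cells with zero FPP and zero stock map to 0;
#' zero FPP under a positive stock is an error (the index is undefined
#' there).
#'
#' @param fp_density tonnes of fish per cell (matrix).
#' @param annual_net_fpp_t tonnes of annual net FPP per cell (matrix; for
#'   1 km2 cells this is numerically the annual net FPP in g/m2).
#' @return Matrix of per-cell FCCI values (NA off the shared mask).
#' @export
fcci_map <- function(fp_density, annual_net_fpp_t) {
  if (!all(dim(fp_density) == dim(annual_net_fpp_t)))
    stop("'fp_density' and 'annual_net_fpp_t' grids are misaligned")
  both <- !is.na(fp_density) & !is.na(annual_net_fpp_t)
  if (any(both & annual_net_fpp_t == 0 & fp_density > 0))
    stop("positive stock over zero FPP: per-cell FCCI undefined")
  out <- fp_density / annual_net_fpp_t
  out[both & annual_net_fpp_t == 0 & fp_density == 0] <- 0
  out[!both] <- NA_real_
  out
}

#' Classify a carrying-capacity map into management zones
#'
#' Labels every defined cell on the five-level ladder (underutilised <
#' `0.3`, moderate, high pressure > `0.5`, over benchmark > `0.6`,
#' overexploited > `1.0`) and recommends the largest contiguous
#' underutilised region as the release zone for restocking.
#'
#' @param fcci_grid matrix of per-cell FCCI values (see [fcci_map()]).
#' @param thresholds a [threshold_config()].
#' @return A list of class `fcci_zones`: `zones` (character matrix),
#'   `counts` (named integer vector over all five labels),
#'   `release_zone` (logical matrix marking the recommended region),
#'   `release_cells` (its size).
#' @export
classify_zones <- function(fcci_grid, thresholds = threshold_config()) {
  z <- fcci_zone(fcci_grid, thresholds)
  zones <- matrix(z, nrow(fcci_grid), ncol(fcci_grid))
  counts <- vapply(fcci_zone_levels,
                   function(l) sum(zones == l, na.rm = TRUE), 0L)
  under <- !is.na(zones) & zones == "underutilised"
  release <- largest_component(under)
  structure(list(zones = zones, counts = counts,
                 release_zone = release, release_cells = sum(release)),
            class = "fcci_zones")
}

#' @export
print.fcci_zones <- function(x, ...) {
  cat("FCCI management zones:\n")
  for (l in names(x$counts)) cat(sprintf("  %-15s %d cells\n", l, x$counts[[l]]))
  cat(sprintf("  recommended release zone: %d contiguous underutilised cells\n",
              x$release_cells))
  invisible(x)
}

# Largest 4-connected component of a logical matrix (flood fill).
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c)); lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  if (nxt == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = nxt)
  lab == which.max(sizes)
}
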