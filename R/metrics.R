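#' Validation statistics for a modelled-vs-surveyed pair
#'
#' The four matchup-validation metrics: average relative error
#' `ARE = mean((Xm - Xs)/Xs) * 100`, Pearson correlation `CC`, root mean
#' square error `RMSE = sqrt(mean((Xm - Xs)^2))`, and estimation accuracy
#' `EA = (1 - RMSE/mean(Xs)) * 100`.  EA can be negative when the RMSE
#' exceeds the surveyed mean; it is reported as-is.
#'
#' @param modelled numeric vector Xm.
#' @param surveyed numeric vector Xs, same length; non-zero (ARE divides by
#'   it).
#' @param variable_name label carried into the report.
#' @return An object of class `validation_report`: `variable_name`, `n`,
#'   `are_pct`, `cc`, `rmse`, `ea_pct`.
#' @examples
#' compare_series(c(2, 4), c(1, 2))  # ARE 100%, RMSE sqrt(2.5)
#' @export
compare_series <- function(modelled, surveyed, variable_name = "variable") {
  if (length(modelled) != length(surveyed))
    stop("length mismatch: ", length(modelled), " modelled vs ",
         length(surveyed), " surveyed")
  if (length(modelled) < 2) stop("need at least 2 pairs")
  if (any(surveyed == 0)) stop("surveyed values contain zero: ARE undefined")
  cc <- if (var(modelled) == 0 || var(surveyed) == 0)
    stop("zero variance: correlation undefined")
  else cor(modelled, surveyed)
  rmse <- sqrt(mean((modelled - surveyed)^2))
  structure(list(
    variable_name = variable_name,
    n = length(modelled),
    are_pct = mean((modelled - surveyed) / surveyed) * 100,
    cc = cc,
    rmse = rmse,
    ea_pct = (1 - rmse / mean(surveyed)) * 100), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): ARE %.2f%%  CC %.3f  RMSE %.4g  EA %.2f%%\n",
              x$variable_name, x$n, x$are_pct, x$cc, x$rmse, x$ea_pct))
  if (x$ea_pct < 0)
    cat("  note: EA < 0 because RMSE exceeds the surveyed mean\n")
  invisible(x)
}

#' Validation reports per variable from a matchup table
#'
#' Splits a matchup table by variable, keeps only matchups flagged valid,
#' and computes a [compare_series()] report for each variable with at least
#' two valid pairs (satellite/modelled vs field/surveyed).
#'
#' @param matchups data.frame with columns `variable`, `satellite_value`,
#'   `field_value`, `valid` (rbind-ed [extract_matchup()] rows).
#' @return Named list of `validation_report` objects.
#' @export
validate_pipeline <- function(matchups) {
  m <- matchups[matchups$valid, , drop = FALSE]
  if (nrow(m) == 0) stop("no valid matchups")
  out <- list()
  for (v in unique(m$variable)) {
    mv <- m[m$variable == v, , drop = FALSE]
    if (nrow(mv) < 2) next
    out[[v]] <- compare_series(mv$satellite_value, mv$field_value, v)
  }
  if (length(out) == 0) stop("no variable has >= 2 valid matchups")
  out
}
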