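#' Trophic energy-transfer parameters
#'
#' Constants of the chain converting phytoplankton carbon fixation into the
#' fish fresh weight it can sustain: trophic transfer efficiency `a`
#' (fraction passed per trophic step), trophic level `n` (number of transfer
#' steps above the producers), production-to-biomass ratio `pb` of the
#' plankton food base, energy conversion `E` (kJ per g fresh weight of
#' fish), lake area `A_lake` (m2), and `kj_per_mgC`, the bundled
#' carbon-to-energy equivalence (kJ per mg C m-2).  Baselines are the
#' single-species alpine-lake values: a = 0.10, n = 2, P/B = 30, E = 2.5,
#' A_lake = 4.5e9 m2.
#'
#' @param a trophic transfer efficiency, 0 < a < 1.
#' @param n trophic level (transfer steps), >= 1.
#' @param pb production-to-biomass ratio of the food base (30-50 typical).
#' @param E energy conversion, kJ per g fresh weight.
#' @param A_lake lake area, m2.
#' @param kj_per_mgC energy content per unit of areal carbon fixation.
#' @return An object of class `trophic_params`.
#' @examples
#' p <- trophic_params()
#' fpp_factor(p)  # 0.1^2 * 30 / 2.5 = 0.12
#' @export
trophic_params <- function(a = 0.10, n = 2, pb = 30, E = 2.5,
                           A_lake = 4500e6, kj_per_mgC = 1) {
  if (a <= 0 || a >= 1) stop("'a' must lie in (0, 1)")
  if (n < 1) stop("'n' must be >= 1")
  if (pb <= 0) stop("'pb' must be > 0")
  if (E <= 0) stop("'E' must be > 0")
  if (A_lake <= 0) stop("'A_lake' must be > 0")
  if (kj_per_mgC <= 0) stop("'kj_per_mgC' must be > 0")
  structure(list(a = a, n = n, pb = pb, E = E, A_lake = A_lake,
                 kj_per_mgC = kj_per_mgC), class = "trophic_params")
}

#' @export
print.trophic_params <- function(x, ...) {
  cat("Trophic energy-transfer parameters\n")
  cat(sprintf("  a = %.3g  n = %.3g  P/B = %.3g  E = %.3g kJ/g  A_lake = %.3g m2\n",
              x$a, x$n, x$pb, x$E, x$A_lake))
  cat(sprintf("  net FPP factor a^n * P/B * kj_per_mgC / E = %.4g\n",
              fpp_factor(x)))
  invisible(x)
}

#' The scalar carbon-to-fish conversion factor
#'
#' `a^n * pb * kj_per_mgC / E`: multiplying monthly net primary production
#' (mg C m-2) by this factor yields net fish potential production (g fresh
#' weight m-2).  Exposed separately so alternative readings of the chain
#' amount to supplying a different factor.
#'
#' @param params a [trophic_params()].
#' @return Dimensionless conversion factor.
#' @export
fpp_factor <- function(params) {
  stopifnot(inherits(params, "trophic_params"))
  params$a^params$n * params$pb * params$kj_per_mgC / params$E
}

#' Net fish potential production per cell
#'
#' Converts monthly net primary production into the fish fresh weight it can
#' sustain: `net_fpp = net_pp * a^n * P/B / E` (with `kj_per_mgC` carrying
#' the carbon-to-energy equivalence), g m-2 month-1.
#'
#' @param net_pp monthly net primary production, mg C m-2 month-1 (scalar,
#'   vector or matrix; NA cells propagate).
#' @param params a [trophic_params()].
#' @return Net FPP, g m-2 month-1, same shape as `net_pp`.
#' @export
net_fpp <- function(net_pp, params = trophic_params()) {
  if (any(net_pp < 0, na.rm = TRUE)) stop("'net_pp' must be >= 0")
  net_pp * fpp_factor(params)
}

#' Lake-wide gross monthly fish potential production
#'
#' Mean net FPP over defined cells times the full lake area, in tonnes:
#' `mean(net_fpp) * A_lake * 1e-6`.  The difference between this
#' full-area extrapolation and the sum over defined cell areas only is
#' attached as attribute `coverage_gap_t` (a mask-coverage diagnostic).
#'
#' @param fpp_field net FPP, g m-2 (matrix or vector; NA = undefined).
#' @param params a [trophic_params()].
#' @return Gross monthly FPP, tonnes.
#' @export
gross_monthly_fpp <- function(fpp_field, params = trophic_params()) {
  vals <- fpp_field[!is.na(fpp_field)]
  if (length(vals) == 0) stop("no defined cells in 'fpp_field'")
  gross <- mean(vals) * params$A_lake * 1e-6
  defined_only <- sum(vals) * 1e6 * 1e-6  # 1 km2 cells
  structure(gross, coverage_gap_t = gross - defined_only)
}

#' Gross annual fish potential production
#'
#' Sum of the May-October gross monthly values, tonnes.
#'
#' @param monthlies numeric vector of gross monthly FPP (tonnes), named or
#'   ordered by month; or a data.frame with columns `month` and `gross_t`.
#' @param months the months the year must cover (default 5:10).
#' @param strict error on missing months (default) or sum what is present
#'   with a warning.
#' @return Gross annual FPP, tonnes.
#' @export
gross_annual_fpp <- function(monthlies, months = 5:10, strict = TRUE) {
  if (is.data.frame(monthlies)) {
    got <- monthlies$month
    vals <- monthlies$gross_t
  } else {
    vals <- as.numeric(monthlies)
    got <- if (!is.null(names(monthlies))) as.integer(names(monthlies))
           else months[seq_along(vals)]
  }
  if (anyDuplicated(got)) stop("duplicate months in 'monthlies'")
  missing <- setdiff(months, got)
  if (length(missing)) {
    msg <- paste("missing months:", paste(missing, collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; summing available months")
  }
  sum(vals[got %in% months])
}
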