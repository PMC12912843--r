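#' Temperature-dependent optimal photosynthetic rate
#'
#' The maximum chlorophyll-specific carbon fixation rate of the Vertically
#' Generalised Production Model, as a seventh-order polynomial in surface
#' temperature with the published clamps: 0 below -10 degC, 1.13 below
#' -1 degC, 4.00 above 28.5 degC.
#'
#' @param sst surface temperature, degC (vectorised).
#' @return Optimal rate, mg C (mg Chl)-1 h-1.
#' @examples
#' popt_b(c(-5, 10, 30))
#' @export
popt_b <- function(sst) {
  p <- 1.2956 + 2.749e-1 * sst + 6.17e-2 * sst^2 - 2.05e-2 * sst^3 +
    2.462e-3 * sst^4 - 1.348e-4 * sst^5 + 3.4132e-6 * sst^6 - 3.27e-8 * sst^7
  out <- p
  out[sst < -1] <- 1.13
  out[sst < -10] <- 0
  out[sst > 28.5] <- 4.00
  out[is.na(sst)] <- NA_real_
  out
}

#' Diffuse attenuation of PAR from Kd490
#'
#' Default relation is the empirical broadband form
#' `KdPAR = 0.0665 + 0.874 * Kd490 - 0.00121 / Kd490`; an alternative
#' function of Kd490 can be supplied.  The result is floored at a small
#' positive value because the empirical form turns negative in extremely
#' clear water (the euphotic depth is capped at the lake depth anyway).
#'
#' @param kd490 diffuse attenuation at 490 nm, m-1; must be positive.
#' @param relation optional function `kd490 -> kd_par` replacing the default.
#' @return KdPAR, m-1.
#' @export
kd_par_from_kd490 <- function(kd490, relation = NULL) {
  if (any(kd490 <= 0, na.rm = TRUE)) stop("'kd490' must be > 0")
  kp <- if (is.null(relation)) 0.0665 + 0.874 * kd490 - 0.00121 / kd490
        else relation(kd490)
  pmax(kp, 1e-4)
}

#' Euphotic (1\% light) depth
#'
#' `zeu = ln(100) / KdPAR`, capped at the lake depth so no production is
#' credited below the lakebed.
#'
#' @param kd_par diffuse attenuation of PAR, m-1.
#' @param depth_cap lake depth, m (default 20).
#' @return Euphotic depth, m.
#' @export
euphotic_depth <- function(kd_par, depth_cap = 20) {
  if (any(kd_par <= 0, na.rm = TRUE)) stop("'kd_par' must be > 0")
  pmin(log(100) / kd_par, depth_cap)
}

#' Astronomical daylength
#'
#' Hours of daylight from standard solar declination geometry.
#'
#' @param latitude_deg latitude, degrees (sub-polar: |lat| < 66.5).
#' @param day_of_year integer day of year, 1-366.
#' @return Daylength, hours.
#' @examples
#' daylength(36.9, 172) > daylength(36.9, 355)  # summer longer than winter
#' @export
daylength <- function(latitude_deg, day_of_year) {
  if (any(abs(latitude_deg) >= 66.5))
    stop("'latitude_deg' must be sub-polar (|lat| < 66.5)")
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude_deg * pi / 180
  cos_h <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 / pi * acos(cos_h)
}

#' Daily depth-integrated primary production (VGPM)
#'
#' `PP = 0.66125 * popt_b(sst) * PAR / (PAR + 4.1) * zeu * chl * dirr`,
#' in mg C m-2 day-1.  Linear in chlorophyll; saturating in light; zero at
#' zero chlorophyll or zero light.
#'
#' @param chl chlorophyll-a, mg/m3.
#' @param sst surface temperature, degC.
#' @param par daily PAR, mol quanta m-2 day-1.
#' @param zeu euphotic depth, m (see [euphotic_depth()]); alternatively pass
#'   `kd490` and it is derived.
#' @param dirr daylength, hours.
#' @param kd490 optional Kd490 (m-1) used to derive `zeu` when `zeu` is NULL.
#' @param depth_cap lake depth cap for the derived euphotic depth, m.
#' @return Daily production, mg C m-2 day-1 (same shape as `chl`).
#' @examples
#' vgpm_daily(chl = 1, sst = 10, par = 41, zeu = 10, dirr = 12)
#' @export
vgpm_daily <- function(chl, sst, par, zeu = NULL, dirr, kd490 = NULL,
                       depth_cap = 20) {
  if (is.null(zeu)) {
    if (is.null(kd490)) stop("supply either 'zeu' or 'kd490'")
    zeu <- euphotic_depth(kd_par_from_kd490(kd490), depth_cap = depth_cap)
  }
  if (any(chl < 0, na.rm = TRUE)) stop("'chl' must be >= 0")
  if (any(par < 0, na.rm = TRUE)) stop("'par' must be >= 0")
  if (any(dirr < 0 | dirr > 24, na.rm = TRUE)) stop("'dirr' must be in [0, 24]")
  0.66125 * popt_b(sst) * par / (par + 4.1) * zeu * chl * dirr
}

#' Monthly primary production from a composite
#'
#' Evaluates VGPM on a monthly composite's layers and scales the daily rate
#' by the number of days in the month.  Undefined composite cells stay
#' undefined.
#'
#' @param composite a `monthly_composite` (gap-filled or not).
#' @param latitude_deg latitude for the daylength term.
#' @param depth_cap lake depth, m.
#' @return An object of class `pp_field`: `pp_daily` (mg C m-2 day-1),
#'   `pp_monthly` (mg C m-2 month-1), `zeu`, `year`, `month`, `days`.
#' @export
monthly_pp <- function(composite, latitude_deg = 36.9, depth_cap = 20) {
  stopifnot(inherits(composite, "monthly_composite"))
  mid_doy <- as.integer(format(
    as.Date(sprintf("%04d-%02d-15", composite$year, composite$month)), "%j"))
  dirr <- daylength(latitude_deg, mid_doy)
  zeu <- euphotic_depth(kd_par_from_kd490(pmax(composite$kd490, 1e-6)),
                        depth_cap = depth_cap)
  ppd <- vgpm_daily(chl = composite$chl, sst = composite$sst,
                    par = composite$par, zeu = zeu, dirr = dirr)
  nd <- days_in_month(composite$year, composite$month)
  structure(list(year = composite$year, month = composite$month, days = nd,
                 pp_daily = ppd, pp_monthly = ppd * nd, zeu = zeu),
            class = "pp_field")
}
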