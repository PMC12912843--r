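#' Monte Carlo configuration for trophic-parameter sensitivity
#'
#' @param iterations number of Monte Carlo draws (baseline 1000).
#' @param variation relative half-width of the uniform parameter variation
#'   (baseline 0.20, i.e. +/-20\% of each baseline value).
#' @param varied_params subset of `c("a", "pb", "n", "E")` to vary.
#' @param seed integer seed.
#' @param batch_sizes nested prefix sizes for the convergence check.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(iterations = 1000, variation = 0.20,
                      varied_params = c("a", "pb", "n", "E"),
                      seed = 42L, batch_sizes = c(500, 800, 1000)) {
  if (iterations < 1) stop("'iterations' must be >= 1")
  if (variation < 0 || variation >= 1) stop("'variation' must be in [0, 1)")
  if (!all(varied_params %in% c("a", "pb", "n", "E")))
    stop("'varied_params' must be a subset of a, pb, n, E")
  batch_sizes <- pmin(sort(batch_sizes), iterations)
  structure(list(iterations = as.integer(iterations), variation = variation,
                 varied_params = varied_params, seed = as.integer(seed),
                 batch_sizes = as.integer(unique(batch_sizes))),
            class = "mc_config")
}

#' Back out the annual production index from an FPP series
#'
#' Given gross annual FPP (tonnes) and the baseline parameters, returns the
#' parameter-free production index (lake-mean annual net PP, mg C m-2) such
#' that `FPP = index * fpp_factor(params) * A_lake * 1e-6`.  This lets a
#' published FPP series drive the sensitivity analysis through the same
#' conversion chain.
#'
#' @param fpp_t gross annual FPP series, tonnes.
#' @param params baseline [trophic_params()].
#' @return Numeric series of annual production indices.
#' @export
pp_series_from_fpp <- function(fpp_t, params = trophic_params()) {
  fpp_t / (fpp_factor(params) * params$A_lake * 1e-6)
}

# Gross annual FPP (tonnes) from a production index under given parameters.
fpp_from_pp <- function(pp_index, params)
  pp_index * fpp_factor(params) * params$A_lake * 1e-6

#' Monte Carlo sensitivity of FPP and FCCI to trophic parameters
#'
#' Each iteration draws every varied parameter from
#' `Uniform(baseline * (1 - v), baseline * (1 + v))` and recomputes the
#' annual FPP and FCCI series through the conversion chain.  Two designs are
#' reported: one-at-a-time (one parameter varied, the rest at baseline)
#' gives a per-parameter FPP relative RMSE (percent, relative to the
#' baseline FPP); all-at-once (all varied together) gives the probability
#' that FCCI exceeds the benchmark, pooled over iteration-year pairs, per
#' year, and as the worst single year.
#'
#' @param baseline baseline [trophic_params()].
#' @param fp_series annual fish population biomass, tonnes.
#' @param pp_series annual production index, same length (see
#'   [pp_series_from_fpp()]).
#' @param cfg an [mc_config()].
#' @param thresholds a [threshold_config()] (supplies the benchmark).
#' @return An object of class `mc_result`: `fpp_rmse_pct` (named per
#'   parameter), `p_fcci_gt_benchmark` (list: `pooled_pct`, `per_year_pct`,
#'   `max_year_pct`), `convergence` (see [convergence_check()]),
#'   `draws_summary`, plus the configuration echo.
#' @export
run_monte_carlo <- function(baseline, fp_series, pp_series,
                            cfg = mc_config(),
                            thresholds = threshold_config()) {
  stopifnot(inherits(baseline, "trophic_params"), inherits(cfg, "mc_config"))
  if (length(fp_series) == 0 || length(pp_series) == 0)
    stop("empty FP/PP series")
  if (length(fp_series) != length(pp_series))
    stop("'fp_series' and 'pp_series' must have equal length")
  v <- cfg$variation
  base_fpp <- fpp_from_pp(pp_series, baseline)
  with_seed(cfg$seed, {
    draw <- function(p0, n) if (v == 0) rep(p0, n)
                            else runif(n, p0 * (1 - v), p0 * (1 + v))
    modified <- function(p) {
      out <- baseline
      for (nm in names(p)) out[[nm]] <- p[[nm]]
      out
    }
    # one-at-a-time relative RMSE per parameter
    rmse <- numeric(0)
    draws_summary <- list()
    for (nm in cfg$varied_params) {
      d <- draw(baseline[[nm]], cfg$iterations)
      draws_summary[[nm]] <- c(min = min(d), mean = mean(d), max = max(d))
      rel2 <- vapply(d, function(val) {
        fpp <- fpp_from_pp(pp_series, modified(stats::setNames(list(val), nm)))
        mean(((fpp - base_fpp) / base_fpp)^2)
      }, 0)
      rmse[nm] <- 100 * sqrt(mean(rel2))
    }
    # all-at-once FCCI exceedance
    ny <- length(fp_series)
    exceed <- matrix(FALSE, cfg$iterations, ny)
    mean_fpp <- numeric(cfg$iterations)
    all_draws <- lapply(cfg$varied_params,
                        function(nm) draw(baseline[[nm]], cfg$iterations))
    names(all_draws) <- cfg$varied_params
    for (i in seq_len(cfg$iterations)) {
      p <- modified(lapply(all_draws, `[`, i))
      fpp_i <- fpp_from_pp(pp_series, p)
      exceed[i, ] <- fp_series / fpp_i > thresholds$benchmark
      mean_fpp[i] <- mean(fpp_i)
    }
    per_year <- 100 * colMeans(exceed)
    structure(list(
      fpp_rmse_pct = rmse,
      p_fcci_gt_benchmark = list(pooled_pct = 100 * mean(exceed),
                                 per_year_pct = per_year,
                                 max_year_pct = max(per_year)),
      convergence = convergence_check(mean_fpp, cfg$batch_sizes),
      draws_summary = draws_summary,
      iterations = cfg$iterations, variation = v, seed = cfg$seed,
      benchmark = thresholds$benchmark), class = "mc_result")
  })
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo sensitivity: %d iterations, +/-%.0f%% uniform variation\n",
              x$iterations, 100 * x$variation))
  cat("  one-at-a-time FPP relative RMSE (%):\n")
  for (nm in names(x$fpp_rmse_pct))
    cat(sprintf("    %-3s %6.2f\n", nm, x$fpp_rmse_pct[[nm]]))
  cat(sprintf("  P(FCCI > %.1f): pooled %.2f%%, worst year %.2f%%\n",
              x$benchmark, x$p_fcci_gt_benchmark$pooled_pct,
              x$p_fcci_gt_benchmark$max_year_pct))
  cat(sprintf("  convergence CV across batches: %.4f%% (stable: %s)\n",
              x$convergence$cv_pct, x$convergence$stable))
  invisible(x)
}

#' Convergence check over nested iteration batches
#'
#' Computes the mean-FPP over each prefix batch, the coefficient of
#' variation across those batch means, and whether the mean moved by less
#' than 0.5\% between the two largest batches.
#'
#' @param mean_fpp_stream per-iteration mean FPP values, in draw order.
#' @param batch_sizes increasing nested prefix sizes.
#' @param stability_pct relative change regarded as stable (default 0.5).
#' @return List with `batch_means`, `cv_pct`, `last_change_pct`, `stable`.
#' @export
convergence_check <- function(mean_fpp_stream, batch_sizes,
                              stability_pct = 0.5) {
  batch_sizes <- sort(unique(as.integer(batch_sizes)))
  if (any(batch_sizes > length(mean_fpp_stream)))
    stop("batch size exceeds the number of iterations (",
         length(mean_fpp_stream), ")")
  if (any(batch_sizes < 1)) stop("batch sizes must be positive")
  bm <- vapply(batch_sizes, function(b) mean(mean_fpp_stream[seq_len(b)]), 0)
  cv <- if (length(bm) > 1 && mean(bm) != 0) 100 * sd(bm) / mean(bm) else 0
  change <- if (length(bm) > 1)
    100 * abs(bm[length(bm)] - bm[length(bm) - 1]) / abs(bm[length(bm) - 1])
  else 0
  list(batch_sizes = batch_sizes, batch_means = bm, cv_pct = cv,
       last_change_pct = change, stable = change < stability_pct)
}
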