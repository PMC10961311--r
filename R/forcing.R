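#' Derive the chlorophyll-to-biomass scaling factor alpha
#'
#' The daily chlorophyll-a density series (g/m3) is converted to an areal
#' phytoplankton biomass (g/m2) through a single composite factor alpha (m)
#' that folds together phytoplankton cell mass, the chlorophyll-to-cell
#' regression slope, and the average water-column depth under the sampling
#' quadrat. None of those constituents is needed individually: alpha is fixed
#' by requiring that the total subsidy potential over the study period equal
#' that of a reference model delivering a constant daily subsidy, so
#' `alpha = daily_subsidy * 365 * n_years / sum(chloro)`.
#'
#' @param series Data frame with columns `date`, `chloro_g_m3` (daily
#'   chlorophyll-a density, nonnegative).
#' @param daily_subsidy Constant-subsidy reference rate in g/(m2 day).
#'   Default 7355, the constant-input rate the scaling is normalised against.
#' @param n_years Number of years the series spans (years counted as 365
#'   days for the subsidy total).
#' @return alpha in metres (scalar, > 0).
#' @export
compute_alpha <- function(series, daily_subsidy = 7355, n_years) {
  series <- validate_chloro(series)
  if (missing(n_years)) {
    n_years <- round(nrow(series) / 365)
  }
  stopifnot(n_years > 0, daily_subsidy > 0)
  total <- sum(series$chloro_g_m3)
  if (total <= 0) {
    stop("chlorophyll series sums to zero; alpha undefined", call. = FALSE)
  }
  daily_subsidy * 365 * n_years / total
}

#' @keywords internal
validate_chloro <- function(series) {
  series <- tibble::as_tibble(series)
  if (!all(c("date", "chloro_g_m3") %in% names(series))) {
    stop("chlorophyll series needs columns date, chloro_g_m3", call. = FALSE)
  }
  series$date <- as.Date(series$date)
  if (any(is.na(series$date))) stop("unparseable dates", call. = FALSE)
  if (is.unsorted(series$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(series$chloro_g_m3 < 0)) {
    stop("negative chlorophyll density", call. = FALSE)
  }
  series
}

#' Scale a chlorophyll series to areal phytoplankton biomass
#'
#' @param series Data frame with `date`, `chloro_g_m3`.
#' @param alpha Scaling factor in metres, see [compute_alpha()].
#' @return Tibble with `date`, `biomass_g_m2 = alpha * chloro_g_m3`.
#' @export
scale_chlorophyll <- function(series, alpha) {
  series <- validate_chloro(series)
  stopifnot(is.numeric(alpha), alpha > 0)
  tibble::tibble(date = series$date,
                 biomass_g_m2 = alpha * series$chloro_g_m3)
}

#' Fit a continuous forcing function to a scaled biomass series
#'
#' Fits a cubic spline through the daily areal-biomass samples and exposes it
#' as a continuous function of time in hours, which the non-autonomous term
#' of the food-web phytoplankton equation evaluates pointwise. Negative
#' spline excursions are clipped to zero (biomass cannot be negative), and
#' evaluation outside the sampled window holds the boundary value.
#'
#' @param scaled Data frame with `date`, `biomass_g_m2` (from
#'   [scale_chlorophyll()]), at least 4 rows. Gaps are bridged by the spline;
#'   gaps longer than 30 days trigger a warning.
#' @param smooth Smoothing parameter passed to [stats::smooth.spline()]'s
#'   `spar`; `NULL` (default) fits an interpolating spline through the
#'   samples instead.
#' @return An `atn_forcing` object: callable via [evaluate_forcing()], with
#'   fields `t_min`, `t_max` (hours) and `knots` (the input samples with
#'   their hour offsets).
#' @export
fit_forcing <- function(scaled, smooth = NULL) {
  scaled <- tibble::as_tibble(scaled)
  if (!all(c("date", "biomass_g_m2") %in% names(scaled))) {
    stop("scaled series needs columns date, biomass_g_m2", call. = FALSE)
  }
  if (nrow(scaled) < 4) {
    stop("need at least 4 samples to fit the forcing spline", call. = FALSE)
  }
  scaled$date <- as.Date(scaled$date)
  if (is.unsorted(scaled$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  gaps <- diff(as.numeric(scaled$date))
  if (any(gaps > 30)) {
    warning("gap(s) longer than 30 days in the series; the spline bridges ",
            "them but the fit is unconstrained there", call. = FALSE)
  }
  t_hours <- as.numeric(scaled$date - scaled$date[1]) * 24
  if (is.null(smooth)) {
    fun <- stats::splinefun(t_hours, scaled$biomass_g_m2, method = "fmm")
  } else {
    ss <- stats::smooth.spline(t_hours, scaled$biomass_g_m2, spar = smooth)
    fun <- function(t) stats::predict(ss, t)$y
  }
  structure(
    list(fun = fun, t_min = min(t_hours), t_max = max(t_hours),
         origin = scaled$date[1],
         knots = tibble::tibble(t_hours = t_hours,
                                biomass_g_m2 = scaled$biomass_g_m2)),
    class = "atn_forcing"
  )
}

#' Evaluate a forcing function
#'
#' @param fn An `atn_forcing`.
#' @param t_hours Numeric vector of times in hours since the series origin.
#'   Times outside the fitted window are held at the boundary value.
#' @return Nonnegative biomass values (g/m2), same length as `t_hours`.
#' @export
evaluate_forcing <- function(fn, t_hours) {
  stopifnot(inherits(fn, "atn_forcing"))
  t <- pmin(pmax(t_hours, fn$t_min), fn$t_max)
  pmax(fn$fun(t), 0)
}

#' Constant forcing helper
#'
#' Builds an `atn_forcing` that returns `level` everywhere — useful for
#' constant-subsidy regressions against the autonomous model.
#'
#' @param level Biomass level g/m2.
#' @param t_max Upper domain bound in hours (default one 365-day year).
#' @return An `atn_forcing`.
#' @export
constant_forcing <- function(level, t_max = 365 * 24) {
  stopifnot(level >= 0)
  structure(
    list(fun = function(t) rep(level, length(t)), t_min = 0, t_max = t_max,
         origin = as.Date("2000-01-01"),
         knots = tibble::tibble(t_hours = c(0, t_max),
                                biomass_g_m2 = level)),
    class = "atn_forcing"
  )
}

#' @export
print.atn_forcing <- function(x, ...) {
  cat("<atn_forcing> ", nrow(x$knots), " knots over [",
      x$t_min, ", ", x$t_max, "] h; range ",
      format(min(x$knots$biomass_g_m2)), "-",
      format(max(x$knots$biomass_g_m2)), " g/m2\n", sep = "")
  invisible(x)
}
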