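#' @useDynLib reefsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# 365-day calendar used throughout the simulator
MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_ENDS <- cumsum(MONTH_LENGTHS)
DAYS_PER_YEAR <- 365L

#' Default parameters of the synthetic sea-surface-temperature generator
#'
#' A Zanzibar-like seasonal cycle: sinusoidal annual course peaking in
#' mid-March, with small autocorrelated daily noise. Hot years superimpose a
#' short temperature anomaly peaking at about +2 degC in mid-March (Gaussian
#' pulse in time). The pulse duration is calibrated so that the 20-day
#' bleaching statistic of a hot March slightly exceeds 30 degC, the
#' bleaching onset of the least susceptible species: in a major event all
#' four species bleach (*P. damicornis* only in such years, and bleached
#' *P. damicornis* virtually always dies), whole-colony mortality of massive
#' Porites is of order 10 % per event while branching *A. muricata* suffers
#' the largest losses — the species-specific 1998-type response pattern the
#' model community is built around. Normal years stay below 29.9 degC
#' (massive Porites never bleach) but cross 29.4 degC in roughly a quarter
#' of years, so *A. muricata* shows occasional bleaching in ordinary
#' years.
#'
#' @return list of generator parameters: `mean_c` (annual mean, degC),
#'   `amplitude_c` (seasonal half-range, degC), `peak_doy` (day of year of
#'   the seasonal maximum), `noise_sd` (daily noise SD, degC), `noise_ar`
#'   (lag-1 autocorrelation of the noise), `hot_anomaly_c` (peak daily
#'   anomaly of a hot year, degC), `hot_sd_days` (temporal SD of the hot
#'   pulse, days).
#' @export
sst_defaults <- function() {
  list(mean_c = 27.4, amplitude_c = 1.9, peak_doy = 74,
       noise_sd = 0.2, noise_ar = 0.5,
       hot_anomaly_c = 2.0, hot_sd_days = 4)
}

#' Generate a synthetic daily sea-surface-temperature series
#'
#' @param years number of simulated years (365-day calendar).
#' @param hot_year_interval every k-th year is a hot year (first at year k);
#'   `NULL`, `NA` or `Inf` disables hot years.
#' @param params generator parameters, see [sst_defaults()].
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `sst_series`: list with `temp_c` (daily degC),
#'   `year` (year index per day), `doy` (day of year) and `hot` (logical per
#'   year).
#' @export
synth_sst <- function(years, hot_year_interval = NULL,
                      params = sst_defaults(), seed = NULL) {
  stopifnot(years >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(sst_defaults(), params)
  if (p$noise_sd < 0 || p$amplitude_c < 0 || abs(p$noise_ar) >= 1)
    stop("invalid SST generator parameters")
  nd <- years * DAYS_PER_YEAR
  doy <- rep(seq_len(DAYS_PER_YEAR), years)
  yr <- rep(seq_len(years), each = DAYS_PER_YEAR)

  hot <- rep(FALSE, years)
  if (!is.null(hot_year_interval) && is.finite(hot_year_interval)) {
    stopifnot(hot_year_interval >= 1)
    hot[seq_len(years) %% hot_year_interval == 0] <- TRUE
  }

  seasonal <- p$mean_c +
    p$amplitude_c * cos(2 * pi * (doy - p$peak_doy) / DAYS_PER_YEAR)
  anomaly <- ifelse(hot[yr],
                    p$hot_anomaly_c *
                      exp(-0.5 * ((doy - p$peak_doy) / p$hot_sd_days)^2),
                    0)
  noise <- as.numeric(stats::filter(stats::rnorm(nd, 0, p$noise_sd),
                                    p$noise_ar, method = "recursive"))
  temp <- seasonal + anomaly + noise
  temp <- pmin(pmax(temp, 15), 40) # physical bounds
  structure(list(temp_c = temp, year = yr, doy = doy, hot = hot),
            class = "sst_series")
}

#' @export
print.sst_series <- function(x, ...) {
  cat(sprintf("<sst_series: %d years (%d days), %d hot year(s), %.1f-%.1f degC>\n",
              max(x$year), length(x$temp_c), sum(x$hot),
              min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

# month index (1-based over the whole series) -> day range
month_day_range <- function(month) {
  yr <- (month - 1) %/% 12
  m <- (month - 1) %% 12 + 1
  first <- yr * DAYS_PER_YEAR + c(1L, MONTH_ENDS)[m]
  last <- yr * DAYS_PER_YEAR + MONTH_ENDS[m]
  c(first, last)
}

#' 20-day bleaching temperature statistic for one month
#'
#' The thermal-stress statistic that drives bleaching: cumulative
#' temperatures over running 20-day windows, expressed as the window mean so
#' the statistic is comparable to the degC thresholds; a month's statistic is
#' the hottest 20-day mean over all windows ending in that month.
#'
#' @param series an `sst_series` (or any object with a numeric `temp_c`).
#' @param month month index over the series (1 = January of year 1).
#' @param window window length in days.
#' @return The statistic in degC.
#' @export
bleaching_statistic <- function(series, month, window = 20L) {
  temp <- series$temp_c
  rng <- month_day_range(month)
  if (rng[1] - (window - 1) < 1 || rng[2] > length(temp))
    stop("series does not cover month ", month,
         " and its ", window - 1, " preceding days")
  ends <- rng[1]:rng[2]
  cs <- c(0, cumsum(temp))
  max((cs[ends + 1] - cs[ends - window + 1]) / window)
}

# vectorized monthly statistics for a whole series; early months whose
# leading windows would reach before day 1 use the windows that do fit
monthly_bleaching_statistics <- function(series, window = 20L) {
  temp <- series$temp_c
  nd <- length(temp)
  nmonths <- (nd %/% DAYS_PER_YEAR) * 12L
  cs <- c(0, cumsum(temp))
  out <- numeric(nmonths)
  for (m in seq_len(nmonths)) {
    rng <- month_day_range(m)
    ends <- max(rng[1], window):rng[2]
    out[m] <- max((cs[ends + 1] - cs[ends - window + 1]) / window)
  }
  out
}

#' Bleaching probability at a given thermal statistic
#'
#' Zero below the species' minimum bleaching temperature, then linear from
#' 0.30 at onset to 1.0 at the all-bleach temperature (the observed 30-100 %
#' mortality range transformed to bleaching probability), clamped above.
#'
#' @param T_stat the 20-day statistic, degC.
#' @param th thermal thresholds, see [thermal_thresholds()].
#' @return Probability in \[0, 1\]; vectorized over `T_stat`.
#' @export
bleach_probability <- function(T_stat, th) {
  stopifnot(th$min_bleach_T < th$all_bleach_T)
  p <- 0.3 + 0.7 * (T_stat - th$min_bleach_T) /
    (th$all_bleach_T - th$min_bleach_T)
  ifelse(T_stat < th$min_bleach_T, 0, pmin(p, 1))
}

#' Mortality probability of a freshly bleached colony
#'
#' Linear from 0 at the species' minimum death temperature to 1 at the
#' temperature where all corals die, clamped to \[0, 1\]. Applied only to
#' colonies that bleached in the current step.
#'
#' @inheritParams bleach_probability
#' @return Probability in \[0, 1\]; vectorized over `T_stat`.
#' @export
death_probability <- function(T_stat, th) {
  stopifnot(th$min_death_T < th$all_death_T)
  pmin(pmax((T_stat - th$min_death_T) /
              (th$all_death_T - th$min_death_T), 0), 1)
}

#' Mechanical disturbance regime
#'
#' Two circular disturbance classes: small events (default 2-4 m diameter,
#' e.g. anchor or boat strikes) and large events (default 5-10 m, e.g. anchor
#' chains or net damage). An interval of `NULL`, `NA` or `Inf` disables a
#' class.
#'
#' @param small_interval,large_interval months between events of each class.
#' @param small_diam_m,large_diam_m diameter ranges in metres.
#' @return list of class `disturbance_regime`.
#' @export
disturbance_regime <- function(small_interval = 12, large_interval = 60,
                               small_diam_m = c(2, 4),
                               large_diam_m = c(5, 10)) {
  chk <- function(x) is.null(x) || (is.na(x) || !is.finite(x)) || x >= 1
  stopifnot(chk(small_interval), chk(large_interval),
            all(small_diam_m > 0), all(large_diam_m > 0))
  structure(list(small_interval = small_interval,
                 large_interval = large_interval,
                 small_diam_m = small_diam_m,
                 large_diam_m = large_diam_m),
            class = "disturbance_regime")
}

#' Schedule disturbance events
#'
#' One event per elapsed interval per size class; the radius is drawn
#' uniformly from the class's diameter range, and the centre uniformly on the
#' arena extended by the event radius on all sides, so every point of the
#' core arena has equal probability of being hit.
#'
#' @param regime a [disturbance_regime()].
#' @param months number of simulated months.
#' @param arena `c(width, height)` of the core arena in metres.
#' @return data.frame with columns `month`, `x`, `y` (metres, may lie outside
#'   the core), `radius` (metres), `class`.
#' @export
schedule_disturbances <- function(regime, months, arena = c(40, 40)) {
  one_class <- function(interval, diam, cls) {
    if (is.null(interval) || is.na(interval) || !is.finite(interval) ||
        interval > months)
      return(NULL)
    at <- seq(interval, months, by = interval)
    r <- stats::runif(length(at), diam[1], diam[2]) / 2
    data.frame(month = at,
               x = stats::runif(length(at), -r, arena[1] + r),
               y = stats::runif(length(at), -r, arena[2] + r),
               radius = r, class = cls, stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(regime$small_interval, regime$small_diam_m, "small"),
               one_class(regime$large_interval, regime$large_diam_m, "large"))
  if (is.null(out))
    return(data.frame(month = integer(), x = numeric(), y = numeric(),
                      radius = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  out[order(out$month), , drop = FALSE]
}
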