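# -- temperature series I/O ---------------------------------------------------

#' Read a daily sea-surface-temperature series from CSV
#'
#' Expects a two-column file with header `date,temp_c`, ISO dates and one row
#' per day. The simulator runs on a 365-day calendar, so February 29 rows are
#' dropped; every retained year must then have 365 daily values.
#'
#' @param path file path.
#' @return An `sst_series` (see [synth_sst()]); the `hot` flag is set for
#'   years whose March statistic exceeds 30 degC (all four species above
#'   their bleaching onset).
#' @export
read_sst_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "temp_c") %in% names(df)))
    stop("expected columns 'date' and 'temp_c'")
  d <- as.Date(df$date)
  if (any(is.na(d))) stop("unparseable dates in ", path)
  keep <- !(format(d, "%m-%d") == "02-29")
  temp <- as.numeric(df$temp_c[keep])
  if (any(!is.finite(temp) | temp < 15 | temp > 40))
    stop("temperatures must be finite and within 15-40 degC")
  nd <- length(temp)
  years <- nd %/% 365L
  if (years < 1) stop("need at least one full year of daily data")
  temp <- temp[seq_len(years * 365L)]
  s <- structure(list(temp_c = temp,
                      year = rep(seq_len(years), each = 365L),
                      doy = rep(seq_len(365L), years),
                      hot = rep(FALSE, years)),
                 class = "sst_series")
  mar <- vapply(seq_len(years), function(y)
    bleaching_statistic(s, (y - 1) * 12 + 3), numeric(1))
  s$hot <- mar > 30
  s
}

#' Write a temperature series to CSV
#'
#' Inverse of [read_sst_csv()]: writes `date,temp_c` rows, one per day,
#' skipping February 29 so that every calendar year carries 365 values.
#'
#' @param series an `sst_series`.
#' @param path output file path.
#' @param start_date first date of the series.
#' @return `path`, invisibly.
#' @export
write_sst_csv <- function(series, path, start_date = "2000-01-01") {
  nd <- length(series$temp_c)
  dates <- seq(as.Date(start_date), by = "day", length.out = ceiling(nd * 1.01) + 2)
  dates <- dates[format(dates, "%m-%d") != "02-29"][seq_len(nd)]
  utils::write.csv(data.frame(date = format(dates), temp_c = series$temp_c),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- run output ---------------------------------------------------------------

#' Write run outputs to a directory
#'
#' Writes `covers.csv` (long format: replicate, month, species, cover_pct)
#' and `summary.csv` (pooled means and SDs over the analysis window).
#'
#' @param run a `reefsim_run` ([run_simulation()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_csv <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$covers, file.path(dir, "covers.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a state snapshot
#'
#' One row per organism: corals carry their full 24-axis shape (centre in
#' metres, axis lengths in cm), macroalgae their height and zone diameter.
#'
#' @param state a community state.
#' @param config the [sim_config()] (for species names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_snapshot <- function(state, config, path) {
  co <- state$corals
  nco <- length(co$x)
  axcols <- t(co$axes)
  colnames(axcols) <- paste0("axis_", seq_len(24))
  coral_df <- data.frame(
    type = rep("coral", nco),
    species = config$species$name[co$species],
    x = co$x, y = co$y,
    state = ifelse(co$bleached, "bleached", "healthy"),
    months_since_bleach = co$msb, age = co$age,
    height = NA_real_, diameter = 2 * coral_mean_radii(co),
    stringsAsFactors = FALSE)
  if (nco > 0) coral_df <- cbind(coral_df, axcols)
  al <- state$algae
  nal <- length(al$x)
  alga_df <- data.frame(
    type = rep("macroalga", nal),
    species = rep("macroalga", nal),
    x = al$x, y = al$y,
    state = rep("alive", nal),
    months_since_bleach = rep(NA_integer_, nal), age = al$age,
    height = al$height, diameter = al$diameter,
    stringsAsFactors = FALSE)
  if (nal > 0 && nco > 0)
    alga_df <- cbind(alga_df,
                     matrix(NA_real_, nal, 24,
                            dimnames = list(NULL, paste0("axis_", 1:24))))
  out <- if (nco > 0 && nal > 0) rbind(coral_df, alga_df)
         else if (nco > 0) coral_df else alga_df
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the turf grid
#'
#' @param state a community state.
#' @param path output CSV path (plain matrix of cell cover fractions).
#' @return `path`, invisibly.
#' @export
write_turf_csv <- function(state, path) {
  utils::write.table(state$turf, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# -- configuration files ------------------------------------------------------

#' Write a configuration to YAML
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$disturbance <- unclass(x$disturbance)
  if (!is.null(x$herbivory)) x$herbivory <- unclass(x$herbivory)
  x$species <- lapply(seq_len(nrow(config$species)), function(i)
    as.list(config$species[i, ]))
  x$sst <- NULL # a fixed series is not serialized
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' @param path file written by [write_config()] (or hand-edited in the same
#'   shape; missing fields fall back to the standard parameterization).
#' @return A [sim_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  defaults <- sim_config()
  cfg <- utils::modifyList(unclass(defaults), x, keep.null = TRUE)
  if (!is.null(x$species))
    cfg$species <- do.call(rbind, lapply(x$species, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(x$disturbance))
    cfg$disturbance <- do.call(disturbance_regime, x$disturbance)
  if (!is.null(x$herbivory))
    cfg$herbivory <- do.call(herbivory_params, x$herbivory)
  cfg$arena <- as.numeric(cfg$arena)
  class(cfg) <- "sim_config"
  cfg
}
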