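# -- internal state containers (struct-of-arrays for speed) -----------------

corals_new <- function() {
  list(species = integer(0), x = numeric(0), y = numeric(0),
       axes = matrix(numeric(0), nrow = 24, ncol = 0),
       morph = integer(0), bleached = logical(0), msb = integer(0),
       age = integer(0))
}

corals_subset <- function(co, keep) {
  list(species = co$species[keep], x = co$x[keep], y = co$y[keep],
       axes = co$axes[, keep, drop = FALSE], morph = co$morph[keep],
       bleached = co$bleached[keep], msb = co$msb[keep], age = co$age[keep])
}

corals_add <- function(co, species_idx, x, y, radius, morph) {
  n <- length(x)
  if (n == 0) return(co)
  if (length(radius) == 1) radius <- rep(radius, 24 * n)
  else if (length(radius) == n) radius <- rep(radius, each = 24)
  stopifnot(length(radius) == 24 * n)
  list(species = c(co$species, rep(as.integer(species_idx), n)),
       x = c(co$x, x), y = c(co$y, y),
       axes = cbind(co$axes, matrix(radius, nrow = 24)),
       morph = c(co$morph, rep(as.integer(morph), n)),
       bleached = c(co$bleached, rep(FALSE, n)),
       msb = c(co$msb, rep(0L, n)),
       age = c(co$age, rep(0L, n)))
}

algae_new <- function() {
  list(x = numeric(0), y = numeric(0), height = numeric(0),
       diameter = numeric(0), age = integer(0))
}

algae_subset <- function(al, keep) {
  list(x = al$x[keep], y = al$y[keep], height = al$height[keep],
       diameter = al$diameter[keep], age = al$age[keep])
}

algae_add <- function(al, x, y, height, diameter, age = 0L) {
  n <- length(x)
  if (n == 0) return(al)
  list(x = c(al$x, x), y = c(al$y, y),
       height = c(al$height, rep_len(height, n)),
       diameter = c(al$diameter, rep_len(diameter, n)),
       age = c(al$age, rep_len(as.integer(age), n)))
}

turf_cell_index <- function(px, py, grid) {
  ix <- pmin(pmax(floor(px) + 1L, 1L), nrow(grid))
  iy <- pmin(pmax(floor(py) + 1L, 1L), ncol(grid))
  ix + (iy - 1L) * nrow(grid)
}

turf_cell_centers <- function(grid) {
  list(x = rep(seq_len(nrow(grid)) - 0.5, ncol(grid)),
       y = rep(seq_len(ncol(grid)) - 0.5, each = nrow(grid)))
}

coral_mean_radii <- function(co) {
  if (ncol(co$axes) == 0) return(numeric(0))
  colMeans(co$axes)
}

# core-arena algal cover in percent (zone-of-influence circles; margin
# organisms excluded from every metric)
algal_cover_pct <- function(al, arena) {
  core <- al$x >= 0 & al$x < arena[1] & al$y >= 0 & al$y < arena[2]
  sum(pi * (al$diameter[core] / 2)^2) / (arena[1] * arena[2] * 1e4) * 100
}

# -- per-concern RNG streams -------------------------------------------------

make_streams <- function(master, names = c("thermal", "disturb", "demog",
                                           "herbiv", "algae", "init")) {
  e <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(as.integer((abs(master) + i * 1000003) %% 2147483629L))
    e[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  e
}

with_stream <- function(streams, name, fun) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", streams[[name]], envir = globalenv())
  res <- fun()
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

# -- configuration ------------------------------------------------------------

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a simulation run. The
#' defaults are the standard parameterization: 40 x 40 m arena with a 10 m
#' margin, monthly time step, 10 % initial cover per coral species and 5 %
#' macroalgae, a major bleaching (hot) year every 15 years, small mechanical
#' disturbances every 12 months and large ones every 60 months, and
#' density-dependent herbivory around a 5 % macroalgal threshold.
#'
#' @param arena `c(width, height)` of the core arena, metres.
#' @param margin width of the surrounding margin in which macroalgae live
#'   but are excluded from all metrics, metres.
#' @param months simulated months per replicate.
#' @param analysis_window months from the end of the run used in summaries.
#' @param replicates number of replicate runs.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param bleaching logical: simulate temperature-driven bleaching at all?
#' @param hot_year_interval years between major (hot) bleaching years;
#'   `NULL`/`NA`/`Inf` for none.
#' @param sst_params synthetic SST generator parameters ([sst_defaults()]).
#' @param sst optional fixed `sst_series` to use instead of generating one
#'   per replicate.
#' @param disturbance a [disturbance_regime()], or `NULL` to disable.
#' @param herbivory a [herbivory_params()].
#' @param species species parameter table ([default_species_params()]).
#' @param init_coral_cover initial relative cover per coral species (0-1).
#' @param init_algal_cover initial macroalgal cover (0-1).
#' @param init_turf initial turf cover per cell (0-1).
#' @param init_max_radius_cm upper bound of the initial colony-size draw, cm.
#' @param spawning_month calendar month of the annual spawning events.
#' @param algae macroalgal life-cycle parameters ([algae_defaults()]).
#' @param turf turf parameters: `growth`, `graze_factor`, `floor`.
#' @param breakage_prob monthly branch-breakage probability.
#' @param contact_buffer_cm contact distance buffer, cm.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(arena = c(40, 40), margin = 10,
                       months = 12000, analysis_window = 6000,
                       replicates = 10, seed = 1,
                       bleaching = TRUE, hot_year_interval = 15,
                       sst_params = sst_defaults(), sst = NULL,
                       disturbance = disturbance_regime(),
                       herbivory = herbivory_params(),
                       species = default_species_params(),
                       init_coral_cover = 0.10, init_algal_cover = 0.05,
                       init_turf = 0.5, init_max_radius_cm = 25,
                       spawning_month = 3,
                       algae = algae_defaults(),
                       turf = list(growth = 1.2, graze_factor = 0.5,
                                   floor = 0.01),
                       breakage_prob = 0.005, contact_buffer_cm = 10) {
  stopifnot(all(arena > 0), margin >= 0, months >= 1,
            analysis_window >= 1, analysis_window <= months,
            replicates >= 1,
            init_coral_cover >= 0, init_coral_cover <= 1,
            init_algal_cover >= 0, init_algal_cover <= 1)
  if (is.null(disturbance))
    disturbance <- disturbance_regime(NA, NA)
  structure(list(arena = arena, margin = margin, months = months,
                 analysis_window = analysis_window, replicates = replicates,
                 seed = seed, bleaching = bleaching,
                 hot_year_interval = hot_year_interval,
                 sst_params = sst_params, sst = sst,
                 disturbance = disturbance, herbivory = herbivory,
                 species = species,
                 init_coral_cover = init_coral_cover,
                 init_algal_cover = init_algal_cover,
                 init_turf = init_turf,
                 init_max_radius_cm = init_max_radius_cm,
                 spawning_month = spawning_month,
                 algae = algae, turf = turf,
                 breakage_prob = breakage_prob,
                 contact_buffer_cm = contact_buffer_cm),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %gx%g m arena, %d months x %d replicates, ",
                     "bleaching %s (hot year every %s yr), ",
                     "disturbance small/%s large/%s months>\n"),
              x$arena[1], x$arena[2], x$months, x$replicates,
              if (x$bleaching) "on" else "off",
              format(if (is.null(x$hot_year_interval)) NA
                     else x$hot_year_interval),
              format(x$disturbance$small_interval),
              format(x$disturbance$large_interval)))
  invisible(x)
}

# -- initialization -----------------------------------------------------------

#' Initialize the community
#'
#' Places coral colonies of each species at uniform random positions, with
#' mean radii drawn uniformly between spat size and `init_max_radius_cm`,
#' until the species' cover first reaches its initial target; likewise
#' macroalgae; turf starts at a uniform cover. Uses the current RNG state
#' (the scheduler calls it inside the `init` stream).
#'
#' @param config a [sim_config()].
#' @return A community state: list with elements `corals`, `algae`, `turf`,
#'   `prev_algal_cover` and `month`.
#' @export
init_community <- function(config) {
  arena <- config$arena
  area_cm2 <- arena[1] * arena[2] * 1e4
  if (config$init_coral_cover * nrow(config$species) +
      config$init_algal_cover > 4)
    stop("infeasible initial cover demand")
  co <- corals_new()
  for (i in seq_len(nrow(config$species))) {
    sp <- config$species[i, ]
    target <- config$init_coral_cover * area_cm2
    if (target <= 0) next
    r0 <- sp$spat_size_mm / 20
    radii <- numeric(0)
    repeat {
      radii <- c(radii, stats::runif(256, r0, config$init_max_radius_cm))
      cum <- cumsum(pi * radii^2)
      if (cum[length(cum)] >= target) {
        radii <- radii[seq_len(which(cum >= target)[1])]
        break
      }
    }
    n <- length(radii)
    co <- corals_add(co, i,
                     x = stats::runif(n, 0, arena[1]),
                     y = stats::runif(n, 0, arena[2]),
                     radius = rep(radii, each = 24),
                     morph = if (sp$morphology == "massive") 0L else 1L)
  }
  al <- algae_new()
  target <- config$init_algal_cover * area_cm2
  if (target > 0) {
    diams <- numeric(0)
    repeat {
      diams <- c(diams, stats::runif(256, 5, config$algae$max_diam))
      cum <- cumsum(pi * (diams / 2)^2)
      if (cum[length(cum)] >= target) {
        diams <- diams[seq_len(which(cum >= target)[1])]
        break
      }
    }
    n <- length(diams)
    al <- algae_add(al, x = stats::runif(n, 0, arena[1]),
                    y = stats::runif(n, 0, arena[2]),
                    height = diams, diameter = diams,
                    age = sample.int(12L, n, replace = TRUE) - 1L)
  }
  turf <- matrix(config$init_turf, nrow = arena[1], ncol = arena[2])
  state <- list(corals = co, algae = al, turf = turf, month = 0L,
                prev_algal_cover = 0)
  state$prev_algal_cover <- algal_cover_pct(al, arena)
  state
}

# -- cover metrics ------------------------------------------------------------

#' Relative cover record of the current state
#'
#' Per-species relative cover in percent of the core arena: each living
#' colony contributes its full planar cover, so overlapping colonies count
#' twice and the total benthic cover (the sum over all benthic groups:
#' corals, macroalgae and turf) may exceed 100 %. Macroalgal cover uses the
#' zone-of-influence circles of core-arena algae; turf is the mean cell
#' cover. Margin organisms are excluded.
#'
#' @param state a community state ([init_community()]).
#' @param config the [sim_config()].
#' @return One-row data.frame: `month`, one column per coral species,
#'   `macroalgae`, `turf`, `total_benthic` (percent).
#' @export
relative_cover <- function(state, config) {
  cv <- cover_vector(state, config)
  out <- data.frame(month = state$month, t(cv))
  rownames(out) <- NULL
  out
}

# fast named cover vector (percent) used once per step
cover_vector <- function(state, config) {
  arena <- config$arena
  area_cm2 <- arena[1] * arena[2] * 1e4
  nsp <- nrow(config$species)
  cover <- numeric(nsp)
  co <- state$corals
  if (length(co$x) > 0) {
    pa <- pi * colMeans(co$axes)^2
    for (i in seq_len(nsp)) cover[i] <- sum(pa[co$species == i])
    cover <- cover / area_cm2 * 100
  }
  macro <- algal_cover_pct(state$algae, arena)
  turf <- mean(state$turf) * 100
  out <- c(cover, macro, turf, sum(cover) + macro + turf)
  names(out) <- c(config$species$name, "macroalgae", "turf", "total_benthic")
  out
}

# -- the monthly step ---------------------------------------------------------

# env carries the precomputed monthly thermal statistics, the disturbance
# schedule and the RNG streams for one replicate
step_community <- function(state, month, config, env) {
  sp <- config$species
  arena <- config$arena
  ext <- config$margin

  # (1) thermal check: recovery progression, then bleaching draws
  if (config$bleaching && ncol(state$corals$axes) > 0) {
    state$corals <- with_stream(env$streams, "thermal", function() {
      co <- state$corals
      rec <- co$bleached
      co$msb[rec] <- co$msb[rec] + 1L
      done <- rec & co$msb >= 6L
      co$bleached[done] <- FALSE
      co$msb[done] <- 0L
      Tstat <- env$stats[month]
      pb <- bleach_probability(Tstat, list(
        min_bleach_T = env$spv$minb[co$species],
        all_bleach_T = env$spv$allb[co$species]))
      pb[co$bleached] <- 0 # recovering colonies are immune
      newly <- stats::runif(length(pb)) < pb
      if (any(newly)) {
        pd <- death_probability(Tstat, list(
          min_death_T = env$spv$mind[co$species[newly]],
          all_death_T = env$spv$alld[co$species[newly]]))
        dies <- stats::runif(sum(newly)) < pd
        idx <- which(newly)
        co$bleached[idx[!dies]] <- TRUE
        co$msb[idx[!dies]] <- 0L
        if (any(dies)) {
          keep <- rep(TRUE, length(co$x))
          keep[idx[dies]] <- FALSE
          co <- corals_subset(co, keep)
        }
      }
      co
    })
  }

  # (2) scheduled mechanical disturbances
  ev <- env$disturbances[env$disturbances$month == month, , drop = FALSE]
  for (k in seq_len(nrow(ev))) state <- apply_disturbance(state, ev[k, ])

  # (3)+(4) competitive growth modifiers, then constrained growth
  co <- state$corals
  n <- ncol(co$axes)
  inter <- NULL
  if (n > 0) {
    perf <- rep(1, n)
    perf[co$bleached] <- co$msb[co$bleached] / 6
    base <- env$spv$growth[co$species]
    inter <- interaction_kernel(co$x * 100, co$y * 100, co$axes,
                                co$morph, co$species, perf, base,
                                state$algae$x * 100, state$algae$y * 100,
                                state$algae$diameter / 2,
                                env$sp_focal, env$sp_comp, 1.25, 0.3,
                                config$contact_buffer_cm)
    co$axes <- grow_kernel(co$axes, inter$modifiers, base * perf,
                           env$spv$maxr[co$species],
                           co$x * 100, co$y * 100,
                           arena[1] * 100, arena[2] * 100)
    co$age <- co$age + 1L
    state$corals <- co
  }

  # (5) interaction mortality: overgrowth, branch breakage, displacement
  if (n > 0) {
    thresh <- ifelse(co$morph == 1L, 0.5, 0.75)
    dead <- inter$overgrowth > thresh
    unsheltered <- co$morph == 1L & inter$shelter < 2L
    if (any(unsheltered)) {
      broke <- with_stream(env$streams, "demog", function()
        stats::runif(sum(unsheltered)) < config$breakage_prob)
      dead[which(unsheltered)[broke]] <- TRUE
    }
    if (length(state$algae$x) > 0) {
      disp <- alga_coral_kernel(state$algae$x * 100, state$algae$y * 100,
                                state$algae$diameter / 2,
                                co$x * 100, co$y * 100, colMeans(co$axes))
      dead <- dead | disp$coral_removed
      state$algae <- algae_subset(state$algae, !disp$alga_removed)
    }
    if (any(dead)) state$corals <- corals_subset(state$corals, !dead)
  }

  # (6) macroalgal life cycle, conspecific thinning, yearly recruitment
  state <- with_stream(env$streams, "algae", function() {
    al <- state$algae
    ap <- config$algae
    if (length(al$x) > 0) {
      al$age <- al$age + 1L
      al <- algae_subset(al, al$age <= ap$max_age)
    }
    frag_x <- numeric(0); frag_y <- numeric(0)
    if (length(al$x) > 0) {
      dd <- pmin(ap$growth_cm / 2, ap$max_diam - al$diameter)
      al$diameter <- al$diameter + dd
      al$height <- pmin(ap$max_height, al$height + ap$growth_cm - dd)
      nfrag <- pmax(0, floor((al$height - ap$frag_threshold) / ap$frag_loss))
      al$height <- al$height - nfrag * ap$frag_loss
      tot <- sum(nfrag)
      if (tot > 0) {
        parent <- rep(seq_along(al$x), nfrag)
        ang <- stats::runif(tot, 0, 2 * pi)
        rad <- ap$frag_dispersal_m * sqrt(stats::runif(tot))
        fx <- al$x[parent] + rad * cos(ang)
        fy <- al$y[parent] + rad * sin(ang)
        keep <- stats::runif(tot) < ap$frag_establish &
          fx >= -ext & fx <= arena[1] + ext &
          fy >= -ext & fy <= arena[2] + ext
        frag_x <- fx[keep]; frag_y <- fy[keep]
      }
      rm <- alga_alga_kernel(al$x * 100, al$y * 100, al$diameter / 2)
      al <- algae_subset(al, !rm)
    }
    new_x <- frag_x; new_y <- frag_y
    new_h <- rep(5, length(frag_x)); new_d <- rep(5, length(frag_x))
    if ((month - 1) %% 12 == 0) { # yearly algal recruitment
      rec <- algal_recruitment(arena, ap$recruit_rate_m2_yr)
      new_x <- c(new_x, rec$x); new_y <- c(new_y, rec$y)
      new_h <- c(new_h, rep(0, nrow(rec))); new_d <- c(new_d, rep(0, nrow(rec)))
    }
    if (length(new_x) > 0) {
      # arrivals die on living coral tissue (bleached or healthy)
      co2 <- state$corals
      loc <- locate_points_kernel(new_x * 100, new_y * 100,
                                  co2$x * 100, co2$y * 100, co2$axes,
                                  co2$morph, as.integer(co2$bleached),
                                  co2$msb, numeric(0), numeric(0), numeric(0))
      open <- !loc$in_healthy_coral & loc$msb_max < 0
      al <- algae_add(al, new_x[open], new_y[open],
                      height = new_h[open], diameter = new_d[open], age = 0L)
    }
    state$algae <- al
    state
  })

  # (7) herbivory: grazing probability from last month's macroalgal cover
  if (!is.null(config$herbivory)) {
    state <- with_stream(env$streams, "herbiv", function()
      apply_herbivory(state, config$herbivory, config$turf))
  }

  # (8) reproduction: stock-recruitment pool and settlement
  state <- with_stream(env$streams, "demog", function() {
    area_cm2 <- arena[1] * arena[2] * 1e4
    spv <- env$spv
    co3 <- state$corals
    rbar <- coral_mean_radii(co3)
    perf <- rep(1, length(rbar))
    perf[co3$bleached] <- co3$msb[co3$bleached] / 6
    month_of_year <- (month - 1) %% 12 + 1
    for (i in seq_len(length(spv$name))) {
      if (spv$events[i] < 12 && month_of_year != config$spawning_month) next
      sel <- co3$species == i & 2 * rbar >= spv$maturity[i]
      internal <- sum(spv$eggs[i] * 2 * pi * rbar[sel]^2 *
                        spv$sf[i] * perf[sel])
      expected <- internal * (1 + spv$conn[i]) * spv$retention[i] +
        spv$fixed[i] * area_cm2 / 1e4
      nrec <- stats::rpois(1, expected)
      if (nrec > 0) state <- settle(nrec, spv$name[i], state, config)
    }
    state
  })

  # (9) cover record and the herbivory lag
  state$month <- month
  state$prev_algal_cover <- algal_cover_pct(state$algae, arena)
  state
}

# -- full runs ----------------------------------------------------------------

#' Run the simulation
#'
#' Runs all replicates of a configuration. Replicate `r` is seeded with
#' `seed + r`; each stochastic concern (thermal, disturbance, demography,
#' herbivory, algae, initialization) draws from its own RNG stream, so
#' disabling one process does not shift another's draws. Identical
#' configurations and seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param progress print a line per replicate?
#' @return list of class `reefsim_run`: `covers` (long data.frame with
#'   `replicate`, `month`, `species`, `cover_pct`), `summary` (pooled mean
#'   and SD per species over the analysis window), and the `config`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  sp <- config$species
  nsp <- nrow(sp)
  years <- ceiling(config$months / 12)
  cover_cols <- c(sp$name, "macroalgae", "turf", "total_benthic")
  all_recs <- vector("list", config$replicates)

  for (r in seq_len(config$replicates)) {
    streams <- make_streams(config$seed + r)
    if (config$bleaching) {
      sst <- if (!is.null(config$sst)) config$sst else
        with_stream(streams, "thermal", function()
          synth_sst(years, config$hot_year_interval, config$sst_params))
      stats_m <- monthly_bleaching_statistics(sst)
    } else {
      stats_m <- rep(-Inf, config$months)
    }
    dist_df <- with_stream(streams, "disturb", function()
      schedule_disturbances(config$disturbance, config$months, config$arena))
    state <- with_stream(streams, "init", function() init_community(config))
    env <- list(streams = streams, stats = stats_m, disturbances = dist_df,
                sp_focal = match("P_lobata", sp$name),
                sp_comp = match("P_lutea", sp$name),
                spv = list(name = sp$name, growth = sp$growth_cm_month,
                           maxr = sp$max_radius_cm,
                           maturity = sp$maturity_diam_cm,
                           eggs = sp$eggs_per_cm2, sf = sp$surface_factor,
                           retention = sp$retention_factor,
                           fixed = sp$fixed_input_m2,
                           conn = sp$connectivity,
                           events = sp$events_per_year,
                           minb = sp$min_bleach_T, allb = sp$all_bleach_T,
                           mind = sp$min_death_T, alld = sp$all_death_T))
    if (is.na(env$sp_focal)) env$sp_focal <- -1L
    if (is.na(env$sp_comp)) env$sp_comp <- -1L

    rec <- matrix(0, nrow = config$months, ncol = length(cover_cols),
                  dimnames = list(NULL, cover_cols))
    for (m in seq_len(config$months)) {
      state <- step_community(state, m, config, env)
      rec[m, ] <- cover_vector(state, config)
    }
    all_recs[[r]] <- data.frame(replicate = r,
                                month = rep(seq_len(config$months),
                                            length(cover_cols)),
                                species = rep(cover_cols,
                                              each = config$months),
                                cover_pct = as.numeric(rec),
                                stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("replicate %d/%d done (final total %.1f %%)",
                      r, config$replicates,
                      rec[config$months, "total_benthic"]))
  }
  covers <- do.call(rbind, all_recs)
  out <- list(covers = covers,
              summary = summarize_covers(covers, config$analysis_window,
                                         config$months),
              config = config)
  class(out) <- "reefsim_run"
  out
}

#' @export
print.reefsim_run <- function(x, ...) {
  cat(sprintf("<reefsim_run: %d replicate(s) x %d months>\n",
              max(x$covers$replicate), max(x$covers$month)))
  cat("Pooled cover over the analysis window (%):\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Pooled cover summary over the analysis window
#'
#' Mean and SD of each cover column over the last `window` months of each
#' replicate, pooled across replicates.
#'
#' @param covers long cover table (see [run_simulation()]).
#' @param window analysis window in months, counted from the end.
#' @param months run length in months.
#' @return data.frame with `species`, `mean_cover_pct`, `sd_cover_pct`.
#' @export
summarize_covers <- function(covers, window, months = max(covers$month)) {
  sel <- covers$month > months - window
  mean_c <- tapply(covers$cover_pct[sel], covers$species[sel], mean)
  sd_c <- tapply(covers$cover_pct[sel], covers$species[sel], stats::sd)
  out <- data.frame(species = names(mean_c),
                    mean_cover_pct = as.numeric(mean_c),
                    sd_cover_pct = as.numeric(sd_c),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pielou evenness
#'
#' Shannon diversity divided by the log of richness, computed on a vector of
#' species covers (or any abundances). `NA` when fewer than two categories
#' are present.
#'
#' @param x non-negative abundances.
#' @return Evenness in \[0, 1\], or `NA`.
#' @export
pielou_evenness <- function(x) {
  x <- x[x > 0]
  if (length(x) < 2) return(NA_real_)
  vegan::diversity(x) / log(length(x))
}

#' Scenario sweeps over perturbation frequencies
#'
#' Runs one full [run_simulation()] per grid point of a perturbation axis,
#' all else held at the base configuration:
#' `"bleach"` varies the hot-year interval with mechanical disturbances
#' disabled; `"disturb"` crosses small- and large-event intervals with
#' bleaching disabled; `"combined"` varies the hot-year interval under the
#' base disturbance regime.
#'
#' @param base_config a [sim_config()].
#' @param axis `"bleach"`, `"disturb"` or `"combined"`.
#' @param bleach_intervals hot-year intervals (years) for the bleaching axes.
#' @param small_intervals,large_intervals event intervals (months) for the
#'   disturbance grid; `NA` disables a class.
#' @param progress print progress lines?
#' @return Long data.frame: axis value(s), `species`, `mean_cover_pct`,
#'   `sd_cover_pct`.
#' @export
scenario_sweep <- function(base_config,
                           axis = c("bleach", "disturb", "combined"),
                           bleach_intervals = 1:20,
                           small_intervals = c(3, 6, 12, 24, 48),
                           large_intervals = c(12, 30, 60, 120, 240),
                           progress = FALSE) {
  axis <- match.arg(axis)
  run_point <- function(cfg, meta) {
    res <- run_simulation(cfg, progress = progress)
    cbind(meta, res$summary, row.names = NULL)
  }
  out <- list()
  if (axis %in% c("bleach", "combined")) {
    for (iv in bleach_intervals) {
      cfg <- base_config
      cfg$bleaching <- TRUE
      cfg$hot_year_interval <- iv
      if (axis == "bleach") cfg$disturbance <- disturbance_regime(NA, NA)
      out[[length(out) + 1]] <-
        run_point(cfg, data.frame(bleach_interval_yr = iv))
      if (progress) message("bleach interval ", iv, " yr done")
    }
  } else {
    for (si in small_intervals) for (li in large_intervals) {
      cfg <- base_config
      cfg$bleaching <- FALSE
      cfg$disturbance <- disturbance_regime(si, li)
      out[[length(out) + 1]] <-
        run_point(cfg, data.frame(small_interval = si, large_interval = li))
      if (progress) message("disturbance ", si, "/", li, " months done")
    }
  }
  do.call(rbind, out)
}
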