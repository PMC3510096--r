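#' Create a coral colony agent
#'
#' @param species species name (row of the species table).
#' @param shape a [colony_shape()].
#' @param state `"healthy"`, `"bleached"` or `"dead"`.
#' @param months_since_bleach recovery clock, 0-6 (only for bleached).
#' @param age age in months.
#' @return list of class `coral_colony`.
#' @export
coral_colony <- function(species, shape, state = "healthy",
                         months_since_bleach = 0L, age = 0L) {
  stopifnot(state %in% c("healthy", "bleached", "dead"),
            months_since_bleach >= 0, months_since_bleach <= 6)
  structure(list(species = species, shape = shape, state = state,
                 months_since_bleach = as.integer(months_since_bleach),
                 age = as.integer(age)),
            class = "coral_colony")
}

#' Growth/interaction performance of a recovering colony
#'
#' Rates affected by bleaching (growth, interaction strength) increase
#' linearly from 0 % (full effect, just bleached) to 100 % (no effect) over
#' the 6-month recovery span.
#'
#' @param months_since_bleach months since the bleaching onset, 0-6.
#' @return Fraction in \[0, 1\].
#' @export
recovery_performance <- function(months_since_bleach) {
  if (any(months_since_bleach < 0 | months_since_bleach > 6))
    stop("months_since_bleach must be in [0, 6]")
  months_since_bleach / 6
}

#' Survival of a recruit settling on a bleached colony
#'
#' Recruits can establish on bleached tissue: survival falls linearly from
#' 100 % on a fully bleached coral to 0 % on a fully recovered one.
#'
#' @inheritParams recovery_performance
#' @return Survival probability in \[0, 1\].
#' @export
recruit_survival_on_bleached <- function(months_since_bleach) {
  if (any(months_since_bleach < 0 | months_since_bleach > 6))
    stop("months_since_bleach must be in [0, 6]")
  1 - months_since_bleach / 6
}

#' Thermal state update of one colony
#'
#' A healthy colony bleaches with [bleach_probability()]; a colony that
#' bleaches dies with [death_probability()] in the same step; a bleached
#' survivor enters the 6-month recovery. A colony already recovering is
#' immune to a second bleaching trigger until fully recovered; its recovery
#' clock advances by one month and it returns to healthy after 6 months.
#'
#' @param colony a [coral_colony()] (must be alive).
#' @param T_stat the month's 20-day thermal statistic, degC.
#' @param th the species' [thermal_thresholds()].
#' @return The updated [coral_colony()].
#' @export
thermal_update <- function(colony, T_stat, th) {
  stopifnot(colony$state != "dead")
  if (colony$state == "bleached") {
    colony$months_since_bleach <- colony$months_since_bleach + 1L
    if (colony$months_since_bleach >= 6L) {
      colony$state <- "healthy"
      colony$months_since_bleach <- 0L
    }
    return(colony)
  }
  if (stats::runif(1) < bleach_probability(T_stat, th)) {
    if (stats::runif(1) < death_probability(T_stat, th)) {
      colony$state <- "dead"
    } else {
      colony$state <- "bleached"
      colony$months_since_bleach <- 0L
    }
  }
  colony
}

#' Branch breakage survival check
#'
#' Branching colonies break off with 0.5 % monthly probability unless
#' sheltered by at least two neighbouring corals of at least their own size
#' within contact distance (centres closer than the sum of mean radii plus a
#' 10 cm buffer).
#'
#' @param colony a branching [coral_colony()].
#' @param neighbours list of [coral_colony()] agents.
#' @param breakage_prob monthly removal probability when unsheltered.
#' @param contact_buffer_cm buffer added to the contact distance, cm.
#' @return `TRUE` if the colony survives this step.
#' @export
branch_breakage <- function(colony, neighbours, breakage_prob = 0.005,
                            contact_buffer_cm = 10) {
  stopifnot(colony$shape$morphology == "branching")
  r0 <- mean_radius(colony$shape)
  n_shelter <- 0L
  for (nb in neighbours) {
    rj <- mean_radius(nb$shape)
    d_cm <- sqrt(sum((nb$shape$center - colony$shape$center)^2)) * 100
    if (d_cm <= r0 + rj + contact_buffer_cm && rj >= r0)
      n_shelter <- n_shelter + 1L
  }
  if (n_shelter >= 2L) return(TRUE)
  stats::runif(1) >= breakage_prob
}

#' Apply a mechanical disturbance event
#'
#' Kills every organism within the affected circle: coral colonies and
#' macroalgae whose centre lies inside are removed, turf cells whose centre
#' lies inside are reset to zero cover.
#'
#' @param state a community state (see [init_community()]).
#' @param event one row of [schedule_disturbances()] output (or a list with
#'   `x`, `y`, `radius` in metres).
#' @return The updated state.
#' @export
apply_disturbance <- function(state, event) {
  r2 <- event$radius^2
  if (ncol(state$corals$axes) > 0) {
    hit <- (state$corals$x - event$x)^2 + (state$corals$y - event$y)^2 <= r2
    state$corals <- corals_subset(state$corals, !hit)
  }
  if (length(state$algae$x) > 0) {
    hit <- (state$algae$x - event$x)^2 + (state$algae$y - event$y)^2 <= r2
    state$algae <- algae_subset(state$algae, !hit)
  }
  tc <- turf_cell_centers(state$turf)
  hit <- (tc$x - event$x)^2 + (tc$y - event$y)^2 <= r2
  state$turf[hit] <- 0
  state
}

#' One monthly life-cycle step of a macroalga
#'
#' Growth of 30 cm per month is split equally between height and diameter
#' until the maximum diameter (45 cm) is reached, then goes entirely to
#' height, capped at 60 cm. Above the 30 cm fragmentation threshold one
#' fragment is shed per 5 cm of excess height, and the height drops by 5 cm
#' per fragment (never below the threshold). Fragments land uniformly within
#' the dispersal radius of the parent; their subsequent establishment is
#' handled by the community scheduler.
#'
#' @param alga list with `x`, `y` (metres), `height`, `diameter` (cm),
#'   `age` (months).
#' @param params algal life-cycle parameters, see [algae_defaults()].
#' @return list with `alga` (updated, or `NULL` if it died of old age) and
#'   `fragments` (data.frame of candidate fragment positions).
#' @export
macroalga_step <- function(alga, params = algae_defaults()) {
  alga$age <- alga$age + 1L
  if (alga$age > params$max_age)
    return(list(alga = NULL,
                fragments = data.frame(x = numeric(), y = numeric())))
  dd <- min(params$growth_cm / 2, params$max_diam - alga$diameter)
  dh <- params$growth_cm - dd
  alga$diameter <- alga$diameter + dd
  alga$height <- min(params$max_height, alga$height + dh)
  nfrag <- max(0, floor((alga$height - params$frag_threshold) /
                          params$frag_loss))
  frags <- data.frame(x = numeric(), y = numeric())
  if (nfrag > 0) {
    alga$height <- alga$height - nfrag * params$frag_loss
    ang <- stats::runif(nfrag, 0, 2 * pi)
    rad <- params$frag_dispersal_m * sqrt(stats::runif(nfrag))
    frags <- data.frame(x = alga$x + rad * cos(ang),
                        y = alga$y + rad * sin(ang))
  }
  list(alga = alga, fragments = frags)
}

#' Default macroalgal life-cycle parameters
#'
#' Sargassum-like fleshy macroalgae: 30 cm total growth per month (split
#' between height and diameter), height cap 60 cm, zone-of-influence diameter
#' cap 45 cm, fragmentation from 30 cm height with 5 cm height loss per
#' fragment, 2 m fragment dispersal, 24-month lifespan, yearly recruitment of
#' 0.5 recruits per m2. `frag_establish` is the establishment probability of
#' a shed fragment, calibrated so that grazing holds an algae-only community
#' near the 5 % herbivory threshold (see the package vignette).
#'
#' @return list of parameters.
#' @export
algae_defaults <- function() {
  list(growth_cm = 30, max_height = 60, max_diam = 45,
       frag_threshold = 30, frag_loss = 5, frag_dispersal_m = 2,
       frag_establish = 0.05, max_age = 24, recruit_rate_m2_yr = 0.5)
}

#' Yearly macroalgal recruitment
#'
#' A Poisson realization of the constant recruitment rate over the core
#' arena, at uniform random positions. Called once per simulated year.
#'
#' @param arena `c(width, height)` of the core arena, metres.
#' @param rate_m2_yr recruits per m2 per year.
#' @return data.frame with recruit positions `x`, `y` (metres).
#' @export
algal_recruitment <- function(arena = c(40, 40), rate_m2_yr = 0.5) {
  n <- stats::rpois(1, rate_m2_yr * arena[1] * arena[2])
  data.frame(x = stats::runif(n, 0, arena[1]),
             y = stats::runif(n, 0, arena[2]))
}

#' Monthly turf dynamics
#'
#' Ungrazed cells grow by 20 % per month (from a small recolonization floor,
#' so scoured cells can regrow), capped at full cover; grazed cells are
#' halved.
#'
#' @param grid matrix of per-cell turf cover fractions in \[0, 1\].
#' @param grazed logical matrix (same shape) marking grazed cells.
#' @param growth monthly multiplicative growth of ungrazed cells.
#' @param graze_factor multiplicative reduction of grazed cells.
#' @param floor recolonization floor applied before growth.
#' @return The updated grid.
#' @export
turf_step <- function(grid, grazed, growth = 1.2, graze_factor = 0.5,
                      floor = 0.01) {
  out <- pmin(pmax(grid, floor) * growth, 1) # matrix first: keeps dims
  out[grazed] <- grid[grazed] * graze_factor
  out
}
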