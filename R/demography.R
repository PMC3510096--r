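#' Larval output of one colony
#'
#' A mature colony's fecundity is its gametes-or-larvae per cm2 multiplied by
#' its surface area ([surface_area()] with the species surface factor).
#' Immature colonies (mean diameter below the maturity threshold) and dead
#' colonies produce nothing; a bleached, recovering colony's output is scaled
#' by [recovery_performance()].
#'
#' @param colony a [coral_colony()].
#' @param sp one row of the species parameter table
#'   ([default_species_params()]).
#' @return Expected larvae produced by the colony this event.
#' @export
colony_fecundity <- function(colony, sp) {
  if (colony$state == "dead") return(0)
  if (2 * mean_radius(colony$shape) < sp$maturity_diam_cm) return(0)
  out <- sp$eggs_per_cm2 * surface_area(colony$shape, sp$surface_factor)
  if (colony$state == "bleached")
    out <- out * recovery_performance(colony$months_since_bleach)
  out
}

#' Expected recruit pool for one species at one recruitment event
#'
#' Internal supply is the summed colony fecundity (stock-recruitment); the
#' variable external supply is a connectivity-scaled multiple of it (nearby
#' reefs assumed statistically similar to the focal patch). Both larval terms
#' are multiplied by the species retention factor, which folds fertilization
#' success, predation, larval retention and early mortality into
#' recruits-per-larva. On top of this, a constant external input of
#' already-settled recruits per m2 per event enters independently of the
#' local stock — the rescue term that lets a locally extinct species
#' re-enter.
#'
#' @param colonies list of [coral_colony()] agents of the species (or an
#'   already-summed internal larval output as a single number).
#' @param sp one row of [default_species_params()].
#' @param arena_area_cm2 core arena area in cm2.
#' @return Expected (mean) number of recruits; the realized count is a
#'   Poisson draw of this mean.
#' @export
recruit_pool <- function(colonies, sp, arena_area_cm2) {
  internal <- if (is.numeric(colonies)) sum(colonies)
              else sum(vapply(colonies, colony_fecundity, numeric(1), sp = sp))
  internal * (1 + sp$connectivity) * sp$retention_factor +
    sp$fixed_input_m2 * arena_area_cm2 / 1e4
}

#' Is this month a recruitment event for the species?
#'
#' Brooders (12 events per year) recruit every month; annual spawners once a
#' year in the configured spawning month.
#'
#' @param sp one row of [default_species_params()].
#' @param month_index month of the simulation (1-based).
#' @param spawning_month calendar month (1-12) of the annual spawning event.
#' @return logical.
#' @export
reproduction_schedule <- function(sp, month_index, spawning_month = 3) {
  if (sp$events_per_year >= 12) return(TRUE)
  (month_index - 1) %% 12 + 1 == spawning_month
}

#' Settle recruits onto the community
#'
#' Each recruit receives a uniform random position in the core arena. It dies
#' if it lands inside a healthy coral or a macroalgal zone of influence; on a
#' bleached, recovering coral it survives with
#' [recruit_survival_on_bleached()] (the most-recovered covering colony
#' decides); on free ground it dies with probability equal to the local turf
#' cover. Survivors become colonies at spat size.
#'
#' @param recruits number of settling recruits.
#' @param species species name.
#' @param state a community state (see [init_community()]).
#' @param config the simulation configuration ([sim_config()]).
#' @return The state with the surviving recruits added.
#' @export
settle <- function(recruits, species, state, config) {
  if (recruits <= 0) return(state)
  arena <- config$arena
  px <- stats::runif(recruits, 0, arena[1])
  py <- stats::runif(recruits, 0, arena[2])
  co <- state$corals
  loc <- locate_points_kernel(px * 100, py * 100,
                              co$x * 100, co$y * 100, co$axes,
                              co$morph, as.integer(co$bleached), co$msb,
                              state$algae$x * 100, state$algae$y * 100,
                              state$algae$diameter / 2)
  u <- stats::runif(recruits)
  on_bleached <- loc$msb_max >= 0
  surv <- !loc$in_healthy_coral & !loc$in_alga
  surv[surv & on_bleached] <-
    u[surv & on_bleached] <
      recruit_survival_on_bleached(loc$msb_max[surv & on_bleached])
  # free ground: turf mortality proportional to cover
  free <- surv & !on_bleached
  cell <- turf_cell_index(px, py, state$turf)
  surv[free] <- stats::runif(sum(free)) >= state$turf[cell[free]]
  if (!any(surv)) return(state)
  sp <- config$species[config$species$name == species, ]
  r0 <- sp$spat_size_mm / 20 # spat diameter (mm) -> radius (cm)
  state$corals <- corals_add(state$corals,
                             species_idx = match(species, config$species$name),
                             x = px[surv], y = py[surv], radius = r0,
                             morph = ifelse(sp$morphology == "massive", 0L, 1L))
  state
}
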