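#' Herbivory (grazing) parameters
#'
#' Parameters of the density-dependent grazing response: the grazing
#' probability per organism per month rises logistically from `gp_min` to
#' `gp_max` around the critical algal cover `algal_t`, with slope `z`.
#'
#' @param gp_min,gp_max lower and upper bounds of the grazing probability.
#' @param algal_t critical macroalgal cover, percent.
#' @param z slope of the logistic reaction.
#' @return list of class `herbivory_params`.
#' @export
herbivory_params <- function(gp_min = 0.2, gp_max = 0.3, algal_t = 5,
                             z = 2.0) {
  stopifnot(gp_min < gp_max, gp_min >= 0, gp_max <= 1, z > 0, algal_t >= 0)
  structure(list(gp_min = gp_min, gp_max = gp_max, algal_t = algal_t, z = z),
            class = "herbivory_params")
}

#' Density-dependent grazing probability
#'
#' Logistic response through three anchors: the midpoint
#' `(gp_min + gp_max) / 2` at the critical cover, and the bounds `gp_min`
#' and `gp_max` at very low and very high cover.
#'
#' @param algal_cp macroalgal cover, percent (>= 0).
#' @param hp a [herbivory_params()].
#' @return Grazing probability, strictly within `(gp_min, gp_max)`.
#' @export
grazing_probability <- function(algal_cp, hp = herbivory_params()) {
  stopifnot(all(algal_cp >= 0))
  hp$gp_min + (hp$gp_max - hp$gp_min) /
    (1 + exp(-hp$z * (algal_cp - hp$algal_t)))
}

#' Pairwise competitive growth multiplier
#'
#' The growth-rate multiplier a focal organism experiences on axes in contact
#' with a competitor. Outcomes depend on the morphology pair and on which
#' individual is larger (by mean diameter; ties count as smaller):
#' massive vs massive 0.9 / 0.0, massive vs branching 1.0 / 0.3,
#' branching vs massive always 0.0, branching vs branching 0.7 / 0.3,
#' any coral vs macroalga 1.0 / 0.7, and macroalgae themselves are never
#' growth-inhibited. One species-specific override reflects a competitive
#' index: *P. lobata* retains 30 % of its growth against a larger *P. lutea*
#' whose diameter is less than 25 % bigger than its own.
#'
#' @param focal,competitor lists with `type` (`"coral"` or `"alga"`),
#'   `morphology` (`"massive"`/`"branching"`, corals only), `species`
#'   (corals only) and `diameter` (cm).
#' @param special species-specific override,
#'   `list(focal, competitor, ratio, mult)`.
#' @return Multiplier in \[0, 1\].
#' @export
growth_modifier <- function(focal, competitor,
                            special = list(focal = "P_lobata",
                                           competitor = "P_lutea",
                                           ratio = 1.25, mult = 0.3)) {
  if (identical(focal$type, "alga")) return(1.0)
  bigger <- focal$diameter > competitor$diameter
  if (identical(competitor$type, "alga"))
    return(if (bigger) 1.0 else 0.7)
  fm <- focal$morphology
  cm <- competitor$morphology
  if (fm == "massive" && cm == "massive") {
    if (bigger) return(0.9)
    if (identical(focal$species, special$focal) &&
        identical(competitor$species, special$competitor) &&
        competitor$diameter < special$ratio * focal$diameter)
      return(special$mult)
    return(0.0)
  }
  if (fm == "massive" && cm == "branching") return(if (bigger) 1.0 else 0.3)
  if (fm == "branching" && cm == "massive") return(0.0)
  if (fm == "branching" && cm == "branching") return(if (bigger) 0.7 else 0.3)
  stop("unknown morphology pair: ", fm, " vs ", cm)
}

#' Per-axis growth modifiers of one colony against its neighbourhood
#'
#' For each of the 24 axes the modifier is the minimum [growth_modifier()]
#' over all organisms whose footprint the axis's next endpoint (current
#' extent plus one base growth step) would enter; axes without contact get
#' 1.0. The competitive effect of a recovering (bleached) neighbour is scaled
#' down by its [recovery_performance()].
#'
#' @param colony a [coral_colony()].
#' @param neighbours list of [coral_colony()] agents and/or macroalgae
#'   (`list(x, y, diameter)`, metres/cm).
#' @param base_rate the focal species' base radial growth step, cm.
#' @param species species parameter table.
#' @return Numeric length-24 vector of multipliers.
#' @export
resolve_axis_modifiers <- function(colony, neighbours, base_rate,
                                   species = default_species_params()) {
  corals <- Filter(function(o) inherits(o, "coral_colony"), neighbours)
  algae <- Filter(function(o) !inherits(o, "coral_colony"), neighbours)
  all_corals <- c(list(colony), corals)
  x <- vapply(all_corals, function(c) c$shape$center[1], numeric(1)) * 100
  y <- vapply(all_corals, function(c) c$shape$center[2], numeric(1)) * 100
  A <- vapply(all_corals, function(c) c$shape$axes, numeric(24))
  morph <- vapply(all_corals, function(c)
    if (c$shape$morphology == "massive") 0L else 1L, integer(1))
  spi <- vapply(all_corals, function(c)
    match(c$species, species$name), integer(1))
  perf <- vapply(all_corals, function(c)
    if (c$state == "bleached") recovery_performance(c$months_since_bleach)
    else 1.0, numeric(1))
  gx <- vapply(algae, function(a) a$x, numeric(1)) * 100
  gy <- vapply(algae, function(a) a$y, numeric(1)) * 100
  gr <- vapply(algae, function(a) a$diameter / 2, numeric(1))
  res <- interaction_kernel(x, y, A, morph, spi, perf,
                            rep(base_rate, length(all_corals)),
                            gx, gy, gr,
                            match("P_lobata", species$name),
                            match("P_lutea", species$name),
                            1.25, 0.3, 10.0)
  res$modifiers[, 1]
}

#' Overgrowth mortality check
#'
#' A colony dies when more than half (branching) or three quarters (massive)
#' of its size is overgrown by other organisms; thresholds are strict.
#'
#' @param colony a [coral_colony()], or `NULL` if `fraction`/`morphology`
#'   are given directly.
#' @param others list of neighbouring footprints (see
#'   [overgrowth_fraction()]); ignored when `fraction` is supplied.
#' @param fraction optionally, a pre-computed overgrowth fraction.
#' @param morphology used with `fraction`.
#' @return `TRUE` if the colony dies of overgrowth.
#' @export
overgrowth_death_check <- function(colony = NULL, others = list(),
                                   fraction = NULL, morphology = NULL) {
  if (is.null(fraction)) {
    fraction <- overgrowth_fraction(colony$shape, others)
    morphology <- colony$shape$morphology
  }
  threshold <- if (morphology == "branching") 0.5 else 0.75
  fraction > threshold
}

#' Macroalga vs coral displacement
#'
#' Macroalgae overgrow smaller coral colonies and are overgrown by larger
#' colonies; the competitively inferior individual (the one with the smaller
#' diameter) is removed once it is actually overgrown, i.e. its centre lies
#' within the larger one's footprint (the alga's zone-of-influence circle,
#' or the coral's mean-radius circle). Mere touching has no lethal effect.
#'
#' @param alga `list(x, y, diameter)` (metres, cm).
#' @param coral a [coral_colony()].
#' @return `"remove_coral"`, `"remove_alga"`, or `"none"`.
#' @export
alga_coral_displacement <- function(alga, coral) {
  rbar <- mean_radius(coral$shape)
  d_cm <- sqrt(sum((c(alga$x, alga$y) - coral$shape$center)^2)) * 100
  if (alga$diameter > 2 * rbar) {
    if (d_cm < alga$diameter / 2) "remove_coral" else "none"
  } else {
    if (d_cm < rbar) "remove_alga" else "none"
  }
}

#' Apply one month of herbivory
#'
#' The grazing probability is computed from the macroalgal cover of the
#' *previous* step (`state$prev_algal_cover`), so grazing pressure lags cover
#' by one month. Each macroalga is removed with that probability; each turf
#' cell is independently marked grazed and halved, ungrazed cells grow (see
#' [turf_step()]).
#'
#' @param state a community state ([init_community()]).
#' @param hp a [herbivory_params()].
#' @param turf_params list with `growth`, `graze_factor`, `floor`.
#' @return The updated state.
#' @export
apply_herbivory <- function(state, hp = herbivory_params(),
                            turf_params = list(growth = 1.2,
                                               graze_factor = 0.5,
                                               floor = 0.01)) {
  gp <- grazing_probability(state$prev_algal_cover, hp)
  al <- state$algae
  if (length(al$x) > 0)
    al <- algae_subset(al, stats::runif(length(al$x)) >= gp)
  grazed <- matrix(stats::runif(length(state$turf)) < gp,
                   nrow = nrow(state$turf))
  state$turf <- turf_step(state$turf, grazed, turf_params$growth,
                          turf_params$graze_factor, turf_params$floor)
  state$algae <- al
  state
}

#' Macroalga vs macroalga competition
#'
#' The smaller of two conspecific algae dies if at least half of its zone of
#' influence is shared with the larger one.
#'
#' @param a,b `list(x, y, diameter)` (metres, cm).
#' @return `"remove_a"`, `"remove_b"`, or `"none"`.
#' @export
alga_alga_competition <- function(a, b) {
  res <- alga_alga_kernel(c(a$x, b$x) * 100, c(a$y, b$y) * 100,
                          c(a$diameter, b$diameter) / 2)
  if (res[1]) "remove_a" else if (res[2]) "remove_b" else "none"
}
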