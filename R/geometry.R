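#' Coral colony shape
#'
#' A colony is a 24-point star: 24 axis lengths, one per direction
#' `k * 15` degrees (k = 0..23), around a fixed centre. For massive
#' morphologies the footprint is the polygon joining the axis endpoints;
#' for branching morphologies the star itself is the footprint and cover is
#' derived from the mean radius only.
#'
#' @param center numeric length-2, arena coordinates in metres.
#' @param axes numeric length-24, axis lengths in cm (all >= 0).
#' @param morphology `"massive"` or `"branching"`.
#' @return An object of class `colony_shape`.
#' @export
colony_shape <- function(center, axes, morphology = c("massive", "branching")) {
  morphology <- match.arg(morphology)
  stopifnot(length(center) == 2, length(axes) == 24, all(axes >= 0),
            all(is.finite(axes)))
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 morphology = morphology),
            class = "colony_shape")
}

#' @export
print.colony_shape <- function(x, ...) {
  cat(sprintf("<colony_shape %s at (%.2f, %.2f) m, mean radius %.2f cm>\n",
              x$morphology, x$center[1], x$center[2], mean_radius(x)))
  invisible(x)
}

# unit direction of axis k (1-based index)
axis_directions <- function() {
  k <- 0:23
  cbind(cos(k * pi / 12), sin(k * pi / 12))
}

#' Mean radius of a colony
#'
#' Arithmetic mean of the 24 axis lengths; the size measure from which cover
#' and surface area are derived.
#'
#' @param shape a [colony_shape()].
#' @return Mean radius in cm.
#' @export
mean_radius <- function(shape) mean(shape$axes)

#' Planar cover of a colony
#'
#' The area a colony occupies on the reef plane, `pi * rbar^2` with `rbar`
#' the mean radius. The same formula is used for both morphologies because
#' cover is tied to the average radius.
#'
#' @param shape a [colony_shape()].
#' @return Cover in cm2.
#' @export
planar_cover <- function(shape) pi * mean_radius(shape)^2

#' Colony surface area
#'
#' Hemispherical surface over the mean radius, scaled by the species-specific
#' surface factor that accounts for morphology (branching colonies expose far
#' more tissue per unit footprint than a smooth hemisphere).
#'
#' @param shape a [colony_shape()].
#' @param surface_factor dimensionless, > 0.
#' @return Surface area in cm2.
#' @export
surface_area <- function(shape, surface_factor) {
  stopifnot(surface_factor > 0)
  2 * pi * mean_radius(shape)^2 * surface_factor
}

#' Point-in-footprint test
#'
#' Whether a point lies inside a colony's footprint: inside the endpoint
#' polygon for massive colonies, or within the interpolated star reach along
#' the point's bearing for branching colonies.
#'
#' @param shape a [colony_shape()].
#' @param p numeric length-2 point (metres) or a 2-column matrix of points.
#' @return Logical, one per point.
#' @export
contains_point <- function(shape, p) {
  p <- matrix(as.numeric(p), ncol = 2)
  contains_point_kernel(shape$center[1] * 100, shape$center[2] * 100,
                        shape$axes,
                        if (shape$morphology == "massive") 0L else 1L,
                        p[, 1] * 100, p[, 2] * 100)
}

#' Constrained radial growth
#'
#' Extends each axis by `base_rate` times its per-axis modifier, then applies
#' two clamps: no axis may exceed the species maximum radius, and any axis
#' whose endpoint would cross the arena border may not exceed the colony's
#' (pre-growth) mean radius. Axes never shrink.
#'
#' @param shape a [colony_shape()].
#' @param base_rate radial extension for one time step, cm (>= 0).
#' @param modifiers numeric length-24, per-axis multipliers in \[0, 1\].
#' @param species_max_radius cm.
#' @param arena numeric length-4 `c(xmin, ymin, xmax, ymax)` in metres.
#' @return The grown [colony_shape()].
#' @export
grow <- function(shape, base_rate, modifiers, species_max_radius,
                 arena = c(0, 0, 40, 40)) {
  stopifnot(base_rate >= 0, length(modifiers) == 24,
            all(modifiers >= 0), all(modifiers <= 1))
  rbar <- mean_radius(shape)
  new_axes <- pmin(shape$axes + base_rate * modifiers, species_max_radius)
  dirs <- axis_directions()
  ex <- shape$center[1] + new_axes * dirs[, 1] / 100
  ey <- shape$center[2] + new_axes * dirs[, 2] / 100
  outside <- ex < arena[1] | ex > arena[3] | ey < arena[2] | ey > arena[4]
  new_axes[outside] <- pmax(shape$axes[outside],
                            pmin(new_axes[outside], rbar))
  shape$axes <- pmax(shape$axes, new_axes)
  shape
}

#' Fraction of a colony overgrown by neighbours
#'
#' Endpoint-sampling proxy for areal overgrowth: the fraction of the 24 axis
#' endpoints lying inside at least one other organism's footprint.
#'
#' @param shape a [colony_shape()].
#' @param others list of footprints; each element a [colony_shape()], a
#'   [coral_colony()] (its shape is used), or a circle
#'   `list(center = c(x, y) metres, radius = cm)` (a macroalgal zone of
#'   influence).
#' @return Fraction in \[0, 1\].
#' @export
overgrowth_fraction <- function(shape, others) {
  if (length(others) == 0) return(0)
  dirs <- axis_directions()
  ex <- shape$center[1] + shape$axes * dirs[, 1] / 100
  ey <- shape$center[2] + shape$axes * dirs[, 2] / 100
  covered <- rep(FALSE, 24)
  for (o in others) {
    if (inherits(o, "coral_colony")) o <- o$shape
    if (inherits(o, "colony_shape")) {
      covered <- covered | contains_point(o, cbind(ex, ey))
    } else {
      d2 <- (ex - o$center[1])^2 + (ey - o$center[2])^2
      covered <- covered | d2 <= (o$radius / 100)^2
    }
  }
  mean(covered)
}
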