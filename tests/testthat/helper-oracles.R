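# Independent oracles and small builders shared across the test suite.

# winding-number point-in-polygon test, written independently of the C++
# crossing-number implementation
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    ang <- 0
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      a1 <- atan2(vy[k] - py[i], vx[k] - px[i])
      a2 <- atan2(vy[k2] - py[i], vx[k2] - px[i])
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
    }
    abs(ang) > pi # winding number != 0
  }, logical(1))
}

# footprint oracle for a colony shape: massive = exact 24-gon via winding
# numbers, branching = a fine polygon approximation of the interpolated star
oracle_in_shape <- function(shape, px, py) {
  dirs <- reefsim:::axis_directions()
  if (shape$morphology == "massive") {
    vx <- shape$center[1] + shape$axes * dirs[, 1] / 100
    vy <- shape$center[2] + shape$axes * dirs[, 2] / 100
    oracle_in_polygon(px, py, vx, vy)
  } else {
    th <- seq(0, 2 * pi, length.out = 2401)[-2401]
    pos <- th / (pi / 12)
    k <- floor(pos); f <- pos - k
    r <- shape$axes[k %% 24 + 1] * (1 - f) + shape$axes[(k + 1) %% 24 + 1] * f
    vx <- shape$center[1] + r * cos(th) / 100
    vy <- shape$center[2] + r * sin(th) / 100
    oracle_in_polygon(px, py, vx, vy)
  }
}

# shoelace polygon area (cm2) of the massive 24-gon
oracle_polygon_area <- function(shape) {
  dirs <- reefsim:::axis_directions()
  vx <- shape$axes * dirs[, 1]
  vy <- shape$axes * dirs[, 2]
  n <- length(vx)
  j <- c(2:n, 1)
  abs(sum(vx * vy[j] - vx[j] * vy)) / 2
}

# brute-force hottest 20-day window mean among windows ending in [d1, d2]
oracle_window_stat <- function(temp, d1, d2, window = 20) {
  max(vapply(d1:d2, function(e) mean(temp[(e - window + 1):e]), numeric(1)))
}

# circle-circle lens area, coded independently of the C++ kernel
oracle_lens_area <- function(d, R, r) {
  if (d >= R + r) return(0)
  if (d <= R - r) return(pi * r^2)
  p1 <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r))
  p2 <- R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R))
  p3 <- sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R)) / 2
  p1 + p2 - p3
}

# builders --------------------------------------------------------------------

make_shape <- function(r = 10, center = c(20, 20), morphology = "massive") {
  colony_shape(center, rep(r, 24), morphology)
}

make_colony <- function(species = "P_lutea", r = 10, center = c(20, 20),
                        state = "healthy", msb = 0) {
  morph <- if (species %in% c("P_lobata", "P_lutea")) "massive" else "branching"
  coral_colony(species, make_shape(r, center, morph), state = state,
               months_since_bleach = msb)
}

species_row <- function(name, params = default_species_params()) {
  params[params$name == name, ]
}

# tolerance for a binomial proportion: allow +/- z sd of sampling noise
binom_tol <- function(p, n, z = 4) z * sqrt(p * (1 - p) / n)

# a small, fast configuration for whole-simulation tests
small_config <- function(...) {
  args <- utils::modifyList(list(arena = c(20, 20), months = 120,
                                 analysis_window = 60, replicates = 1,
                                 seed = 7),
                            list(...))
  do.call(sim_config, args)
}

# enumerate the full competitive interaction table
interaction_table_cases <- function() {
  co <- function(m, d, spn) list(type = "coral", morphology = m,
                                 diameter = d, species = spn)
  al <- function(d) list(type = "alga", diameter = d)
  list(
    list(co("massive", 40, "P_lutea"),   co("massive", 20, "P_lutea"),   0.9),
    list(co("massive", 20, "P_lutea"),   co("massive", 40, "P_lutea"),   0.0),
    list(co("massive", 40, "P_lutea"),   co("branching", 20, "A_muricata"), 1.0),
    list(co("massive", 20, "P_lutea"),   co("branching", 40, "A_muricata"), 0.3),
    list(co("branching", 40, "A_muricata"), co("massive", 20, "P_lutea"), 0.0),
    list(co("branching", 20, "A_muricata"), co("massive", 40, "P_lutea"), 0.0),
    list(co("branching", 40, "A_muricata"), co("branching", 20, "P_damicornis"), 0.7),
    list(co("branching", 20, "A_muricata"), co("branching", 40, "P_damicornis"), 0.3),
    list(co("massive", 40, "P_lutea"),   al(20), 1.0),
    list(co("massive", 20, "P_lutea"),   al(40), 0.7),
    list(co("branching", 40, "A_muricata"), al(20), 1.0),
    list(co("branching", 20, "A_muricata"), al(40), 0.7),
    list(al(20), co("massive", 40, "P_lutea"), 1.0),
    list(al(40), co("massive", 20, "P_lutea"), 1.0),
    list(al(20), al(40), 1.0),
    # competition index: P. lobata vs a larger P. lutea less than 25% bigger
    list(co("massive", 40, "P_lobata"), co("massive", 48, "P_lutea"), 0.3),
    list(co("massive", 40, "P_lobata"), co("massive", 50, "P_lutea"), 0.0),
    list(co("massive", 40, "P_lobata"), co("massive", 44, "P_lobata"), 0.0),
    list(co("massive", 40, "P_lutea"),  co("massive", 44, "P_lobata"), 0.0)
  )
}
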