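
test_that("growth_modifier reproduces the full interaction table", {
  for (cs in interaction_table_cases())
    expect_equal(growth_modifier(cs[[1]], cs[[2]]), cs[[3]])
  # ties count as the inferior branch
  tie <- list(type = "coral", morphology = "massive", diameter = 30,
              species = "P_lutea")
  expect_equal(growth_modifier(tie, tie), 0.0)
})

test_that("per-axis modifiers take the minimum over contacted competitors", {
  focal <- make_colony("P_lutea", r = 20, center = c(20, 20))
  expect_equal(resolve_axis_modifiers(focal, list(), 0.11), rep(1, 24))
  # fully enclosed by a larger massive: every axis stops
  big <- make_colony("P_lobata", r = 200, center = c(20, 20))
  expect_equal(resolve_axis_modifiers(focal, list(big), 0.11), rep(0, 24))
  # two competitors on opposite sides: only the facing axes react
  east <- make_colony("P_lobata", r = 50, center = c(20.7, 20))
  west <- list(x = 19.55, y = 20, diameter = 60) # macroalga
  got <- resolve_axis_modifiers(focal, list(east, west), 0.11)
  dirs <- reefsim:::axis_directions()
  nxt <- 20 + (20 + 0.11) * dirs / 100
  in_east <- oracle_in_shape(east$shape, nxt[, 1], nxt[, 2])
  in_west <- (nxt[, 1] - 19.55)^2 + (nxt[, 2] - 20)^2 <= 0.3^2
  want <- pmin(ifelse(in_east, 0, 1),  # smaller massive vs larger massive
               ifelse(in_west, 0.7, 1)) # smaller coral vs larger alga
  expect_equal(got, want)
  expect_true(any(got < 1) && any(got == 1))
})

test_that("a recovering competitor exerts a weakened effect", {
  focal <- make_colony("P_lutea", r = 20, center = c(20, 20))
  big <- make_colony("P_lobata", r = 200, center = c(20, 20),
                     state = "bleached", msb = 3)
  # half recovered: modifier 0 relaxes to 1 - (1 - 0) * 0.5 = 0.5
  expect_equal(resolve_axis_modifiers(focal, list(big), 0.11), rep(0.5, 24))
})

test_that("overgrowth death thresholds are strict and morphology-specific", {
  expect_false(overgrowth_death_check(fraction = 0.5,
                                      morphology = "branching"))
  expect_true(overgrowth_death_check(fraction = 13 / 24,
                                     morphology = "branching"))
  expect_false(overgrowth_death_check(fraction = 0.70,
                                      morphology = "massive"))
  expect_false(overgrowth_death_check(fraction = 0.75,
                                      morphology = "massive"))
  expect_true(overgrowth_death_check(fraction = 19 / 24,
                                     morphology = "massive"))
  # through the geometric path
  small <- make_colony("P_damicornis", r = 10, center = c(20, 20))
  giant <- make_colony("P_lutea", r = 100, center = c(20, 20))
  expect_true(overgrowth_death_check(small, list(giant)))
  expect_false(overgrowth_death_check(small, list()))
})

test_that("alga-coral displacement removes the overgrown inferior", {
  spat <- make_colony("P_lutea", r = 0.1, center = c(10, 10))
  alga <- list(x = 10.05, y = 10, diameter = 40)
  expect_equal(alga_coral_displacement(alga, spat), "remove_coral")
  big <- make_colony("P_lutea", r = 50, center = c(10, 10))
  expect_equal(alga_coral_displacement(list(x = 10.3, y = 10, diameter = 10),
                                       big), "remove_alga")
  expect_equal(alga_coral_displacement(list(x = 15, y = 10, diameter = 10),
                                       big), "none")
  # touching without centre containment is not lethal
  expect_equal(alga_coral_displacement(list(x = 10.55, y = 10, diameter = 20),
                                       big), "none")
})

test_that("conspecific algal competition kills at the 50% shared-zone point", {
  a <- list(x = 10, y = 10, diameter = 40)   # the larger
  b <- list(x = 10, y = 10, diameter = 20)   # concentric smaller: 100% shared
  expect_equal(alga_alga_competition(a, b), "remove_b")
  expect_equal(alga_alga_competition(b, a), "remove_a")
  far <- list(x = 11, y = 10, diameter = 20)
  expect_equal(alga_alga_competition(a, far), "none")
  # threshold distance solved from the closed-form lens area
  R <- 20; r <- 10
  dstar <- uniroot(function(d) oracle_lens_area(d, R, r) - 0.5 * pi * r^2,
                   c(R - r + 1e-6, R + r - 1e-6))$root
  just_in <- list(x = 10 + (dstar - 0.2) / 100, y = 10, diameter = 20)
  just_out <- list(x = 10 + (dstar + 0.2) / 100, y = 10, diameter = 20)
  expect_equal(alga_alga_competition(a, just_in), "remove_b")
  expect_equal(alga_alga_competition(a, just_out), "none")
})

test_that("displacement is antisymmetric over random pairs", {
  set.seed(17)
  for (i in 1:200) {
    a <- list(x = runif(1, 9.8, 10.2), y = runif(1, 9.8, 10.2),
              diameter = runif(1, 5, 45))
    b <- list(x = runif(1, 9.8, 10.2), y = runif(1, 9.8, 10.2),
              diameter = runif(1, 5, 45))
    out <- alga_alga_competition(a, b)
    expect_true(out %in% c("remove_a", "remove_b", "none"))
    if (out != "none") {
      smaller <- if (a$diameter < b$diameter) "remove_a" else "remove_b"
      expect_equal(out, smaller)
    }
  }
})

test_that("grazing probability follows the anchored logistic", {
  hp <- herbivory_params()
  expect_equal(grazing_probability(5, hp), 0.25)
  expect_equal(grazing_probability(0, hp), 0.2, tolerance = 1e-4)
  expect_equal(grazing_probability(100, hp), 0.3, tolerance = 1e-8)
  cps <- seq(0, 20, by = 0.5)
  gp <- grazing_probability(cps, hp)
  expect_true(all(diff(gp) > 0)) # strictly increasing on the working range
  expect_true(all(gp > hp$gp_min & gp < hp$gp_max))
  # far beyond the threshold the curve saturates numerically at the bounds
  wide <- grazing_probability(seq(0, 100, by = 1), hp)
  expect_true(all(wide >= hp$gp_min & wide <= hp$gp_max))
  expect_equal(grazing_probability(hp$algal_t, hp),
               (hp$gp_min + hp$gp_max) / 2)
  expect_error(grazing_probability(-1, hp))
})

test_that("herbivory removes algae at the lagged grazing probability", {
  st <- init_community(small_config(init_coral_cover = 0,
                                    init_algal_cover = 0))
  n <- 10000
  st$algae <- reefsim:::algae_add(reefsim:::algae_new(),
                                  x = runif(n, 0, 20), y = runif(n, 0, 20),
                                  height = 30, diameter = 10)
  st$prev_algal_cover <- 5 # lagged cover drives GP = 0.25
  set.seed(40)
  out <- apply_herbivory(st)
  removed <- 1 - length(out$algae$x) / n
  expect_lt(abs(removed - 0.25), binom_tol(0.25, n))
  # the lag: current cover does not enter this month's grazing draw
  st2 <- st
  st2$prev_algal_cover <- 90 # GP ~ 0.3 regardless of the same current algae
  set.seed(41)
  out2 <- apply_herbivory(st2)
  expect_lt(abs(1 - length(out2$algae$x) / n - 0.3), binom_tol(0.3, n))
  # empty state is a no-op for algae
  empty <- init_community(small_config(init_coral_cover = 0,
                                       init_algal_cover = 0))
  expect_length(apply_herbivory(empty)$algae$x, 0)
})
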