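test_that("thermal update follows the bleach / die / recover state machine", {
  th <- thermal_thresholds("P_lutea")
  col <- make_colony("P_lutea", r = 20)
  set.seed(1)
  # below the onset nothing happens
  expect_identical(thermal_update(col, 29.0, th)$state, "healthy")
  # P. damicornis at 31: bleaches with probability 1 and dies with
  # probability 1 (all-bleach at 31, all-die at 30.4)
  pd <- make_colony("P_damicornis", r = 10)
  out <- thermal_update(pd, 31, thermal_thresholds("P_damicornis"))
  expect_identical(out$state, "dead")
  # recovery progresses monthly and ends after 6 months
  b <- make_colony("P_lutea", r = 20, state = "bleached", msb = 0)
  for (m in 1:5) {
    b <- thermal_update(b, 35, th) # immune while recovering, even at 35 degC
    expect_identical(b$state, "bleached")
    expect_equal(b$months_since_bleach, m)
  }
  b <- thermal_update(b, 20, th)
  expect_identical(b$state, "healthy")
})

test_that("bleaching incidence matches the binomial rate at the onset", {
  th <- thermal_thresholds("P_lobata")
  set.seed(42)
  n <- 10000
  outcomes <- vapply(seq_len(n), function(i) {
    thermal_update(make_colony("P_lobata", r = 20), 29.9, th)$state
  }, character(1))
  affected <- mean(outcomes != "healthy") # bleached at 0.30, some then die
  expect_lt(abs(affected - 0.30), binom_tol(0.3, n))
})

test_that("recovery performance and recruit survival are linear mirrors", {
  expect_equal(recovery_performance(0), 0)
  expect_equal(recovery_performance(6), 1)
  expect_equal(recovery_performance(3), 0.5)
  expect_equal(recruit_survival_on_bleached(0), 1)
  expect_equal(recruit_survival_on_bleached(6), 0)
  expect_equal(recruit_survival_on_bleached(3), 0.5)
  for (m in 0:6)
    expect_equal(recovery_performance(m) + recruit_survival_on_bleached(m), 1)
  expect_error(recovery_performance(7))
  expect_error(recruit_survival_on_bleached(-1))
})

test_that("branch breakage spares sheltered colonies and removes 0.5% of isolated ones", {
  focal <- make_colony("A_muricata", r = 20, center = c(10, 10))
  nb <- list(make_colony("A_muricata", r = 25, center = c(10.3, 10)),
             make_colony("P_lutea", r = 30, center = c(9.7, 10)))
  set.seed(2)
  expect_true(all(vapply(1:300, function(i)
    branch_breakage(focal, nb), logical(1))))
  # a single same-size neighbour is not enough
  n <- 6000
  set.seed(3)
  lost <- mean(!vapply(seq_len(n), function(i)
    branch_breakage(focal, nb[1]), logical(1)))
  expect_lt(abs(lost - 0.005), binom_tol(0.005, n))
  # neighbours must be at least the focal size and within contact distance
  small <- list(make_colony("A_muricata", r = 5, center = c(10.2, 10)),
                make_colony("A_muricata", r = 5, center = c(9.8, 10)))
  set.seed(4)
  lost <- mean(!vapply(seq_len(n), function(i)
    branch_breakage(focal, small), logical(1)))
  expect_gt(lost, 0.001)
  expect_error(branch_breakage(make_colony("P_lutea"), nb))
})

test_that("disturbance events kill exactly the organisms inside the circle", {
  cfg <- small_config()
  set.seed(10)
  state <- init_community(cfg)
  ev <- list(x = 10, y = 10, radius = 4)
  before <- state
  after <- apply_disturbance(state, ev)
  keep_oracle <- (before$corals$x - 10)^2 + (before$corals$y - 10)^2 >
    ev$radius^2
  expect_equal(after$corals$x, before$corals$x[keep_oracle])
  expect_true(all((after$corals$x - 10)^2 + (after$corals$y - 10)^2 >
                    ev$radius^2))
  expect_true(all((after$algae$x - 10)^2 + (after$algae$y - 10)^2 >
                    ev$radius^2))
  tc <- reefsim:::turf_cell_centers(after$turf)
  inside <- (tc$x - 10)^2 + (tc$y - 10)^2 <= ev$radius^2
  expect_true(all(after$turf[inside] == 0))
  expect_true(all(after$turf[!inside] == before$turf[!inside]))
  # an event covering the whole arena empties it
  wiped <- apply_disturbance(before, list(x = 10, y = 10, radius = 50))
  expect_length(wiped$corals$x, 0)
  expect_length(wiped$algae$x, 0)
  # an event confined to the margin leaves the core untouched
  far <- apply_disturbance(before, list(x = -8, y = -8, radius = 2))
  expect_equal(far$corals$x, before$corals$x)
  expect_equal(far$turf, before$turf)
})

test_that("macroalgae grow equally in height and diameter, then fragment", {
  # a new recruit after one month
  a <- list(x = 5, y = 5, height = 0, diameter = 0, age = 0L)
  set.seed(6)
  out <- macroalga_step(a)
  expect_equal(out$alga$height, 15)
  expect_equal(out$alga$diameter, 15)
  # fragmentation rule in isolation (no growth): one fragment per 5 cm
  # above the 30 cm threshold, height reduced accordingly
  p0 <- algae_defaults(); p0$growth_cm <- 0
  tall <- list(x = 5, y = 5, height = 40, diameter = 45, age = 2L)
  out <- macroalga_step(tall, p0)
  expect_equal(nrow(out$fragments), 2)
  expect_equal(out$alga$height, 30)
  # fragments land within the dispersal radius
  expect_true(all((out$fragments$x - 5)^2 + (out$fragments$y - 5)^2 <=
                    algae_defaults()$frag_dispersal_m^2 + 1e-9))
  # caps hold over long random sequences, and old algae die
  a <- list(x = 5, y = 5, height = 0, diameter = 0, age = 0L)
  repeat {
    out <- macroalga_step(a)
    if (is.null(out$alga)) break
    a <- out$alga
    expect_lte(a$height, 60)
    expect_lte(a$diameter, 45)
  }
  expect_equal(a$age, algae_defaults()$max_age)
})

test_that("algal recruitment realizes the constant 0.5 per m2 yearly rate", {
  set.seed(9)
  n <- vapply(1:300, function(i) nrow(algal_recruitment(c(40, 40))),
              numeric(1))
  expect_lt(abs(mean(n) - 800), 4 * sqrt(800 / 300))
  rec <- algal_recruitment(c(40, 40))
  expect_true(all(rec$x >= 0 & rec$x <= 40 & rec$y >= 0 & rec$y <= 40))
  expect_equal(nrow(algal_recruitment(c(40, 40), rate_m2_yr = 0)), 0)
  set.seed(5); a <- algal_recruitment(c(40, 40))
  set.seed(5); b <- algal_recruitment(c(40, 40))
  expect_identical(a, b)
})

test_that("turf grows 20% when ungrazed and halves when grazed", {
  g <- matrix(0.5, 2, 2)
  none <- matrix(FALSE, 2, 2)
  all_g <- matrix(TRUE, 2, 2)
  expect_equal(turf_step(g, none), matrix(0.6, 2, 2))
  expect_equal(turf_step(g, all_g), matrix(0.25, 2, 2))
  expect_equal(turf_step(matrix(1, 2, 2), none), matrix(1, 2, 2)) # cap
  # scoured cells regrow from the recolonization floor
  expect_equal(turf_step(matrix(0, 2, 2), none), matrix(0.012, 2, 2))
  # cover stays in [0, 1] under arbitrary grazing sequences
  set.seed(13)
  g <- matrix(runif(25), 5, 5)
  for (i in 1:200) {
    g <- turf_step(g, matrix(runif(25) < 0.3, 5, 5))
    expect_true(all(g >= 0 & g <= 1))
  }
})
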