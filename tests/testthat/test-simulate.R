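test_that("initialization reaches the target covers", {
  cfg <- small_config()
  set.seed(5)
  state <- init_community(cfg)
  cv <- reefsim:::cover_vector(state, cfg)
  for (nm in cfg$species$name) {
    expect_gte(cv[[nm]], 9)
    expect_lte(cv[[nm]], 11)
  }
  expect_gte(cv[["macroalgae"]], 4)
  expect_lte(cv[["macroalgae"]], 6.5)
  expect_equal(cv[["turf"]], 50)
  # a species with zero target gets no colonies
  none <- init_community(small_config(init_coral_cover = 0))
  expect_length(none$corals$x, 0)
  # determinism
  set.seed(9); a <- init_community(cfg)
  set.seed(9); b <- init_community(cfg)
  expect_identical(a, b)
  # infeasible demand errors
  expect_error(init_community(small_config(init_coral_cover = 1)),
               "infeasible")
})

test_that("relative cover counts overlapping colonies in full", {
  cfg <- sim_config(arena = c(40, 40), months = 12, analysis_window = 6,
                    replicates = 1, init_coral_cover = 0,
                    init_algal_cover = 0, init_turf = 0)
  state <- init_community(cfg)
  cv <- relative_cover(state, cfg)
  expect_equal(cv$total_benthic, 0)
  # one colony of 100 cm mean radius on 40 x 40 m
  state$corals <- reefsim:::corals_add(state$corals, 2L, x = 20, y = 20,
                                       radius = 100, morph = 0L)
  cv <- relative_cover(state, cfg)
  expect_equal(cv$P_lutea, pi * 1^2 / 1600 * 100, tolerance = 1e-10)
  # a second, fully overlapping colony of another species counts in full
  state$corals <- reefsim:::corals_add(state$corals, 1L, x = 20, y = 20,
                                       radius = 100, morph = 0L)
  cv2 <- relative_cover(state, cfg)
  expect_equal(cv2$total_benthic, 2 * cv$total_benthic)
  # margin algae are excluded from the metric
  state$algae <- reefsim:::algae_add(state$algae, x = c(20, -5),
                                     y = c(20, -5), height = 30,
                                     diameter = 40)
  cv3 <- relative_cover(state, cfg)
  expect_equal(cv3$macroalgae, pi * 0.2^2 / 1600 * 100, tolerance = 1e-10)
})

test_that("an undisturbed lone colony grows at exactly the base rate", {
  cfg <- sim_config(arena = c(20, 20), months = 12, analysis_window = 6,
                    replicates = 1, seed = 1, bleaching = FALSE,
                    disturbance = NULL, herbivory = NULL,
                    init_coral_cover = 0, init_algal_cover = 0,
                    init_turf = 0)
  cfg$algae$recruit_rate_m2_yr <- 0
  state <- init_community(cfg)
  state$corals <- reefsim:::corals_add(state$corals, 3L, x = 10, y = 10,
                                       radius = 10, morph = 1L)
  env <- list(streams = reefsim:::make_streams(1),
              stats = rep(-Inf, 12),
              disturbances = schedule_disturbances(disturbance_regime(NA, NA),
                                                   12),
              sp_focal = 1L, sp_comp = 2L,
              spv = with(cfg$species,
                         list(name = name, growth = growth_cm_month,
                              maxr = max_radius_cm,
                              maturity = maturity_diam_cm,
                              eggs = eggs_per_cm2, sf = surface_factor,
                              retention = retention_factor,
                              fixed = fixed_input_m2, conn = connectivity,
                              events = events_per_year, minb = min_bleach_T,
                              allb = all_bleach_T, mind = min_death_T,
                              alld = all_death_T)))
  env$spv$fixed <- rep(0, 4) # isolate growth from external recruits
  for (m in 1:10) state <- reefsim:::step_community(state, m, cfg, env)
  expect_equal(as.numeric(state$corals$axes[, 1]),
               rep(10 + 10 * cfg$species$growth_cm_month[3], 24),
               tolerance = 1e-12)
})

test_that("runs are reproducible and summaries re-aggregate from raw covers", {
  cfg <- small_config(replicates = 2, months = 60, analysis_window = 36)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$covers, b$covers)
  expect_identical(a$summary, b$summary)
  # independent re-aggregation of the summary from the long table
  sel <- a$covers$month > 60 - 36
  want_mean <- tapply(a$covers$cover_pct[sel], a$covers$species[sel], mean)
  got <- a$summary$mean_cover_pct[match(names(want_mean), a$summary$species)]
  expect_equal(got, as.numeric(want_mean))
  # full-window summary covers every record
  full <- summarize_covers(a$covers, 60, 60)
  want_all <- tapply(a$covers$cover_pct, a$covers$species, mean)
  expect_equal(full$mean_cover_pct[match(names(want_all), full$species)],
               as.numeric(want_all))
})

test_that("disabling herbivory leaves an algae-free coral trajectory unchanged", {
  base <- small_config(months = 36, analysis_window = 12,
                       init_algal_cover = 0, init_turf = 0,
                       turf = list(growth = 1.2, graze_factor = 0.5,
                                   floor = 0))
  base$algae$recruit_rate_m2_yr <- 0 # keep the run truly algae-free
  with_h <- run_simulation(base)
  no_h <- base; no_h$herbivory <- NULL
  without_h <- run_simulation(no_h)
  expect_identical(with_h$covers, without_h$covers)
})

test_that("a single-point sweep reproduces a plain run", {
  cfg <- small_config(months = 48, analysis_window = 24)
  sw <- scenario_sweep(cfg, "bleach", bleach_intervals = 3)
  direct <- cfg
  direct$bleaching <- TRUE
  direct$hot_year_interval <- 3
  direct$disturbance <- disturbance_regime(NA, NA)
  run <- run_simulation(direct)
  expect_equal(sw$mean_cover_pct, run$summary$mean_cover_pct)
  expect_equal(sw$bleach_interval_yr, rep(3, nrow(run$summary)))
  # the disturbance grid covers the cross product
  grid <- scenario_sweep(small_config(months = 24, analysis_window = 12),
                         "disturb", small_intervals = c(6, 12),
                         large_intervals = c(24, 48))
  expect_equal(nrow(unique(grid[, c("small_interval", "large_interval")])), 4)
})

test_that("state snapshots and run outputs serialize to CSV", {
  cfg <- small_config(months = 13, analysis_window = 6)
  run <- run_simulation(cfg)
  d <- tempfile()
  write_run_csv(run, d)
  covers <- read.csv(file.path(d, "covers.csv"))
  expect_equal(nrow(covers), nrow(run$covers))
  set.seed(2)
  state <- init_community(cfg)
  f <- tempfile(fileext = ".csv")
  write_state_snapshot(state, cfg, f)
  snap <- read.csv(f)
  expect_equal(sum(snap$type == "coral"), length(state$corals$x))
  expect_equal(sum(snap$type == "macroalga"), length(state$algae$x))
  expect_true(all(paste0("axis_", 1:24) %in% names(snap)))
  ft <- tempfile(fileext = ".csv")
  write_turf_csv(state, ft)
  expect_equal(dim(as.matrix(read.csv(ft, header = FALSE))),
               dim(state$turf))
  unlink(c(f, ft)); unlink(d, recursive = TRUE)
})

test_that("configurations round-trip through YAML", {
  cfg <- small_config(hot_year_interval = 7,
                      disturbance = disturbance_regime(6, 30))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$hot_year_interval, 7)
  expect_equal(back$disturbance$small_interval, 6)
  expect_equal(back$species$eggs_per_cm2, cfg$species$eggs_per_cm2)
  expect_equal(back$arena, cfg$arena)
  unlink(f)
})

# -- emergent community properties (slower) ----------------------------------

test_that("without perturbations P. lutea dominates with P. lobata second", {
  cfg <- sim_config(arena = c(20, 20), months = 3000, analysis_window = 600,
                    replicates = 1, seed = 2, bleaching = FALSE,
                    disturbance = NULL)
  run <- run_simulation(cfg)
  s <- run$summary
  cov <- function(nm) s$mean_cover_pct[s$species == nm]
  expect_gt(cov("P_lutea"), cov("P_lobata"))
  expect_gt(cov("P_lobata"), cov("A_muricata"))
  expect_gt(cov("P_lobata"), cov("P_damicornis"))
  expect_gt(cov("P_lutea"), 30) # clear dominance, not a draw
})

test_that("herbivory holds an algae-only community near the 5% threshold", {
  cfg <- sim_config(arena = c(20, 20), months = 1200, analysis_window = 600,
                    replicates = 1, seed = 3, bleaching = FALSE,
                    disturbance = NULL, init_coral_cover = 0,
                    init_algal_cover = 0.05)
  cfg$species$fixed_input_m2 <- 0 # no external coral recruits: algae only
  run <- run_simulation(cfg)
  macro <- run$summary$mean_cover_pct[run$summary$species == "macroalgae"]
  expect_gt(macro, 2)
  expect_lt(macro, 10)
})

test_that("coral cover falls and evenness peaks along the bleaching axis", {
  corals <- list(); benthos <- list()
  for (iv in c(2, 7, 20)) {
    cfg <- sim_config(arena = c(20, 20), months = 1800,
                      analysis_window = 900, replicates = 2, seed = 11,
                      bleaching = TRUE, hot_year_interval = iv,
                      disturbance = NULL)
    s <- run_simulation(cfg)$summary
    corals[[as.character(iv)]] <-
      s$mean_cover_pct[match(c("P_lobata", "P_lutea", "A_muricata",
                               "P_damicornis"), s$species)]
    benthos[[as.character(iv)]] <-
      s$mean_cover_pct[match(c("P_lobata", "P_lutea", "A_muricata",
                               "P_damicornis", "macroalgae"), s$species)]
  }
  totals <- vapply(corals, sum, numeric(1))
  # perturbation monotonicity: more frequent bleaching, less coral
  expect_lt(totals[["2"]], totals[["7"]])
  expect_lt(totals[["7"]], totals[["20"]])
  # intermediate-disturbance signature over the benthic groups: a single
  # dominant at either end (macroalgae at yearly bleaching, P. lutea at
  # 20-yr), the most even mixture at an interior frequency
  ev <- vapply(benthos, pielou_evenness, numeric(1))
  expect_gt(ev[["7"]], ev[["2"]])
  expect_gt(ev[["7"]], ev[["20"]])
})
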