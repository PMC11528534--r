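small_cfg <- function(..., total_cycles = 2) {
  sim_config(n_cells = 30L, total_cycles = total_cycles,
             domain_params = list(width = 7, height = 7, base_height = 4.5),
             init_relax_window = 8, relax_window = 2, ...)
}

test_that("initialisation seeds, tags and calibrates as configured", {
  cfg <- small_cfg(seed = 5, n_cancer = 6L)
  st <- init_simulation(cfg)
  expect_equal(nrow(st$tissue$cells), 30)
  expect_equal(sum(st$tissue$cells$lineage == "cancer"), 6)
  # cancer cells are the ones nearest the duct lumen
  dd <- paninsim:::dist_to_duct(cbind(st$tissue$cells$x, st$tissue$cells$y),
                                st$tissue$domain)
  expect_true(max(dd[st$tissue$cells$lineage == "cancer"]) <=
                min(dd[st$tissue$cells$lineage == "healthy"]) + 1e-12)
  # consumption calibration hits the fully active operating point
  f <- glucose_field(st$tissue, D = cfg$glucose$D)
  fs <- steady_state(st$tissue, f, consumption = st$kappa)
  expect_equal(mean_concentration(st$tissue, fs), 0.5, tolerance = 1e-3)
  # shared network trajectories cover the horizon
  expect_gte(max(st$grn$healthy$time), cfg$total_cycles)
  expect_false(is.null(st$grn$cancer))
  # all clocks start at zero
  expect_true(all(st$tissue$cells$Ti == 0))
  # no cancer cells requested: all healthy, no cancer trajectory
  st0 <- init_simulation(small_cfg(seed = 5, n_cancer = 0L))
  expect_true(all(st0$tissue$cells$lineage == "healthy"))
  expect_null(st0$grn$cancer)
})

test_that("same seed gives identical initial states and runs", {
  cfg <- small_cfg(seed = 11, n_cancer = 6L)
  a <- init_simulation(cfg)
  b <- init_simulation(cfg)
  expect_identical(a$tissue$cells, b$tissue$cells)
  expect_identical(a$kappa, b$kappa)
  ra <- run_simulation(cfg)
  rb <- run_simulation(cfg)
  expect_identical(ra$series, rb$series)
  expect_identical(ra$tissue$cells, rb$tissue$cells)
})

test_that("zero-length run returns the initial state unchanged", {
  cfg <- small_cfg(seed = 2)
  st <- init_simulation(cfg)
  st2 <- run_simulation(st, cycles = 0)
  expect_identical(st2$tissue$cells, st$tissue$cells)
  expect_null(st2$series)
})

test_that("run log is coherent and area partition is maintained", {
  cfg <- small_cfg(seed = 3, n_cancer = 8L, total_cycles = 3)
  st <- run_simulation(cfg)
  s <- st$series
  expect_equal(nrow(s), 6) # one row per half-cycle check
  expect_equal(s$time, seq(0.5, 3, by = 0.5))
  expect_true(all(s$label == classify_inflammation(s$index)))
  expect_true(all(s$stage == "PanIN1")) # 3 cycles is far below tau1
  # cell-count bookkeeping matches the event log
  if (!is.null(st$events)) {
    net <- sum(st$events$event == "divide") - sum(st$events$event == "die")
    expect_equal(tail(s$n_cells, 1), 30 + net)
  }
  # the tessellation still partitions the (possibly elongated) domain
  expect_equal(sum(st$tissue$geom$area), st$tissue$domain$area,
               tolerance = 1e-9)
  # glucose stays within physical bounds
  expect_true(all(st$tissue$cells$ci >= 0 & st$tissue$cells$ci <= 1))
})

test_that("scenario helper maps names to seedings", {
  expect_equal(scenario_config("healthy")$n_cancer, 0L)
  expect_equal(scenario_config("panin2-14")$n_cancer, 14L)
  expect_equal(scenario_config("panin2-18")$n_cancer, 18L)
  expect_error(scenario_config("panin4"))
})

test_that("infeasible placement is reported", {
  expect_error(
    init_simulation(sim_config(n_cells = 100L, domain = "rect",
                               domain_params = list(width = 2, height = 2),
                               min_spacing_frac = 5)),
    "infeasible")
})
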