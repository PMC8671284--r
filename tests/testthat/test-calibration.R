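test_that("Sobol sequence matches the reference construction", {
  # first 8 unscrambled 3-d points (computed once with an independent
  # generator implementing the same Joe-Kuo direction numbers)
  expected <- matrix(c(
    0,     0,     0,
    0.5,   0.5,   0.5,
    0.75,  0.25,  0.25,
    0.25,  0.75,  0.75,
    0.375, 0.375, 0.625,
    0.875, 0.875, 0.125,
    0.625, 0.125, 0.875,
    0.125, 0.625, 0.375), ncol = 3, byrow = TRUE)
  expect_equal(unname(sobol_sequence(8, 3)), expected, tolerance = 1e-12)
  # skip drops leading points
  expect_equal(sobol_sequence(4, 3, skip = 2), expected[3:6, ],
               tolerance = 1e-12)
})

test_that("Sobol population respects the grid and is deterministic", {
  q <- constant_inflow(100)
  tgt <- pressure_summary(90, 60, 75)
  prob <- calibration_problem(tgt, q)
  s2 <- ga_settings(population_size = 8, grid_points = 2)
  pop <- sobol_population(prob, s2)
  for (j in 1:3) {
    expect_true(all(pop[, j] %in% c(prob$lower[[j]], prob$upper[[j]])))
  }
  expect_identical(sobol_population(prob, s2), sobol_population(prob, s2))
  # a 64-point population on a 64-value grid has no duplicate triples
  s64 <- ga_settings(population_size = 64, grid_points = 64)
  pop64 <- sobol_population(prob, s64)
  expect_equal(nrow(unique(pop64)), 64L)
})

test_that("objective and constraints follow the target definition", {
  p_true <- ref_params()
  q <- constant_inflow(100)
  flat_mmHg <- convert_pressure((p_true$rp + p_true$rd) * 100, "barye", "mmHg")
  tgt <- pressure_summary(flat_mmHg, flat_mmHg, flat_mmHg)
  prob <- calibration_problem(tgt, q)
  oc <- objective_and_constraints(p_true, prob)
  expect_equal(oc$objective, 0, tolerance = 1e-16)
  expect_equal(unname(oc$violations), c(0, 0))
  # pmean off by 2 mmHg -> objective 4
  tgt2 <- pressure_summary(flat_mmHg + 2, flat_mmHg - 2, flat_mmHg - 2)
  oc2 <- objective_and_constraints(p_true, calibration_problem(tgt2, q))
  expect_equal(oc2$objective, 4, tolerance = 1e-9)
})

test_that("no-op operators leave the population unchanged", {
  q <- constant_inflow(100)
  prob <- calibration_problem(pressure_summary(90, 60, 75), q)
  s <- ga_settings(population_size = 8, p_crossover = 0, p_mutation = 0,
                   p_selection = 0, seed = 4)
  pop <- sobol_population(prob, s)
  set.seed(s$seed)
  out <- ga_step(pop, prob, s)
  expect_identical(out$population, pop)
})

test_that("elitism makes the best penalized fitness non-increasing", {
  q <- smooth_pulse(n = 96)
  prob <- calibration_problem(pressure_summary(97, 64, 80), q)
  s <- ga_settings(population_size = 12, generations = 25, seed = 9)
  res <- ga_optimize(rcrtune:::.calibration_eval_fn(prob),
                     lower = unlist(prob$lower), upper = unlist(prob$upper),
                     settings = s)
  pen <- res$trace$best_objective + s$penalty_weight * res$trace$best_violation
  expect_true(all(diff(pen) <= 1e-9))
})

test_that("the GA core minimises a convex surrogate objective", {
  x0 <- c(120, 2000, 5e-3)
  eval_fn <- function(x) {
    list(objective = sum(((x - x0) / c(295, 4900, 9.9e-3))^2),
         violations = 0)
  }
  s <- ga_settings(population_size = 32, generations = 200, seed = 2)
  res <- ga_optimize(eval_fn, lower = c(5, 100, 1e-4),
                     upper = c(300, 5000, 1e-2), settings = s)
  expect_lt(res$objective, 1e-4)
})

test_that("identical seeds give bit-identical calibrations", {
  q <- constant_inflow(120)
  flat <- convert_pressure(700 * 120, "barye", "mmHg")
  prob <- calibration_problem(pressure_summary(flat, flat, flat), q)
  s <- ga_settings(seed = 5, generations = 25)
  r1 <- calibrate_total_wk(prob, s)
  r2 <- calibrate_total_wk(prob, s)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$diagnostics, r2$diagnostics)
})

test_that("constant inflow pins the total resistance (compliance unidentifiable)", {
  q0 <- 150
  q <- constant_inflow(q0)
  r_true <- 601.2556
  flat <- convert_pressure(r_true * q0, "barye", "mmHg")
  prob <- calibration_problem(pressure_summary(flat, flat, flat), q)
  res <- calibrate_total_wk(prob, ga_settings(seed = 3, generations = 150))
  expect_equal(res$params$rp + res$params$rd, r_true, tolerance = 0.01)
})

test_that("recovery: a synthetic pulse problem is matched within the practical tolerance", {
  # coarse budget check; the full-budget recovery lives in the acceptance suite
  inflow <- default_inflow("pre", 128)
  true <- windkessel_params(100, 1000, 1e-3)
  targets <- summarize_pressure(wk_pressure(true, inflow))
  prob <- calibration_problem(targets, inflow)
  res <- calibrate_total_wk(prob, ga_settings(seed = 1, generations = 300))
  expect_true(res$feasible)
  expect_lt(abs(res$summary$pmax - targets$pmax), 0.5 + 1e-9)
  expect_lt(abs(res$summary$pmin - targets$pmin), 0.5 + 1e-9)
  expect_lt(abs(res$summary$pmean - targets$pmean), 2)
})

test_that("invalid targets and settings are rejected", {
  q <- constant_inflow(100)
  expect_error(calibration_problem(list(pmax = 50, pmin = 60, pmean = 55), q),
               "pmin <= pmean <= pmax")
  expect_error(ga_settings(population_size = 2), ">= 4")
  expect_error(ga_settings(p_crossover = 1.2), "probabilities")
  expect_error(ga_settings(grid_points = 1), ">= 2")
})
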