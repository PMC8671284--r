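test_that("two identical outlets split a constant inflow evenly", {
  p <- windkessel_params(100, 1500, 1e-3)
  bcs <- outlet_bc_set(list(a = p, b = p))
  q <- constant_inflow(80)
  sim <- simulate_network(q, bcs, solver_settings(dt = 0.002, max_cycles = 30,
                                                  periodicity_tol = 1e-9))
  expect_true(sim$converged)
  expect_equal(sim$outlet_flows$a$values, rep(40, length(sim$outlet_flows$a)),
               tolerance = 1e-6)
  expect_equal(sim$outlet_flows$b$values, sim$outlet_flows$a$values)
})

test_that("a single outlet reduces to the closed-form Windkessel solution", {
  p <- ref_params()
  inflow <- smooth_pulse(n = 350)
  bcs <- outlet_bc_set(list(da = p))
  sim <- simulate_network(inflow, bcs,
                          solver_settings(dt = 5e-4, max_cycles = 40,
                                          periodicity_tol = 1e-10))
  pw <- wk_pressure(p, sim$inflow)
  expect_lt(max(abs(sim$junction_pressure$values - pw$values)) /
              max(abs(pw$values)), 1e-6)
})

test_that("constant inflow settles on the resistive divider", {
  fx <- patient_fixture("pre")
  bcs <- distribute_by_area(fx$totals, fx$geometry)
  q <- constant_inflow(100)
  sim <- simulate_network(q, bcs, solver_settings(dt = 0.002, max_cycles = 60,
                                                  periodicity_tol = 1e-10))
  g <- vapply(bcs$outlets, function(p) 1 / (p$rp + p$rd), numeric(1L))
  expected <- 100 * g / sum(g)
  got <- vapply(sim$outlet_flows, function(w) mean(w$values), numeric(1L))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("flow is conserved at every sample, with and without the CoA element", {
  fx <- patient_fixture("pre")
  inflow <- smooth_pulse(n = 350)
  bcs <- apply_alpha(fx$totals, fx$geometry, -0.13)
  for (coa in list(NULL, coa_element(k = 1.5, area_coa = 0.75))) {
    sim <- simulate_network(inflow, bcs, solver_settings(), coa = coa)
    qs <- vapply(sim$outlet_flows, function(w) w$values,
                 numeric(length(sim$inflow)))
    expect_lt(max(abs(rowSums(qs) - sim$inflow$values)) /
                max(abs(sim$inflow$values)), 1e-8)
  }
})

test_that("cycle-mean pressure over mean flow equals the parallel resistance", {
  fx <- patient_fixture("pre")
  inflow <- smooth_pulse(n = 350)
  for (a in c(0, -0.13)) {
    bcs <- apply_alpha(fx$totals, fx$geometry, a)
    sim <- simulate_network(inflow, bcs,
                            solver_settings(dt = 0.002, max_cycles = 40,
                                            periodicity_tol = 1e-9))
    expect_equal(wf_mean(sim$junction_pressure) / wf_mean(sim$inflow),
                 parallel_total_resistance(bcs), tolerance = 1e-3)
  }
})

test_that("mean descending-aorta flow increases monotonically with alpha", {
  fx <- patient_fixture("pre")
  inflow <- default_inflow("pre", 350)
  means <- vapply(c(-0.15, -0.13, -0.10, -0.08, -0.04, 0), function(a) {
    sim <- simulate_network(inflow, apply_alpha(fx$totals, fx$geometry, a),
                            solver_settings(max_cycles = 12,
                                            periodicity_tol = 1e-7))
    wf_mean(sim$outlet_flows$da)
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("halving the time step changes the solution at first order or better", {
  fx <- patient_fixture("pre")
  inflow <- smooth_pulse(n = 350)
  bcs <- distribute_by_area(fx$totals, fx$geometry)
  run <- function(dt) {
    simulate_network(inflow, bcs,
                     solver_settings(dt = dt, max_cycles = 30,
                                     periodicity_tol = 1e-10))
  }
  s1 <- run(0.002); s2 <- run(0.001); s4 <- run(0.0005)
  p2 <- wf_interp(s2$junction_pressure, s1$junction_pressure$times)
  p4 <- wf_interp(s4$junction_pressure, s1$junction_pressure$times)
  d12 <- max(abs(s1$junction_pressure$values - p4))
  d24 <- max(abs(p2 - p4))
  expect_lt(d24, d12)
  expect_lt(d12 / max(abs(p4)), 1e-4)
})

test_that("the nonlinear CoA element adds the quadratic drop at steady state", {
  p <- ref_params()
  coa <- coa_element(k = 2, area_coa = 0.75)
  q0 <- 90
  sim <- simulate_network(constant_inflow(q0), outlet_bc_set(list(da = p)),
                          solver_settings(dt = 0.001, max_cycles = 80,
                                          periodicity_tol = 1e-11),
                          coa = coa)
  expect_true(sim$converged)
  # at steady state: dp = Rp Q + b Q^2 with b = K rho / (2 A^2)
  expected <- p$rp * q0 + coa$b * q0^2
  expect_equal(mean(sim$dp$values), expected, tolerance = 1e-5)
  expect_equal(mean(sim$outlet_flows$da$values), q0, tolerance = 1e-7)
})

test_that("solver settings are validated", {
  expect_error(solver_settings(dt = 0), "> 0")
  expect_error(solver_settings(max_cycles = 0), ">= 1")
  q <- constant_inflow(10, period = 0.1)
  fx <- patient_fixture("pre")
  bcs <- distribute_by_area(fx$totals, fx$geometry)
  expect_error(simulate_network(q, bcs, solver_settings(dt = 0.02)),
               "period/20")
})
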