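# Shared fixtures and independent oracles for the test suite.

# reference RCR triplet used across windkessel tests
ref_params <- function() windkessel_params(rp = 56.32, rd = 845.56, c = 1.06e-3)

# constant-flow waveform (flat pulse)
constant_inflow <- function(q0, period = 0.7, n = 64L) {
  make_inflow(pulse_spec(period = period, peak = q0, diastolic_level = q0,
                         systolic_fraction = 0.3), n_samples = n)
}

# smooth physiological pulse for oracle comparisons
smooth_pulse <- function(n = 1024L, period = 0.7) {
  make_inflow(pulse_spec(period = period, peak = 420, diastolic_level = 30,
                         systolic_fraction = 0.35), n_samples = n)
}

# independent stiff-ODE oracle for the Windkessel pressure:
#   C dPc/dt = Q - Pc/Rd,  P = Pc + Rp Q
# integrated with deSolve::lsoda at tight tolerances from the same P(0).
wk_ode_oracle <- function(params, inflow, p0) {
  qfun <- function(t) wf_interp(inflow, t)
  rhs <- function(t, y, parms) {
    list((qfun(t) - y[1L] / params$rd) / params$c)
  }
  pc0 <- p0 - params$rp * inflow$values[1L]
  sol <- deSolve::lsoda(c(pc = pc0), times = inflow$times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-8)
  sol[, "pc"] + params$rp * inflow$values
}
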