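# 0D single-junction forward model: a prescribed inlet flow is split among
# RCR-terminated outlets that all see one junction pressure (zero proximal
# branch impedance, so the flow split is governed entirely by the outlet
# Windkessel parameters).  Per outlet the compliance-node pressure obeys
#   C_i dPc_i/dt = Q_i - Pc_i / Rd_i,   Q_i = (Pj - Pc_i) / Rp_i,
# and the junction pressure solves mass conservation
#   sum_i Q_i = Q_in  =>  Pj = (Q_in + sum Pc_i/Rp_i) / (sum 1/Rp_i).
# Time integration is explicit RK4 with the junction pressure recomputed at
# every stage; the model is run cycle by cycle until the junction-pressure
# trace is periodic.
#
# An optional nonlinear coarctation element adds a quadratic drop
# dP = K (rho/2) (Q_da/A_coa)^2 in series on the descending-aorta pathway,
# in which case the junction pressure is found by a Newton iteration.

#' Solver settings for the 0D network
#'
#' @param dt time step in seconds (must satisfy `dt < period/20`).
#' @param max_cycles maximum number of cardiac cycles to integrate.
#' @param periodicity_tol relative cycle-to-cycle change of the junction
#'   pressure trace below which the run is declared periodic.
#' @return an object of class `"solver_settings"`.
#' @export
solver_settings <- function(dt = 0.002, max_cycles = 6L,
                            periodicity_tol = 1e-6) {
  if (dt <= 0) stop("dt must be > 0")
  if (max_cycles < 1L) stop("max_cycles must be >= 1")
  if (periodicity_tol <= 0) stop("periodicity_tol must be > 0")
  structure(list(dt = dt, max_cycles = as.integer(max_cycles),
                 periodicity_tol = periodicity_tol),
            class = "solver_settings")
}

#' Nonlinear coarctation element
#'
#' Quadratic pressure drop `K * (rho/2) * (Q/A)^2 * sign(Q)` added in
#' series on the descending-aorta pathway.  Off by default in
#' [simulate_network()]: the alpha mechanism already represents the
#' coarctation resistance; this element lets users emulate a
#' stenosis-dominated pressure-drop waveform shape.
#'
#' @param k dimensionless loss coefficient (>= 0).
#' @param area_coa coarctation area in cm^2.
#' @param rho blood density in g/cm^3 (default 1.060).
#' @return an object of class `"coa_element"`.
#' @export
coa_element <- function(k, area_coa, rho = .BLOOD_RHO) {
  stopifnot(k >= 0, area_coa > 0, rho > 0)
  structure(list(k = k, area_coa = area_coa, rho = rho,
                 b = k * rho / (2 * area_coa^2)),
            class = "coa_element")
}

# junction pressure and outlet flows given compliance-node pressures pc.
# Linear case closed form; with a coa element on outlet `ida`, Newton on Pj.
.junction_solve <- function(pc, q_in, rp, ida = NA_integer_, b = 0) {
  inv_rp <- 1 / rp
  pj <- (q_in + sum(pc * inv_rp)) / sum(inv_rp)
  if (!is.na(ida) && b > 0) {
    rp_da <- rp[ida]
    q_da_of <- function(pj) {
      dp <- pj - pc[ida]
      s <- sign(dp)
      # solve rp q + b q^2 sign(q) = dp for q with sign(q) = sign(dp)
      s * (-rp_da + sqrt(rp_da^2 + 4 * b * abs(dp))) / (2 * b)
    }
    f <- function(pj) {
      q_lin <- sum((pj - pc[-ida]) * inv_rp[-ida])
      q_lin + q_da_of(pj) - q_in
    }
    # Newton iteration from the linear solution
    for (it in 1:50) {
      q_da <- q_da_of(pj)
      dq_da <- 1 / (rp_da + 2 * b * abs(q_da))
      fval <- sum((pj - pc[-ida]) * inv_rp[-ida]) + q_da - q_in
      step <- fval / (sum(inv_rp[-ida]) + dq_da)
      pj <- pj - step
      if (abs(step) < 1e-12 * max(1, abs(pj))) break
    }
  }
  q <- (pj - pc) * inv_rp
  if (!is.na(ida) && b > 0) {
    dp <- pj - pc[ida]
    q[ida] <- sign(dp) * (-rp[ida] + sqrt(rp[ida]^2 + 4 * b * abs(dp))) /
      (2 * b)
  }
  list(pj = pj, q = q)
}

#' Run the 0D single-junction forward model
#'
#' @param inflow prescribed inlet flow [waveform()] (cm^3/s).
#' @param bcs an [outlet_bc_set()] (any number of outlets >= 1).
#' @param settings a [solver_settings()].
#' @param coa optional [coa_element()] placed on the `"da"` outlet.
#' @return an object of class `"sim_result"`: named list of per-outlet flow
#'   waveforms (`outlet_flows`), the `junction_pressure` and
#'   `distal_pressure_da` waveforms (barye), the pressure-drop waveform
#'   `dp` (junction minus descending-aorta compliance node, barye; `NULL`
#'   without a `"da"` outlet), and diagnostics (`converged`, `cycles`,
#'   `rel_change`).
#' @export
simulate_network <- function(inflow, bcs, settings = solver_settings(),
                             coa = NULL) {
  stopifnot(inherits(inflow, "waveform"), inherits(bcs, "outlet_bc_set"),
            inherits(settings, "solver_settings"))
  if (inflow$units != "cm3/s") stop("`inflow` must be a flow waveform")
  T <- inflow$period
  dt <- settings$dt
  if (dt >= T / 20) stop("dt must be smaller than period/20")
  n_steps <- max(20L, as.integer(round(T / dt)))
  dt <- T / n_steps                     # land exactly on the cycle end
  nm <- names(bcs$outlets)
  rp <- vapply(bcs$outlets, `[[`, numeric(1L), "rp")
  rd <- vapply(bcs$outlets, `[[`, numeric(1L), "rd")
  cc <- vapply(bcs$outlets, `[[`, numeric(1L), "c")
  ida <- if (!is.null(coa)) match("da", nm) else NA_integer_
  if (!is.null(coa)) {
    stopifnot(inherits(coa, "coa_element"))
    if (is.na(ida)) stop("a coa element requires an outlet named 'da'")
  }
  b <- if (is.null(coa)) 0 else coa$b

  times <- seq(0, by = dt, length.out = n_steps)
  q_full <- wf_interp(inflow, times)
  q_half <- wf_interp(inflow, times + dt / 2)
  q_next <- c(q_full[-1L], q_full[1L])

  deriv <- function(pc, q_in) {
    j <- .junction_solve(pc, q_in, rp, ida, b)
    (j$q - pc / rd) / cc
  }

  # steady resistive initial state: Q_i ~ conductance share of the mean flow
  q_mean <- wf_mean(inflow)
  r_par <- 1 / sum(1 / (rp + rd))
  pc <- rd * q_mean * r_par / (rp + rd)

  pj_prev <- NULL
  converged <- FALSE
  rel_change <- NA_real_
  cycles <- 0L
  pj_trace <- numeric(n_steps)
  q_trace <- matrix(0, nrow = n_steps, ncol = length(nm))
  pc_da_trace <- numeric(n_steps)
  for (cyc in seq_len(settings$max_cycles)) {
    cycles <- cyc
    for (k in seq_len(n_steps)) {
      j <- .junction_solve(pc, q_full[k], rp, ida, b)
      pj_trace[k] <- j$pj
      q_trace[k, ] <- j$q
      if (!is.na(ida)) pc_da_trace[k] <- pc[ida]
      k1 <- deriv(pc, q_full[k])
      k2 <- deriv(pc + dt / 2 * k1, q_half[k])
      k3 <- deriv(pc + dt / 2 * k2, q_half[k])
      k4 <- deriv(pc + dt * k3, q_next[k])
      pc <- pc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.null(pj_prev)) {
      rel_change <- max(abs(pj_trace - pj_prev)) / max(abs(pj_trace))
      if (rel_change < settings$periodicity_tol) {
        converged <- TRUE
        break
      }
    }
    pj_prev <- pj_trace
  }

  mk_wave <- function(v, units) waveform(times, v, period = T, units = units)
  outlet_flows <- lapply(seq_along(nm), function(i) mk_wave(q_trace[, i], "cm3/s"))
  names(outlet_flows) <- nm
  has_da <- "da" %in% nm
  res <- list(
    outlet_flows = outlet_flows,
    junction_pressure = mk_wave(pj_trace, "barye"),
    distal_pressure_da = if (has_da) mk_wave(pc_da_trace, "barye") else NULL,
    dp = if (has_da) mk_wave(pj_trace - pc_da_trace, "barye") else NULL,
    inflow = mk_wave(q_full, "cm3/s"),
    converged = converged, cycles = cycles, rel_change = rel_change,
    alpha = bcs$alpha)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d outlets, %d samples/cycle, %d cycles (%s)\n",
              length(x$outlet_flows), length(x$junction_pressure$times),
              x$cycles,
              if (x$converged) "periodic" else "not converged"))
  invisible(x)
}
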