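# Closed-form RCR pressure response to a prescribed flow waveform.
#
# P(t) = [P(0) - Rp Q(0)] e^{-t/tau} + Rp Q(t)
#        + int_0^t e^{-(t-s)/tau} Q(s) / C ds,      tau = Rd C.
#
# The convolution integral is evaluated by product integration: within each
# sampling interval Q is taken piecewise linear (the waveform's own
# interpolation rule) and the exponential kernel is integrated in closed
# form, giving the O(n) recursion
#   I_{k+1} = E_k I_k + [Q_k (A_k - B_k) + Q_{k+1} B_k] / C,
#   E_k = e^{-h_k/tau},  A_k = tau (1 - E_k),  B_k = tau (1 - (1 - E_k)/x_k),
# with x_k = h_k / tau.  The rule is second order in h and, unlike a plain
# trapezoid of the kernel, remains exact in the stiff resistive limit
# tau -> 0 (where I -> Rd Q).

# stable 1 - (1 - e^{-x})/x for x >= 0
.one_minus_em1x <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- xs / 2 - xs^2 / 6 + xs^3 / 24
  xl <- x[!small]
  out[!small] <- 1 + expm1(-xl) / xl
  out
}

# convolution integral I(t_k) at the given nodes (flow values q at nodes)
.wk_convolution <- function(times, q, tau, cc) {
  n <- length(times)
  if (n == 1L) return(0)
  h <- diff(times)
  x <- h / tau
  E <- exp(-x)
  A <- tau * (-expm1(-x))
  B <- tau * .one_minus_em1x(x)
  inc <- (q[-n] * (A - B) + q[-1L] * B) / cc
  if (max(x) - min(x) < 1e-12 * max(x)) {
    # uniform grid: linear recurrence via stats::filter
    I <- c(0, as.numeric(filter(inc, E[1L], method = "recursive")))
  } else {
    I <- numeric(n)
    for (k in seq_len(n - 1L)) I[k + 1L] <- E[k] * I[k] + inc[k]
  }
  I
}

#' Windkessel pressure waveform for a prescribed inflow
#'
#' Evaluates the closed-form RCR pressure response at the inflow's own
#' sample times.  By default the initial pressure `p0` is the periodic
#' value from [wk_periodic_p0()], so the returned waveform is the
#' limit-cycle solution (equivalent to discarding start-up transients by
#' simulating many cycles).
#'
#' @param params a [windkessel_params()] triplet.
#' @param inflow a flow [waveform()] (cm^3/s).
#' @param p0 initial pressure `P(0)` in barye, or `NULL` for the periodic
#'   value.
#' @return a pressure [waveform()] in barye on the inflow's time grid.  The
#'   attribute `"p_end"` carries `P(T)` (equal to `P(0)` for the periodic
#'   solution).
#' @export
wk_pressure <- function(params, inflow, p0 = NULL) {
  stopifnot(inherits(params, "windkessel_params"), inherits(inflow, "waveform"))
  if (inflow$units != "cm3/s") stop("`inflow` must be a flow waveform (cm3/s)")
  if (is.null(p0)) p0 <- wk_periodic_p0(params, inflow)
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0))
  tau <- wk_tau(params)
  # extend the grid with the cycle end t = T, Q(T) = Q(0)
  t_ext <- c(inflow$times, inflow$period)
  q_ext <- c(inflow$values, inflow$values[1L])
  I <- .wk_convolution(t_ext, q_ext, tau, params$c)
  p_ext <- (p0 - params$rp * q_ext[1L]) * exp(-t_ext / tau) +
    params$rp * q_ext + I
  n <- length(inflow$times)
  out <- waveform(inflow$times, p_ext[seq_len(n)], period = inflow$period,
                  units = "barye")
  attr(out, "p_end") <- p_ext[n + 1L]
  out
}

#' Periodic initial pressure of the Windkessel solution
#'
#' The pressure response is affine in `P(0)`, so the unique initial value
#' making the solution T-periodic (`P(T) = P(0)`) is obtained in closed
#' form: `P(0) = [Rp Q(T) - Rp Q(0) e^{-T/tau} + I(T)] / (1 - e^{-T/tau})`,
#' with `Q(T) = Q(0)` by periodicity of the inflow and `I(T)` the
#' convolution integral over one cycle.
#'
#' @inheritParams wk_pressure
#' @return scalar pressure in barye.
#' @export
wk_periodic_p0 <- function(params, inflow) {
  stopifnot(inherits(params, "windkessel_params"), inherits(inflow, "waveform"))
  tau <- wk_tau(params)
  T <- inflow$period
  denom <- -expm1(-T / tau)           # 1 - e^{-T/tau}
  if (denom < 1e-14) {
    stop("period/tau too small: periodic initial pressure is ill-conditioned")
  }
  t_ext <- c(inflow$times, T)
  q_ext <- c(inflow$values, inflow$values[1L])
  I_T <- .wk_convolution(t_ext, q_ext, tau, params$c)[length(t_ext)]
  q0 <- inflow$values[1L]
  (params$rp * q0 * denom + I_T) / denom
}

#' Summarise a pressure waveform as (max, min, mean) in mmHg
#'
#' The mean is the periodic trapezoidal cycle average `(1/T) int_0^T P dt`;
#' max and min are taken over the samples.  Barye input is converted to
#' mmHg.
#'
#' @param p a pressure [waveform()] (mmHg or barye).
#' @return a [pressure_summary()].
#' @export
summarize_pressure <- function(p) {
  stopifnot(inherits(p, "waveform"))
  if (!p$units %in% c("mmHg", "barye")) {
    stop("`p` must be a pressure waveform (mmHg or barye)")
  }
  v <- p$values
  m <- wf_mean(p)
  if (p$units == "barye") {
    v <- convert_pressure(v, "barye", "mmHg")
    m <- convert_pressure(m, "barye", "mmHg")
  }
  pressure_summary(pmax = max(v), pmin = min(v), pmean = m)
}
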