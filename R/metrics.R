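# Quantities of interest computed from forward results: pressure drop
# between a proximal and a distal station, time-averaged wall shear stress,
# and peak-based flow-agreement errors.

#' Pressure drop between two stations
#'
#' `dP(t) = P_proximal(t) - P_distal(t)` pointwise on the proximal grid;
#' the distal waveform is resampled by periodic interpolation if its grid
#' differs.  Both waveforms must share the period and the pressure unit.
#'
#' @param proximal,distal pressure [waveform()]s.
#' @return a pressure [waveform()] in the common unit.
#' @export
pressure_drop <- function(proximal, distal) {
  stopifnot(inherits(proximal, "waveform"), inherits(distal, "waveform"))
  if (abs(proximal$period - distal$period) > 1e-12) {
    stop("mismatched periods")
  }
  if (proximal$units != distal$units) stop("mismatched pressure units")
  dv <- if (length(proximal$times) == length(distal$times) &&
            all(abs(proximal$times - distal$times) < 1e-12)) {
    distal$values
  } else {
    wf_interp(distal, proximal$times)
  }
  waveform(proximal$times, proximal$values - dv, proximal$period,
           units = proximal$units)
}

#' Wall-shear-stress magnitude field
#'
#' `|WSS|(s, t)` sampled at abstract wall positions `s` over one cardiac
#' cycle, in dyn/cm^2.
#'
#' @param positions identifiers of the wall sites (length = rows of
#'   `magnitudes`).
#' @param times sample times in seconds, strictly increasing, first at 0,
#'   all `< period`.
#' @param magnitudes nonnegative matrix, positions x times.
#' @param period cycle length in seconds.
#' @return an object of class `"wss_field"`.
#' @export
wss_field <- function(positions, times, magnitudes, period) {
  magnitudes <- as.matrix(magnitudes)
  if (length(positions) != nrow(magnitudes)) {
    stop("`positions` must match the rows of `magnitudes`")
  }
  if (length(times) != ncol(magnitudes)) {
    stop("`times` must match the columns of `magnitudes`")
  }
  if (any(magnitudes < 0)) stop("WSS magnitudes must be >= 0")
  if (any(diff(times) <= 0) || abs(times[1L]) > 1e-12 ||
      times[length(times)] >= period) {
    stop("`times` must be strictly increasing from 0 and < period")
  }
  structure(list(positions = positions, times = as.numeric(times),
                 magnitudes = magnitudes, period = as.numeric(period)),
            class = "wss_field")
}

#' Time-averaged wall shear stress per position
#'
#' `TAWSS(s) = (1/T) int_0^T |WSS|(s, t) dt` by the trapezoidal rule with
#' periodic closure of the cycle.
#'
#' @param field a [wss_field()].
#' @return named numeric vector of TAWSS values (dyn/cm^2) per position.
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  xs <- c(field$times, field$period)
  out <- apply(field$magnitudes, 1L, function(row) {
    pracma::trapz(xs, c(row, row[1L])) / field$period
  })
  setNames(out, field$positions)
}

#' Peak-based flow agreement error
#'
#' Compares the systolic peaks of a simulated and a reference flow
#' waveform: `peak_diff = max(sim) - max(ref)` (cm^3/s) and
#' `peak_pct = 100 * peak_diff / max(ref)`.  A root-mean-square error over
#' the cycle (on the reference grid) is included as a secondary metric.
#'
#' @param sim,ref flow [waveform()]s with the same period.
#' @return list with `peak_diff`, `peak_pct` and `rms`.
#' @export
flow_error <- function(sim, ref) {
  stopifnot(inherits(sim, "waveform"), inherits(ref, "waveform"))
  if (abs(sim$period - ref$period) > 1e-12) stop("mismatched periods")
  ref_peak <- max(ref$values)
  if (ref_peak == 0) stop("reference waveform has zero peak")
  peak_diff <- max(sim$values) - ref_peak
  sim_on_ref <- wf_interp(sim, ref$times)
  list(peak_diff = peak_diff,
       peak_pct = 100 * peak_diff / ref_peak,
       rms = sqrt(mean((sim_on_ref - ref$values)^2)))
}
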