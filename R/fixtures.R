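# Synthetic inputs: physiological single-peaked inflow pulses, the
# published clinical fixture numbers (catheter pressures, printed
# cross-sectional areas, calibrated totals), and test WSS fields.  The
# patient flow waveforms exist only as figures, so the pulses here emulate
# their morphology (half-sine systolic lobe over a diastolic baseline)
# rather than reproducing them.

#' Specification of a synthetic inflow pulse
#'
#' @param period cycle length in seconds.
#' @param peak systolic peak flow, cm^3/s.
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   lobe, in (0, 1).
#' @param diastolic_level baseline flow outside the lobe, cm^3/s
#'   (`0 <= diastolic_level < peak`; equality gives a constant waveform).
#' @param noise_sd standard deviation of optional additive Gaussian noise
#'   (cm^3/s); applied only when `seed` is set.
#' @param seed RNG seed for the noise; `NULL` for a noise-free pulse.
#' @return an object of class `"pulse_spec"`.
#' @export
pulse_spec <- function(period = 0.7, peak = 400, systolic_fraction = 0.35,
                       diastolic_level = 30, noise_sd = 0, seed = NULL) {
  if (period <= 0) stop("period must be > 0")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("systolic_fraction must be in (0, 1)")
  }
  if (diastolic_level < 0 || peak < diastolic_level) {
    stop("require peak >= diastolic_level >= 0")
  }
  structure(list(period = period, peak = peak,
                 systolic_fraction = systolic_fraction,
                 diastolic_level = diastolic_level,
                 noise_sd = noise_sd, seed = seed),
            class = "pulse_spec")
}

#' Generate a synthetic inflow waveform
#'
#' Half-sine systolic lobe of width `systolic_fraction * period` rising
#' from the diastolic baseline to the peak, constant baseline elsewhere.
#' The cycle mean is available in closed form:
#' `diastolic_level + (2/pi) * systolic_fraction * (peak - diastolic_level)`.
#'
#' @param spec a [pulse_spec()].
#' @param n_samples number of samples over the cycle (>= 32).
#' @return a flow [waveform()].
#' @export
make_inflow <- function(spec, n_samples = 256L) {
  stopifnot(inherits(spec, "pulse_spec"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 32L) stop("n_samples must be >= 32")
  t <- seq(0, spec$period, length.out = n_samples + 1L)[seq_len(n_samples)]
  w_sys <- spec$systolic_fraction * spec$period
  v <- rep(spec$diastolic_level, n_samples)
  in_sys <- t < w_sys
  v[in_sys] <- spec$diastolic_level +
    (spec$peak - spec$diastolic_level) * sin(pi * t[in_sys] / w_sys)
  if (!is.null(spec$seed) && spec$noise_sd > 0) {
    set.seed(spec$seed)
    v <- v + rnorm(n_samples, sd = spec$noise_sd)
  }
  waveform(t, v, period = spec$period, units = "cm3/s")
}

#' Closed-form mean of a noise-free pulse
#'
#' @param spec a [pulse_spec()].
#' @return mean flow in cm^3/s.
#' @export
pulse_mean <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  spec$diastolic_level +
    (2 / pi) * spec$systolic_fraction * (spec$peak - spec$diastolic_level)
}

#' Published clinical fixture for the coarctation patient
#'
#' Returns the printed clinical numbers for the pre- or post-stenting
#' stage: outlet cross-sectional areas (cm^2), catheter pressure targets at
#' the ascending aorta (mmHg), the calibrated total Windkessel triplet
#' (CGS), and the cardiac cycle length (s).
#'
#' @param stage `"pre"` (before stenting, 0.7 s cycle, coarctation-area DA
#'   pathway) or `"post"` (after stenting, 1.0 s cycle, descending-aorta
#'   pathway).
#' @return list with `geometry`, `targets`, `totals` and `period`.
#' @export
patient_fixture <- function(stage = c("pre", "post")) {
  stage <- match.arg(stage)
  if (stage == "pre") {
    list(
      geometry = outlet_geometry(bca = 1.44, lcca = 0.28, lsa = 1.36,
                                 da = 2.27, coa = 0.75,
                                 da_area_mode = "coa"),
      targets = pressure_summary(pmax = 97, pmin = 64, pmean = 80),
      totals = windkessel_params(rp = 56.32, rd = 845.56, c = 1.06e-3),
      period = 0.7)
  } else {
    list(
      geometry = outlet_geometry(bca = 1.06, lcca = 0.28, lsa = 1.36,
                                 da = 2.27, coa = 0.75,
                                 da_area_mode = "da"),
      targets = pressure_summary(pmax = 85, pmin = 63, pmean = 74),
      totals = windkessel_params(rp = 37.05, rd = 910.49, c = 2.3e-3),
      period = 1.0)
  }
}

#' Default inflow pulse consistent with a clinical fixture
#'
#' Builds a pulse whose cycle mean equals `Pmean / (Rp + Rd)` of the
#' fixture, so that driving the fixture totals with this pulse reproduces
#' the fixture's mean pressure (the fixture pressures and totals become
#' mutually consistent for round-trip tests).  The peak is solved from the
#' closed-form pulse mean.
#'
#' @inheritParams patient_fixture
#' @param n_samples samples per cycle.
#' @param diastolic_level baseline flow, cm^3/s.
#' @param systolic_fraction systolic lobe fraction; the default scales a
#'   ~0.25 s ejection to the stage's cycle length.
#' @return a flow [waveform()].
#' @export
default_inflow <- function(stage = c("pre", "post"), n_samples = 256L,
                           diastolic_level = 30,
                           systolic_fraction = NULL) {
  stage <- match.arg(stage)
  fx <- patient_fixture(stage)
  if (is.null(systolic_fraction)) {
    systolic_fraction <- min(0.245 / fx$period, 0.45)
  }
  q_mean <- convert_pressure(fx$targets$pmean, "mmHg", "barye") /
    (fx$totals$rp + fx$totals$rd)
  peak <- diastolic_level +
    (q_mean - diastolic_level) / ((2 / pi) * systolic_fraction)
  make_inflow(pulse_spec(period = fx$period, peak = peak,
                         systolic_fraction = systolic_fraction,
                         diastolic_level = diastolic_level),
              n_samples = n_samples)
}

#' Synthetic wall-shear-stress field with known time average
#'
#' @param n_positions number of wall sites (>= 1).
#' @param pattern `"constant"` (every site at `high`), `"pulse"`
#'   (rectangular pulse at `high` for `duty` of the cycle, `low`
#'   otherwise; closed-form TAWSS = `duty*high + (1-duty)*low` up to the
#'   trapezoid's jump smoothing), or `"noisy"` (constant plus seeded
#'   half-normal jitter).
#' @param seed RNG seed for the noisy pattern.
#' @param period cycle length, s.
#' @param n_times time samples per cycle.
#' @param high,low,duty pattern parameters (dyn/cm^2 and cycle fraction).
#' @return a [wss_field()].
#' @export
make_wss_field <- function(n_positions, pattern = c("constant", "pulse",
                                                    "noisy"),
                           seed = 1L, period = 0.7, n_times = 128L,
                           high = 10, low = 2, duty = 0.3) {
  pattern <- match.arg(pattern)
  n_positions <- as.integer(n_positions)
  if (n_positions < 1L) stop("n_positions must be >= 1")
  t <- seq(0, period, length.out = n_times + 1L)[seq_len(n_times)]
  base <- switch(pattern,
    constant = rep(high, n_times),
    pulse = ifelse(t < duty * period, high, low),
    noisy = rep(high, n_times))
  M <- matrix(rep(base, each = n_positions), nrow = n_positions)
  if (pattern == "noisy") {
    set.seed(seed)
    M <- M + abs(matrix(rnorm(length(M)), nrow = n_positions))
  }
  wss_field(positions = paste0("s", seq_len(n_positions)), times = t,
            magnitudes = M, period = period)
}
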