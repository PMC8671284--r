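#' Periodic sampled waveform over one cardiac cycle
#'
#' A waveform holds samples of a flow (cm^3/s) or pressure (mmHg or barye)
#' signal on `[0, period)`.  The signal is implicitly periodic: values at
#' arbitrary times are obtained by linear interpolation with wrap-around, so
#' the value at `t` equals the value at `t mod period`.
#'
#' @param times numeric, strictly increasing sample times in seconds; the
#'   first sample must be at 0 and all times must be `< period`.
#' @param values numeric, same length as `times`.
#' @param period cycle length T in seconds, `> 0`.
#' @param units one of `"cm3/s"`, `"mmHg"`, `"barye"`, `"dyn/cm2"`.
#' @return an object of class `"waveform"`.
#' @examples
#' w <- waveform(c(0, 0.35), c(0, 100), period = 0.7)
#' wf_interp(w, 0.175)
#' @export
waveform <- function(times, values, period, units = "cm3/s") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  period <- as.numeric(period)
  if (length(period) != 1L || !is.finite(period) || period <= 0) {
    stop("`period` must be a single positive number")
  }
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length")
  }
  if (length(times) < 1L) stop("waveform needs at least one sample")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing (non-monotonic input)")
  if (abs(times[1L]) > 1e-12) stop("first sample must be at time 0")
  if (times[length(times)] >= period) stop("all sample times must be < period")
  if (!all(is.finite(values))) stop("`values` must be finite")
  units <- match.arg(units, c("cm3/s", "mmHg", "barye", "dyn/cm2"))
  if (units == "dyn/cm2") units <- "barye"
  structure(list(times = times, values = values, period = period,
                 units = units),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples over T = %g s [%s]\n",
              length(x$times), x$period, x$units))
  cat(sprintf("  range: [%.6g, %.6g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$times)

#' Periodic linear interpolation of a waveform
#'
#' @param w a [waveform()].
#' @param t numeric vector of query times (any real values; they are wrapped
#'   into `[0, period)`).
#' @return numeric vector of interpolated values.
#' @export
wf_interp <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  tm <- t %% w$period
  # close the cycle: value at `period` is the value at 0
  xs <- c(w$times, w$period)
  ys <- c(w$values, w$values[1L])
  approx(xs, ys, xout = tm, rule = 2)$y
}

#' Mean of a waveform over one period (periodic trapezoid)
#'
#' Computes `(1/T) * integral_0^T w dt` by the trapezoidal rule with the
#' cycle closed periodically (the value at `T` is the value at 0).
#'
#' @param w a [waveform()].
#' @return scalar mean value in the waveform's units.
#' @export
wf_mean <- function(w) {
  stopifnot(inherits(w, "waveform"))
  xs <- c(w$times, w$period)
  ys <- c(w$values, w$values[1L])
  pracma::trapz(xs, ys) / w$period
}

#' Read / write a waveform CSV
#'
#' The file format is a comment header declaring units and period, followed
#' by `time,value` rows:
#' ```
#' # units=cm3/s period=0.7
#' time,value
#' 0,0
#' 0.35,100
#' ```
#' `write_waveform()` serialises with full (17 significant digit) precision
#' so that `read_waveform(write_waveform(w))` reproduces `w` exactly.
#'
#' @param path file path.
#' @return `read_waveform()` returns a [waveform()]; `write_waveform()`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#")) {
    stop("missing waveform header line '# units=... period=...'")
  }
  hdr <- lines[1L]
  get_field <- function(name) {
    m <- regmatches(hdr, regexec(paste0(name, "=([^ ]+)"), hdr))[[1L]]
    if (length(m) < 2L) stop(sprintf("header missing '%s=' field", name))
    m[2L]
  }
  units <- get_field("units")
  period <- as.numeric(get_field("period"))
  if (!is.finite(period) || period <= 0) stop("negative or invalid period in header")
  df <- read.csv(text = paste(lines[-1L], collapse = "\n"))
  if (!all(c("time", "value") %in% names(df))) {
    stop("expected columns 'time' and 'value'")
  }
  waveform(df$time, df$value, period = period, units = units)
}

#' @rdname read_waveform
#' @param w a [waveform()] to serialise.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=%s period=%s", w$units,
                     format(w$period, digits = 17)), con)
  writeLines("time,value", con)
  writeLines(paste(format(w$times, digits = 17, trim = TRUE, scientific = FALSE),
                   format(w$values, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}
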