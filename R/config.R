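# Structured configuration shared by the command-line entry points: one
# YAML/JSON document holding geometry, pressure targets, GA settings, the
# alpha interval and solver settings.

#' Read a configuration file
#'
#' Accepts YAML (or JSON, which YAML subsumes) with keys `geometry`
#' (`bca`, `lcca`, `lsa`, `da`, `coa`, optional `da_area_mode`),
#' `pressure_targets` (`pmax`, `pmin`, `pmean`), and optional `ga`,
#' `alpha` (`low`, `high`, `order`) and `solver` (`dt`, `max_cycles`,
#' `periodicity_tol`) sections.  Missing optional sections fall back to
#' package defaults.
#'
#' @param path file path.
#' @return list with `geometry` ([outlet_geometry()]), `targets`
#'   ([pressure_summary()]), `ga` ([ga_settings()]), `alpha`
#'   ([uncertain_param()]) and `solver` ([solver_settings()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$geometry) || is.null(raw$pressure_targets)) {
    stop("config needs 'geometry' and 'pressure_targets' sections")
  }
  geometry <- do.call(outlet_geometry, raw$geometry)
  targets <- do.call(pressure_summary, raw$pressure_targets)
  ga <- do.call(ga_settings, if (is.null(raw$ga)) list() else raw$ga)
  alpha <- do.call(uncertain_param,
                   if (is.null(raw$alpha)) list() else raw$alpha)
  solver <- do.call(solver_settings,
                    if (is.null(raw$solver)) list() else raw$solver)
  list(geometry = geometry, targets = targets, ga = ga, alpha = alpha,
       solver = solver)
}

#' Write a fixture configuration for a clinical stage
#'
#' Serialises the published clinical numbers of [patient_fixture()] as a
#' config file usable by every command-line entry point.
#'
#' @inheritParams patient_fixture
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_config <- function(stage = c("pre", "post"), path) {
  stage <- match.arg(stage)
  fx <- patient_fixture(stage)
  g <- fx$geometry
  cfg <- list(
    geometry = list(bca = g$bca, lcca = g$lcca, lsa = g$lsa, da = g$da,
                    coa = g$coa, da_area_mode = g$da_area_mode),
    pressure_targets = list(pmax = fx$targets$pmax, pmin = fx$targets$pmin,
                            pmean = fx$targets$pmean),
    alpha = list(low = -0.15, high = -0.08, order = 3L),
    solver = list(dt = 0.002, max_cycles = 6L, periodicity_tol = 1e-6),
    period = fx$period,
    totals = list(rp = fx$totals$rp, rd = fx$totals$rd, c = fx$totals$c))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
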