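# Pipeline: propagate the uncertain split value alpha through the tuning
# rule and the 0D forward model, building polynomial-chaos surrogates of
# the time-resolved quantities of interest.

#' Propagate split-value uncertainty through tuning and the forward model
#'
#' Runs [apply_alpha()] + [simulate_network()] at each collocation node of
#' the uniform alpha distribution and projects every quantity of interest
#' (per-outlet flows, junction pressure, pressure drop) onto the
#' polynomial-chaos basis, per time sample.
#'
#' @param total calibrated total [windkessel_params()].
#' @param geom an [outlet_geometry()].
#' @param inflow inlet flow [waveform()].
#' @param param an [uncertain_param()] for alpha.
#' @param n_nodes number of Gauss-Legendre collocation nodes (default
#'   `param$order + 1`); ignored when `alphas` is given.
#' @param alphas optional explicit alpha values (e.g. rounded collocation
#'   points); the projection then uses least squares and needs
#'   `length(alphas) >= param$order + 1`.
#' @param settings a [solver_settings()] for the forward runs.
#' @param coa optional [coa_element()] passed to the forward model.
#' @return an object of class `"alpha_propagation"`: list with `nodes`,
#'   `times`, `expansions` (named list of [gpc_project()] objects for each
#'   outlet flow, `junction_pressure` and `dp`), and `node_summaries`
#'   (data.frame of per-node mean outlet flows, cm^3/s).
#' @export
propagate_alpha <- function(total, geom, inflow, param = uncertain_param(),
                            n_nodes = param$order + 1L, alphas = NULL,
                            settings = solver_settings(), coa = NULL) {
  stopifnot(inherits(param, "uncertain_param"))
  if (is.null(alphas)) {
    nodes <- quadrature_nodes(param, n_nodes)$nodes
    ls_nodes <- NULL
  } else {
    nodes <- as.numeric(alphas)
    if (length(nodes) < param$order + 1L) {
      stop("need at least order + 1 alpha values")
    }
    ls_nodes <- nodes
  }
  sims <- lapply(nodes, function(a) {
    simulate_network(inflow, apply_alpha(total, geom, a),
                     settings = settings, coa = coa)
  })
  times <- sims[[1L]]$junction_pressure$times
  period <- sims[[1L]]$junction_pressure$period
  stack <- function(extract) {
    do.call(rbind, lapply(sims, function(s) extract(s)$values))
  }
  qois <- c(
    lapply(names(sims[[1L]]$outlet_flows), function(nm) {
      function(s) s$outlet_flows[[nm]]
    }),
    list(function(s) s$junction_pressure),
    if (!is.null(sims[[1L]]$dp)) list(function(s) s$dp)
  )
  qoi_names <- c(paste0("flow_", names(sims[[1L]]$outlet_flows)),
                 "junction_pressure",
                 if (!is.null(sims[[1L]]$dp)) "dp")
  expansions <- lapply(qois, function(extract) {
    gpc_project(stack(extract), param, order = param$order, nodes = ls_nodes)
  })
  names(expansions) <- qoi_names
  node_summaries <- data.frame(
    alpha = nodes,
    t(vapply(sims, function(s) {
      vapply(s$outlet_flows, wf_mean, numeric(1L))
    }, numeric(length(sims[[1L]]$outlet_flows)))))
  names(node_summaries)[-1L] <- paste0("mean_flow_",
                                       names(sims[[1L]]$outlet_flows))
  structure(list(nodes = nodes, times = times, period = period,
                 expansions = expansions, node_summaries = node_summaries,
                 sims = sims),
            class = "alpha_propagation")
}

#' @export
print.alpha_propagation <- function(x, ...) {
  cat(sprintf("<alpha_propagation> %d nodes on [%g, %g], %d QoIs, %d samples/cycle\n",
              length(x$nodes), min(x$nodes), max(x$nodes),
              length(x$expansions), length(x$times)))
  invisible(x)
}

#' Stochastic moment waveforms of a propagated quantity
#'
#' Convenience accessor: mean and standard-deviation waveforms of one
#' quantity of interest from an [propagate_alpha()] result.
#'
#' @param prop an `"alpha_propagation"` object.
#' @param qoi name of the quantity (e.g. `"flow_da"`, `"dp"`).
#' @return list of two [waveform()]s, `mean` and `std`.
#' @export
propagation_moments <- function(prop, qoi) {
  stopifnot(inherits(prop, "alpha_propagation"))
  if (!qoi %in% names(prop$expansions)) {
    stop(sprintf("unknown quantity '%s'; available: %s", qoi,
                 paste(names(prop$expansions), collapse = ", ")))
  }
  units <- if (startsWith(qoi, "flow")) "cm3/s" else "barye"
  m <- gpc_moments(prop$expansions[[qoi]])
  list(mean = waveform(prop$times, m$mean, prop$period, units = units),
       std = waveform(prop$times, m$std, prop$period, units = units))
}
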