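#' Three-element Windkessel parameter triplet
#'
#' The RCR model: proximal resistance `rp` in series with the parallel pair
#' of compliance `c` and distal resistance `rd`.  All values are in CGS
#' units: resistances in g cm^-4 s^-1, compliance in g^-1 cm^4 s^2.  The
#' time constant of the model is `tau = rd * c`.
#'
#' @param rp proximal resistance, > 0.
#' @param rd distal resistance, > 0.
#' @param c compliance, > 0.
#' @return an object of class `"windkessel_params"`.
#' @examples
#' wk <- windkessel_params(56.32, 845.56, 1.06e-3)
#' wk_tau(wk)
#' @export
windkessel_params <- function(rp, rd, c) {
  vals <- c(rp = as.numeric(rp), rd = as.numeric(rd), c = as.numeric(c))
  if (length(vals) != 3L || !all(is.finite(vals)) || any(vals <= 0)) {
    stop("rp, rd and c must be single positive finite numbers")
  }
  structure(as.list(vals), class = "windkessel_params")
}

#' @rdname windkessel_params
#' @param params a `windkessel_params` object.
#' @export
wk_tau <- function(params) {
  stopifnot(inherits(params, "windkessel_params"))
  params$rd * params$c
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf(
    "<windkessel_params> Rp = %.4g, Rd = %.4g g cm^-4 s^-1, C = %.4g g^-1 cm^4 s^2 (tau = %.4g s)\n",
    x$rp, x$rd, x$c, wk_tau(x)))
  invisible(x)
}

#' Outlet cross-sectional geometry of the aortic model
#'
#' Areas (cm^2) of the three supra-aortic branches (brachiocephalic, left
#' common carotid, left subclavian), of the descending aorta, and the
#' minimum cross-section at the coarctation site.  `da_area_mode` selects
#' which area represents the descending-aorta pathway when distributing
#' lumped parameters: `"coa"` (pre-stenting: the coarctation throat adds
#' resistance, so its minimum area is used) or `"da"` (post-stenting: the
#' restored descending-aorta cross-section).
#'
#' @param bca,lcca,lsa supra-aortic branch areas, cm^2.
#' @param da descending aorta area, cm^2.
#' @param coa minimum coarctation area, cm^2; must not exceed `da`.
#' @param da_area_mode `"coa"` or `"da"`.
#' @return an object of class `"outlet_geometry"`.
#' @export
outlet_geometry <- function(bca, lcca, lsa, da, coa,
                            da_area_mode = c("coa", "da")) {
  da_area_mode <- match.arg(da_area_mode)
  areas <- c(bca = as.numeric(bca), lcca = as.numeric(lcca),
             lsa = as.numeric(lsa), da = as.numeric(da),
             coa = as.numeric(coa))
  if (!all(is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be positive and finite")
  }
  if (areas[["coa"]] > areas[["da"]] + 1e-12) {
    stop("coarctation area cannot exceed the descending aorta area")
  }
  structure(list(bca = areas[["bca"]], lcca = areas[["lcca"]],
                 lsa = areas[["lsa"]], da = areas[["da"]],
                 coa = areas[["coa"]], da_area_mode = da_area_mode),
            class = "outlet_geometry")
}

# area used for the descending-aorta pathway under the selected mode
da_pathway_area <- function(geom) {
  if (geom$da_area_mode == "coa") geom$coa else geom$da
}

#' @export
print.outlet_geometry <- function(x, ...) {
  cat(sprintf(
    "<outlet_geometry> BCA %.3g, LCCA %.3g, LSA %.3g, DA %.3g, CoA %.3g cm^2 (DA pathway: %s)\n",
    x$bca, x$lcca, x$lsa, x$da, x$coa,
    if (x$da_area_mode == "coa") "CoA area" else "DA area"))
  invisible(x)
}

#' Pressure summary statistics (mmHg)
#'
#' Maximum, minimum and cycle-averaged pressure, as recorded by catheter
#' at the ascending aorta and used as calibration targets.
#'
#' @param pmax,pmin,pmean pressures in mmHg with `pmin <= pmean <= pmax`.
#' @return an object of class `"pressure_summary"`.
#' @export
pressure_summary <- function(pmax, pmin, pmean) {
  vals <- c(pmax = as.numeric(pmax), pmin = as.numeric(pmin),
            pmean = as.numeric(pmean))
  if (!all(is.finite(vals))) stop("pressure summary values must be finite")
  if (vals[["pmin"]] > vals[["pmean"]] + 1e-9 ||
      vals[["pmean"]] > vals[["pmax"]] + 1e-9) {
    stop("pressure summary must satisfy pmin <= pmean <= pmax")
  }
  structure(as.list(vals), class = "pressure_summary")
}

#' @export
print.pressure_summary <- function(x, ...) {
  cat(sprintf("<pressure_summary> max %.4g / min %.4g / mean %.4g mmHg\n",
              x$pmax, x$pmin, x$pmean))
  invisible(x)
}

#' Per-outlet Windkessel boundary-condition set
#'
#' A named collection of RCR triplets, one per outlet, together with the
#' split value `alpha` used to build it (`alpha = 0` for the plain
#' area-distributed set).  The canonical outlet names are `bca`, `lcca`,
#' `lsa`, `da`, but any non-empty named list is accepted so that degenerate
#' networks (a single outlet, say) can be simulated.
#'
#' @param outlets named list of [windkessel_params()].
#' @param alpha dimensionless split value recorded with the set.
#' @return an object of class `"outlet_bc_set"`.
#' @export
outlet_bc_set <- function(outlets, alpha = 0) {
  if (!is.list(outlets) || length(outlets) < 1L ||
      is.null(names(outlets)) || any(names(outlets) == "")) {
    stop("`outlets` must be a non-empty named list")
  }
  ok <- vapply(outlets, inherits, logical(1L), what = "windkessel_params")
  if (!all(ok)) stop("every outlet must be a windkessel_params object")
  alpha <- as.numeric(alpha)
  if (length(alpha) != 1L || !is.finite(alpha)) stop("`alpha` must be a finite scalar")
  structure(list(outlets = outlets, alpha = alpha), class = "outlet_bc_set")
}

#' @export
print.outlet_bc_set <- function(x, ...) {
  cat(sprintf("<outlet_bc_set> %d outlets, alpha = %g\n",
              length(x$outlets), x$alpha))
  for (nm in names(x$outlets)) {
    p <- x$outlets[[nm]]
    cat(sprintf("  %-5s Rp %10.2f  Rd %11.2f  C %.3e\n", nm, p$rp, p$rd, p$c))
  }
  invisible(x)
}
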