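# Distribution of total lumped parameters to the model outlets by
# cross-sectional area, with the coarctation-area substitution for the
# descending aorta, and the alpha split-value redistribution.
#
# Area rule (per outlet i):   Rp_i = Rp_tot * A_tot / A_i
#                             Rd_i = Rd_tot * A_tot / A_i
#                             C_i  = C_tot  * A_i   / A_tot
# with A_i = A_CoA on the descending-aorta pathway in pre-stenting mode.
#
# Alpha rule: supra-aortic totals R_i = (1 + alpha) R_tot A_tot / A_i; the
# descending aorta absorbs the difference so that the parallel total
# resistance is conserved: R_DA = k R_tot A_tot / A_CoA with
# k = A_CoA / (A_tot - sum_i A_i / (1 + alpha)).

#' Total outlet cross-sectional area
#'
#' Sum of the three supra-aortic areas plus the descending-aorta pathway
#' area selected by the geometry's `da_area_mode` (the minimum coarctation
#' area in pre-stenting mode).
#'
#' @param geom an [outlet_geometry()].
#' @return total area in cm^2.
#' @export
total_area <- function(geom) {
  stopifnot(inherits(geom, "outlet_geometry"))
  geom$bca + geom$lcca + geom$lsa + da_pathway_area(geom)
}

# core distribution over an arbitrary named area vector
distribute_wk <- function(total, areas) {
  stopifnot(inherits(total, "windkessel_params"),
            is.numeric(areas), !is.null(names(areas)), all(areas > 0))
  a_tot <- sum(areas)
  outlets <- lapply(seq_along(areas), function(i) {
    windkessel_params(rp = total$rp * a_tot / areas[[i]],
                      rd = total$rd * a_tot / areas[[i]],
                      c = total$c * areas[[i]] / a_tot)
  })
  names(outlets) <- names(areas)
  outlet_bc_set(outlets, alpha = 0)
}

# named area vector for the four-outlet aortic model
.outlet_areas <- function(geom) {
  c(bca = geom$bca, lcca = geom$lcca, lsa = geom$lsa,
    da = da_pathway_area(geom))
}

#' Distribute total Windkessel parameters to the four outlets by area
#'
#' Resistances scale inversely and compliances proportionally with outlet
#' area; the descending-aorta pathway uses the minimum coarctation area in
#' pre-stenting mode, which encodes the extra resistance of the narrowing
#' geometrically.
#'
#' @param total a [windkessel_params()] triplet of total values.
#' @param geom an [outlet_geometry()].
#' @return an [outlet_bc_set()] with `alpha = 0`.
#' @export
distribute_by_area <- function(total, geom) {
  stopifnot(inherits(geom, "outlet_geometry"))
  distribute_wk(total, .outlet_areas(geom))
}

#' Compact coarctation factor k(alpha)
#'
#' `k = A_CoA / (A_tot - sum_i A_i / (1 + alpha))`, where the sum runs over
#' the supra-aortic branches.  `k = 1` at `alpha = 0`.  The admissible
#' alpha range is bounded below by positivity of the denominator (the
#' descending-aorta resistance diverges as the supra-aortic share of the
#' conductance approaches the total).
#'
#' @param geom an [outlet_geometry()].
#' @param alpha dimensionless split value.
#' @return dimensionless k.
#' @export
coa_k_factor <- function(geom, alpha) {
  stopifnot(inherits(geom, "outlet_geometry"),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= -1) stop("alpha must be > -1")
  a_path <- da_pathway_area(geom)
  a_tot <- total_area(geom)
  supra <- geom$bca + geom$lcca + geom$lsa
  denom <- a_tot - supra / (1 + alpha)
  if (denom <= 0) {
    stop(sprintf("alpha = %g is outside the admissible range for this geometry (nonpositive denominator)",
                 alpha))
  }
  a_path / denom
}

#' Redistribute outlet resistances with the split value alpha
#'
#' Supra-aortic outlets receive total resistance
#' `R_i = (1 + alpha) R_tot A_tot / A_i`; the descending aorta receives
#' `R_DA = k R_tot A_tot / A_CoA` so that the parallel total resistance is
#' conserved for every admissible alpha.  Each outlet's total resistance is
#' split into proximal and distal parts in the constant ratio `Rp : Rd` of
#' the calibrated totals; compliances follow the plain area rule and do not
#' depend on alpha.
#'
#' @inheritParams distribute_by_area
#' @param alpha dimensionless split value (0 recovers
#'   [distribute_by_area()]).
#' @return an [outlet_bc_set()] recording `alpha`.
#' @export
apply_alpha <- function(total, geom, alpha) {
  stopifnot(inherits(total, "windkessel_params"),
            inherits(geom, "outlet_geometry"))
  k <- coa_k_factor(geom, alpha)       # validates alpha
  areas <- .outlet_areas(geom)
  a_tot <- sum(areas)
  r_tot <- total$rp + total$rd
  f_p <- total$rp / r_tot              # proximal fraction, preserved
  r_out <- c((1 + alpha) * r_tot * a_tot / areas[c("bca", "lcca", "lsa")],
             da = k * r_tot * a_tot / areas[["da"]])
  outlets <- lapply(names(areas), function(nm) {
    windkessel_params(rp = f_p * r_out[[nm]],
                      rd = (1 - f_p) * r_out[[nm]],
                      c = total$c * areas[[nm]] / a_tot)
  })
  names(outlets) <- names(areas)
  outlet_bc_set(outlets, alpha = alpha)
}

#' Parallel total resistance of an outlet set
#'
#' `1/R = sum_i 1/(Rp_i + Rd_i)` over the outlets; for any set built by
#' [apply_alpha()] this equals the calibrated `Rp + Rd` exactly.
#'
#' @param bcs an [outlet_bc_set()].
#' @return total resistance in g cm^-4 s^-1.
#' @export
parallel_total_resistance <- function(bcs) {
  stopifnot(inherits(bcs, "outlet_bc_set"))
  1 / sum(vapply(bcs$outlets, function(p) 1 / (p$rp + p$rd), numeric(1L)))
}
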