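# Generalized polynomial chaos over one uniform uncertain parameter
# (the split value alpha).  Basis: Legendre polynomials mapped to the
# parameter interval and normalised to unit norm under the uniform
# probability measure, so all basis norms are 1, the mean is the zeroth
# coefficient and the standard deviation is the Euclidean norm of the
# remaining coefficients.  With M = 1 parameter the tensor truncation
# Lambda = prod(P_i + 1) - 1 reduces to Lambda = order.

#' Uncertain uniform parameter for polynomial-chaos propagation
#'
#' @param low,high interval bounds of the uniform distribution.  The
#'   defaults cover the split-value range explored for the pre-stenting
#'   coarctation model.
#' @param order maximum polynomial degree of the expansion (>= 0).
#' @return an object of class `"uncertain_param"`.
#' @export
uncertain_param <- function(low = -0.15, high = -0.08, order = 3L) {
  if (!(low < high)) stop("require low < high")
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  structure(list(low = low, high = high, order = order),
            class = "uncertain_param")
}

# orthonormal Legendre design matrix: rows = points, cols = degrees 0..kmax
.phi_matrix <- function(xi, param, kmax) {
  z <- 2 * (xi - param$low) / (param$high - param$low) - 1
  n <- length(z)
  P <- matrix(0, nrow = n, ncol = kmax + 1L)
  P[, 1L] <- 1
  if (kmax >= 1L) P[, 2L] <- z
  if (kmax >= 2L) {
    for (k in 2L:kmax) {
      P[, k + 1L] <- ((2 * k - 1) * z * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  sweep(P, 2L, sqrt(2 * seq(0L, kmax) + 1), "*")
}

#' Gauss-Legendre collocation nodes on the parameter interval
#'
#' Nodes and weights of the n-point Gauss-Legendre rule mapped affinely to
#' `[low, high]`, with weights normalised to the probability measure (they
#' sum to 1).
#'
#' @param param an [uncertain_param()].
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`.
#' @export
quadrature_nodes <- function(param, n) {
  stopifnot(inherits(param, "uncertain_param"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) {
    return(list(nodes = (param$low + param$high) / 2, weights = 1))
  }
  gl <- pracma::gaussLegendre(n, param$low, param$high)
  list(nodes = gl$x, weights = gl$w / (param$high - param$low))
}

#' Project model evaluations onto the polynomial-chaos basis
#'
#' Galerkin coefficients `a_k = <X, Phi_k> / <Phi_k, Phi_k>` computed by
#' Gaussian quadrature when the evaluations sit at the Gauss-Legendre nodes
#' (the default), or by least squares when arbitrary `nodes` are supplied
#' (e.g. rounded collocation values) with more points than the order.
#' Waveform-valued quantities are projected independently per time sample
#' (one column per sample).
#'
#' @param evaluations numeric vector (one value per node) or matrix
#'   (nodes x output components).
#' @param param an [uncertain_param()].
#' @param order maximum degree (default `param$order`); the number of nodes
#'   must be at least `order + 1`.
#' @param nodes optional node locations for the least-squares path.
#' @return an object of class `"gpc_expansion"` with the coefficient
#'   matrix `coefficients` ((order+1) x components).
#' @export
gpc_project <- function(evaluations, param, order = param$order,
                        nodes = NULL) {
  stopifnot(inherits(param, "uncertain_param"))
  X <- if (is.matrix(evaluations)) evaluations else
    matrix(evaluations, ncol = 1L)
  n <- nrow(X)
  order <- as.integer(order)
  if (n < order + 1L) {
    stop("need at least order + 1 evaluation nodes")
  }
  if (is.null(nodes)) {
    q <- quadrature_nodes(param, n)
    Phi <- .phi_matrix(q$nodes, param, order)
    A <- t(Phi) %*% (q$weights * X)
  } else {
    stopifnot(length(nodes) == n)
    Phi <- .phi_matrix(nodes, param, order)
    A <- qr.coef(qr(Phi), X)
    A[is.na(A)] <- 0
  }
  structure(list(coefficients = A, param = param, order = order),
            class = "gpc_expansion")
}

#' @export
print.gpc_expansion <- function(x, ...) {
  cat(sprintf("<gpc_expansion> order %d on [%g, %g], %d output component(s)\n",
              x$order, x$param$low, x$param$high, ncol(x$coefficients)))
  invisible(x)
}

#' Evaluate a polynomial-chaos surrogate
#'
#' @param exp a [gpc_project()] expansion.
#' @param xi parameter values; values outside the interval trigger a
#'   warning (extrapolation).
#' @return numeric vector (single component) or matrix
#'   (length(xi) x components).
#' @export
gpc_evaluate <- function(exp, xi) {
  stopifnot(inherits(exp, "gpc_expansion"))
  if (any(xi < exp$param$low - 1e-12 | xi > exp$param$high + 1e-12)) {
    warning("evaluating the polynomial-chaos surrogate outside its interval (extrapolation)")
  }
  out <- .phi_matrix(xi, exp$param, exp$order) %*% exp$coefficients
  if (ncol(out) == 1L) drop(out) else out
}

#' Stochastic mean and standard deviation of an expansion
#'
#' Under the orthonormal basis the mean is the zeroth coefficient and the
#' standard deviation is `sqrt(sum_k>=1 a_k^2)`, per output component.
#'
#' @inheritParams gpc_evaluate
#' @return list with numeric `mean` and `std` (one value per component).
#' @export
gpc_moments <- function(exp) {
  stopifnot(inherits(exp, "gpc_expansion"))
  A <- exp$coefficients
  m <- A[1L, ]
  s <- if (nrow(A) > 1L) sqrt(colSums(A[-1L, , drop = FALSE]^2)) else
    rep(0, ncol(A))
  list(mean = unname(m), std = unname(s))
}

#' Empirical probability density of a surrogate response
#'
#' Samples the uniform parameter, evaluates the surrogate and bins the
#' responses into a normalised histogram (density integrates to 1 per
#' component).  For waveform-valued expansions this yields the
#' time-by-value probability map of the response.
#'
#' @inheritParams gpc_evaluate
#' @param n_samples number of parameter draws (>= 1000).
#' @param seed RNG seed (deterministic output).
#' @param bins number of histogram bins over the global response range.
#' @return list with `breaks` (length bins+1), `mids` (length bins) and
#'   `density` (bins x components matrix).
#' @export
gpc_pdf <- function(exp, n_samples = 5000L, seed = 1L, bins = 40L) {
  stopifnot(inherits(exp, "gpc_expansion"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1000L) stop("n_samples must be >= 1000")
  set.seed(seed)
  xi <- runif(n_samples, exp$param$low, exp$param$high)
  Y <- gpc_evaluate(exp, xi)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  rng <- range(Y)
  if (diff(rng) < 1e-9 * max(1, abs(rng[1L]))) {
    # (near-)constant response: collapse rounding noise into one bin
    Y[] <- mean(rng)
    rng <- mean(rng) + c(-0.5, 0.5)
  }
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  width <- diff(breaks)[1L]
  dens <- apply(Y, 2L, function(col) {
    idx <- findInterval(col, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = bins) / (length(col) * width)
  })
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       density = dens)
}

#' Highest-order contribution ratio of an expansion
#'
#' `|a_Lambda| / sqrt(sum_k a_k^2)` per component (maximum over components
#' for waveform outputs); a small value indicates a converged truncation.
#'
#' @inheritParams gpc_evaluate
#' @return scalar ratio in `[0, 1]`.
#' @export
gpc_convergence <- function(exp) {
  stopifnot(inherits(exp, "gpc_expansion"))
  A <- exp$coefficients
  if (nrow(A) < 2L) stop("convergence ratio needs order >= 1")
  norms <- sqrt(colSums(A^2))
  ratio <- ifelse(norms > 0, abs(A[nrow(A), ]) / norms, 0)
  max(ratio)
}
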