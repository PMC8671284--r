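# Constrained single-objective genetic algorithm (MOGA-II style operator
# family used as a single-objective optimiser) for the total Windkessel
# triplet.  The search space is a uniform grid over the parameter box; the
# initial population is a Sobol sequence snapped to that grid; reproduction
# uses directional crossover, uniform mutation to a random grid value and
# selection, with elitism on a feasibility-first ranking.

#' Genetic algorithm settings
#'
#' Operator probabilities follow the published MOGA-II defaults: directional
#' crossover 0.5, mutation 0.1, selection 0.05.  Each parameter axis is
#' discretised into `grid_points` uniformly spaced values.
#'
#' @param population_size number of individuals (>= 4).
#' @param generations number of reproduction steps.
#' @param p_crossover,p_mutation,p_selection operator probabilities.
#' @param grid_points grid values per parameter (>= 2).
#' @param seed RNG seed; identical seeds give bit-identical runs.
#' @param penalty_weight static penalty weight applied to constraint
#'   violations (mmHg) when forming the scalar fitness.
#' @param n_starts independent restarts of the search (seeds derived from
#'   `seed`); the best final individual across starts is returned.
#' @return an object of class `"ga_settings"`.
#' @export
ga_settings <- function(population_size = 40L, generations = 250L,
                        p_crossover = 0.5, p_mutation = 0.1,
                        p_selection = 0.05, grid_points = 4096L,
                        seed = 1L, penalty_weight = 1e3, n_starts = 2L) {
  s <- list(population_size = as.integer(population_size),
            generations = as.integer(generations),
            p_crossover = p_crossover, p_mutation = p_mutation,
            p_selection = p_selection, grid_points = as.integer(grid_points),
            seed = as.integer(seed), penalty_weight = penalty_weight,
            n_starts = as.integer(n_starts))
  probs <- c(s$p_crossover, s$p_mutation, s$p_selection)
  if (any(probs < 0 | probs > 1)) stop("operator probabilities must be in [0, 1]")
  if (s$population_size < 4L) stop("population_size must be >= 4")
  if (s$grid_points < 2L) stop("grid_points must be >= 2")
  if (s$generations < 1L) stop("generations must be >= 1")
  if (s$n_starts < 1L) stop("n_starts must be >= 1")
  structure(s, class = "ga_settings")
}

#' Total-Windkessel calibration problem
#'
#' Defines the constrained fit of the total RCR triplet to catheter
#' pressure statistics: minimise `(Pmean(x) - Pmean_target)^2` subject to
#' `|Pmax(x) - Pmax_target| <= eps_max` and
#' `|Pmin(x) - Pmin_target| <= eps_min`, with `x = (Rp, Rd, C)` bounded in
#' a box.  Pressure summaries are computed by driving the Windkessel model
#' with `inflow` from the periodic initial pressure.
#'
#' @param targets a [pressure_summary()] (mmHg).
#' @param inflow a flow [waveform()].
#' @param lower,upper named numeric vectors `c(rp=, rd=, c=)` bounding the
#'   search box (CGS units).  The defaults bracket physiological aortic
#'   totals with wide margin.
#' @param eps_max,eps_min constraint tolerances in mmHg (default 0.001).
#' @param eps_run practical tolerance (mmHg) governing the feasibility
#'   ranking during the search; the nominal `eps_*` are reported in the
#'   result diagnostics.
#' @return an object of class `"calibration_problem"`.
#' @export
calibration_problem <- function(targets, inflow,
                                lower = c(rp = 5, rd = 100, c = 1e-4),
                                upper = c(rp = 300, rd = 5000, c = 1e-2),
                                eps_max = 0.001, eps_min = 0.001,
                                eps_run = 0.5) {
  if (!inherits(targets, "pressure_summary")) {
    targets <- do.call(pressure_summary, as.list(targets))
  }
  stopifnot(inherits(inflow, "waveform"))
  nm <- c("rp", "rd", "c")
  lower <- lower[nm]; upper <- upper[nm]
  if (any(is.na(lower)) || any(is.na(upper))) {
    stop("`lower` and `upper` must be named vectors with rp, rd, c")
  }
  if (any(lower >= upper)) stop("require lower < upper componentwise")
  if (any(lower <= 0)) stop("bounds must be positive")
  if (eps_max < 0 || eps_min < 0 || eps_run < 0) stop("tolerances must be >= 0")
  structure(list(targets = targets, inflow = inflow,
                 lower = lower, upper = upper,
                 eps_max = eps_max, eps_min = eps_min, eps_run = eps_run),
            class = "calibration_problem")
}

#' Objective and constraint violations for a candidate triplet
#'
#' @param x a [windkessel_params()] candidate.
#' @param prob a [calibration_problem()].
#' @return list with `objective` (mmHg^2), `violations` (named pair of
#'   mmHg, clipped below at 0, using the nominal `eps_max`/`eps_min`), and
#'   the achieved `summary`.
#' @export
objective_and_constraints <- function(x, prob) {
  stopifnot(inherits(x, "windkessel_params"),
            inherits(prob, "calibration_problem"))
  s <- summarize_pressure(wk_pressure(x, prob$inflow))
  t <- prob$targets
  list(objective = (s$pmean - t$pmean)^2,
       violations = c(max = max(0, abs(s$pmax - t$pmax) - prob$eps_max),
                      min = max(0, abs(s$pmin - t$pmin) - prob$eps_min)),
       summary = s)
}

# grid values along each axis
.ga_grid <- function(prob, settings) {
  lapply(seq_along(prob$lower), function(j) {
    seq(prob$lower[[j]], prob$upper[[j]], length.out = settings$grid_points)
  })
}

# snap a matrix of candidates (rows) to the nearest grid value, clipping
.ga_snap <- function(X, prob, settings) {
  g <- settings$grid_points
  for (j in seq_len(ncol(X))) {
    lo <- prob$lower[[j]]; hi <- prob$upper[[j]]
    u <- (pmin(pmax(X[, j], lo), hi) - lo) / (hi - lo)
    X[, j] <- lo + round(u * (g - 1)) / (g - 1) * (hi - lo)
  }
  X
}

#' Sobol-initialised population on the parameter grid
#'
#' @inheritParams objective_and_constraints
#' @param settings a [ga_settings()].
#' @return a `population_size x 3` matrix with columns rp, rd, c, each
#'   entry a grid value inside the bounds.  Deterministic given the seed.
#' @export
sobol_population <- function(prob, settings) {
  stopifnot(inherits(prob, "calibration_problem"),
            inherits(settings, "ga_settings"))
  U <- sobol_sequence(settings$population_size, dim = 3L, skip = 1L)
  X <- matrix(0, nrow = nrow(U), ncol = 3L,
              dimnames = list(NULL, c("rp", "rd", "c")))
  for (j in 1:3) {
    X[, j] <- prob$lower[[j]] + U[, j] * (prob$upper[[j]] - prob$lower[[j]])
  }
  .ga_snap(X, prob, settings)
}

# ---- generic GA core ------------------------------------------------------
# eval_fn(row) -> list(objective, violations = numeric vector >= 0)

.ga_eval_pop <- function(X, eval_fn) {
  n <- nrow(X)
  obj <- numeric(n); viol <- numeric(n)
  for (i in seq_len(n)) {
    e <- eval_fn(X[i, ])
    obj[i] <- e$objective
    viol[i] <- sum(e$violations)
  }
  list(objective = obj, violation = viol)
}

# feasibility-first ranking key: feasible individuals (violation == 0)
# always beat infeasible ones; infeasible ones compete on the statically
# penalized objective
.ga_rank_key <- function(fit, w = 1e3) {
  feas <- fit$violation <= 0
  offset <- max(fit$objective[feas], 0, na.rm = TRUE) + 1
  ifelse(feas, fit$objective, offset + fit$objective + w * fit$violation)
}

.ga_penalized <- function(fit, w) fit$objective + w * fit$violation

# one reproduction step of the generic GA core
.ga_step_core <- function(X, fit, eval_fn, lower, upper, settings,
                          snap = identity) {
  n <- nrow(X)
  key <- .ga_rank_key(fit, settings$penalty_weight)
  elite_i <- which.min(key)
  elite <- X[elite_i, , drop = FALSE]
  elite_fit <- list(objective = fit$objective[elite_i],
                    violation = fit$violation[elite_i])
  Y <- X
  for (i in seq_len(n)) {
    child <- X[i, ]
    if (runif(1) < settings$p_selection) {
      better <- which(key < key[i])
      if (length(better) > 0L) {
        child <- X[better[sample.int(length(better), 1L)], ]
      }
    }
    if (runif(1) < settings$p_crossover) {
      # directional: partner drawn as the best of a small tournament, so the
      # move is usually toward an improving region
      cand <- sample.int(n, 3L, replace = TRUE)
      j <- cand[which.min(key[cand])]
      dir <- if (key[j] < key[i]) 1 else -1     # toward better, away from worse
      u <- runif(length(child))
      child <- child + dir * u * (X[j, ] - child)
    }
    if (runif(1) < settings$p_mutation) {
      # either a fresh uniform grid value on one coordinate (global
      # exploration) or a small joint perturbation of all coordinates
      # (local drift along the thin feasible set, where single-coordinate
      # moves are blocked by the constraints)
      u <- runif(1)
      if (u < 0.5) {
        k <- sample.int(length(child), 1L)
        child[k] <- runif(1, lower[[k]], upper[[k]])
      } else {
        # two step scales: the finer one matters when two constraints are
        # active and the improving cone is narrow
        rng <- unlist(upper) - unlist(lower)
        sdev <- if (u < 0.75) 0.01 else 0.001
        child <- child + rnorm(length(child), sd = sdev) * rng
      }
    }
    Y[i, ] <- pmin(pmax(child, unlist(lower)), unlist(upper))
  }
  Y <- snap(Y)
  fitY <- .ga_eval_pop(Y, eval_fn)
  # survivor rule: each child competes with its parent
  keyY <- .ga_rank_key(fitY, settings$penalty_weight)
  lost <- keyY > key
  if (any(lost)) {
    Y[lost, ] <- X[lost, ]
    fitY$objective[lost] <- fit$objective[lost]
    fitY$violation[lost] <- fit$violation[lost]
    keyY[lost] <- key[lost]
  }
  # elitism: reinsert the previous elite if it was lost
  if (min(keyY) > min(key)) {
    worst <- which.max(keyY)
    Y[worst, ] <- elite
    fitY$objective[worst] <- elite_fit$objective
    fitY$violation[worst] <- elite_fit$violation
  }
  list(population = Y, fitness = fitY)
}

#' One genetic-algorithm generation
#'
#' Applies selection, directional crossover and mutation with the configured
#' probabilities, snaps offspring to the parameter grid, and preserves the
#' best individual (feasibility-first elitism).
#'
#' @param population matrix of individuals (rows), columns rp, rd, c.
#' @inheritParams sobol_population
#' @return list with the next `population` and its `fitness`
#'   (`objective`, `violation` vectors).
#' @export
ga_step <- function(population, prob, settings) {
  stopifnot(is.matrix(population), ncol(population) == 3L)
  eval_fn <- .calibration_eval_fn(prob)
  fit <- .ga_eval_pop(population, eval_fn)
  .ga_step_core(population, fit, eval_fn, as.list(prob$lower),
                as.list(prob$upper), settings,
                snap = function(X) .ga_snap(X, prob, settings))
}

# evaluation closure for the calibration problem (eps_run feasibility)
.calibration_eval_fn <- function(prob) {
  t <- prob$targets
  force(prob)
  function(row) {
    x <- windkessel_params(row[[1L]], row[[2L]], row[[3L]])
    s <- summarize_pressure(wk_pressure(x, prob$inflow))
    list(objective = (s$pmean - t$pmean)^2,
         violations = c(max(0, abs(s$pmax - t$pmax) - prob$eps_run),
                        max(0, abs(s$pmin - t$pmin) - prob$eps_run)))
  }
}

#' Generic constrained GA minimisation
#'
#' The optimisation core behind [calibrate_total_wk()], exposed for reuse
#' and testing on arbitrary objectives.
#'
#' @param eval_fn function of a numeric vector returning
#'   `list(objective =, violations =)` with violations clipped at 0.
#' @param lower,upper numeric bounds (same length as the decision vector).
#' @param settings a [ga_settings()].
#' @param init optional initial population matrix; default Sobol points
#'   snapped to the grid.
#' @return list with `best` (decision vector), `objective`, `violation`,
#'   `population`, `fitness` and a generation-by-generation `trace`
#'   data.frame.
#' @export
ga_optimize <- function(eval_fn, lower, upper, settings, init = NULL) {
  stopifnot(inherits(settings, "ga_settings"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  set.seed(settings$seed)
  g <- settings$grid_points
  snap <- function(X) {
    for (j in seq_len(d)) {
      u <- (pmin(pmax(X[, j], lower[j]), upper[j]) - lower[j]) /
        (upper[j] - lower[j])
      X[, j] <- lower[j] + round(u * (g - 1)) / (g - 1) * (upper[j] - lower[j])
    }
    X
  }
  if (is.null(init)) {
    U <- sobol_sequence(settings$population_size, dim = min(d, 3L), skip = 1L)
    if (d > ncol(U)) stop("default Sobol initialisation supports dim <= 3")
    X <- sweep(sweep(U[, seq_len(d), drop = FALSE], 2, upper - lower, "*"),
               2, lower, "+")
    X <- snap(X)
  } else {
    X <- snap(init)
  }
  fit <- .ga_eval_pop(X, eval_fn)
  trace <- data.frame(generation = 0L,
                      best_objective = NA_real_, best_violation = NA_real_)
  record <- function(gen, fit) {
    key <- .ga_rank_key(fit, settings$penalty_weight)
    b <- which.min(key)
    data.frame(generation = gen, best_objective = fit$objective[b],
               best_violation = fit$violation[b])
  }
  trace <- record(0L, fit)
  for (gen in seq_len(settings$generations)) {
    stepped <- .ga_step_core(X, fit, eval_fn, as.list(lower), as.list(upper),
                             settings, snap = snap)
    X <- stepped$population
    fit <- stepped$fitness
    trace <- rbind(trace, record(gen, fit))
  }
  key <- .ga_rank_key(fit, settings$penalty_weight)
  b <- which.min(key)
  list(best = X[b, ], objective = fit$objective[b],
       violation = fit$violation[b], population = X, fitness = fit,
       trace = trace)
}

#' Calibrate the total Windkessel triplet against pressure targets
#'
#' Runs the constrained genetic algorithm (`n_starts` independent
#' restarts) and returns the best individual found across starts: feasible
#' under the practical tolerance if any feasible individual exists,
#' otherwise the least-violating one.
#'
#' @inheritParams sobol_population
#' @return list with `params` (a [windkessel_params()]), the achieved
#'   `summary` (mmHg), `objective`, `violation`, logical `feasible`, and
#'   `diagnostics` (the GA trace of the winning start).
#' @export
calibrate_total_wk <- function(prob, settings = ga_settings()) {
  stopifnot(inherits(prob, "calibration_problem"),
            inherits(settings, "ga_settings"))
  eval_fn <- .calibration_eval_fn(prob)
  best <- NULL
  for (start in seq_len(settings$n_starts)) {
    s_i <- settings
    s_i$seed <- as.integer((settings$seed + (start - 1L) * 7919L) %% .Machine$integer.max)
    res <- ga_optimize(eval_fn, lower = unlist(prob$lower),
                       upper = unlist(prob$upper), settings = s_i)
    # feasible beats infeasible; ties broken by objective then violation
    key <- c(res$violation > 0, res$objective, res$violation)
    if (is.null(best) ||
        (key[1L] < best$key[1L]) ||
        (key[1L] == best$key[1L] && key[2L] < best$key[2L]) ||
        (all(key[1:2] == best$key[1:2]) && key[3L] < best$key[3L])) {
      best <- list(res = res, key = key)
    }
  }
  res <- best$res
  params <- windkessel_params(res$best[[1L]], res$best[[2L]], res$best[[3L]])
  s <- summarize_pressure(wk_pressure(params, prob$inflow))
  list(params = params, summary = s, objective = res$objective,
       violation = res$violation, feasible = res$violation <= 0,
       diagnostics = res$trace)
}
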