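#' Configuration of basin-stability estimation
#'
#' @param n_param_samples parameter sets sampled (without replacement) from
#'   the ensemble; all sets are used when the ensemble is smaller.
#' @param n_initial_states perturbed initial states integrated per set.
#' @param perturb_half_width relative half-width h of the initial-state
#'   perturbation: each dynamic coordinate starts at target * (1 + U(-h, h)).
#'   0.15 for the small benchmark models; larger state spaces warrant smaller
#'   values (e.g. 0.105 / 0.101 for the signalling and metabolic models).
#' @param t_end integration horizon before the root solve.
#' @param return_window relative band around the target fixed point within
#'   which the reached fixed point counts as a return (default 90%-110%).
#' @param rtol,atol stiff-solver tolerances.
#' @param seed base seed; state draws are seeded per (set, state) block so
#'   individual trajectories are reproducible.
#' @return object of class `basin_config`.
#' @export
basin_config <- function(n_param_samples = 500L, n_initial_states = 500L,
                         perturb_half_width = 0.15, t_end = 100,
                         return_window = c(0.9, 1.1), rtol = 1e-6,
                         atol = 1e-9, seed = 1L) {
  stopifnot(perturb_half_width > 0, t_end > 0,
            return_window[1] > 0, return_window[1] < 1, return_window[2] > 1)
  structure(list(n_param_samples = as.integer(n_param_samples),
                 n_initial_states = as.integer(n_initial_states),
                 perturb_half_width = perturb_half_width, t_end = t_end,
                 return_window = return_window, rtol = rtol, atol = atol,
                 seed = as.integer(seed)), class = "basin_config")
}

# Fast scalar rhs closure for the integrator (one parameter set).
make_rhs_fun <- function(model, mu) {
  env <- new.env(parent = baseenv())
  for (j in seq_along(model$params)) assign(model$params[j], mu[j], envir = env)
  species <- model$species
  rhs <- model$rhs
  n <- length(species)
  function(t, y, parms) {
    for (j in seq_len(n)) assign(species[j], y[j], envir = env)
    dy <- numeric(n)
    for (j in seq_len(n)) dy[j] <- eval(rhs[[j]], env)
    list(dy)
  }
}

#' Integrate to t_end and root-solve for the reached fixed point
#'
#' Runs the stiff solver from `x0` to `config$t_end`, then polishes the
#' endpoint with a damped Newton iteration on f(x) = 0 (analytic Jacobian,
#' dynamic species only; constant species stay at their initial value). The
#' trajectory counts as stable when every dynamic component of the root lies
#' within `return_window` times the target.
#'
#' @param model an [ode_system].
#' @param mu parameter vector (linear scale, model order or named).
#' @param x0 initial state.
#' @param config a [basin_config].
#' @param target target fixed point for the return judgement (all-ones by
#'   default).
#' @return list with `root` (fixed-point estimate), `stable`, `diverged`,
#'   `endpoint`.
#' @export
converge_to_fixed_point <- function(model, mu, x0, config = basin_config(),
                                    target = rep(1, model$n_phase)) {
  mu <- order_params(model, mu)
  fn <- make_rhs_fun(model, mu)
  sol <- tryCatch(
    suppressWarnings(deSolve::lsoda(
      y = as.numeric(x0), times = c(0, config$t_end), func = fn, parms = NULL,
      rtol = config$rtol, atol = config$atol)),
    error = function(e) NULL)
  bad <- is.null(sol) || nrow(sol) < 2L ||
    any(!is.finite(sol[nrow(sol), -1L])) ||
    abs(sol[nrow(sol), 1L] - config$t_end) > 1e-8
  if (bad)
    return(list(root = rep(NA_real_, model$n_phase), stable = FALSE,
                diverged = TRUE, endpoint = NULL))
  x <- as.numeric(sol[nrow(sol), -1L])
  endpoint <- x
  dyn <- which(!model$constant_mask)
  Pm <- matrix(mu, 1L, model$n_params)
  ok <- FALSE
  for (it in seq_len(60L)) {
    fv <- drop(rhs_eval_batch(model, matrix(x, 1L), Pm))
    if (!all(is.finite(fv))) break
    if (max(abs(fv[dyn])) < 1e-10) { ok <- TRUE; break }
    J <- jac_eval_batch(model, matrix(x, 1L), Pm)[dyn, dyn, 1L]
    step <- tryCatch(solve(J, fv[dyn]), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # damped update, never step more than 50% relative per iteration
    step <- sign(step) * pmin(abs(step), 0.5 * pmax(abs(x[dyn]), 1e-3))
    x[dyn] <- x[dyn] - step
  }
  if (!ok)
    return(list(root = x, stable = FALSE, diverged = FALSE,
                endpoint = endpoint))
  # the root must polish the reached state, not replace it: from a sustained
  # oscillation the solver can still land on the (unstable) fixed point, and
  # crediting that would judge a limit cycle stable
  drift <- max(abs(x[dyn] - endpoint[dyn]) / pmax(abs(target[dyn]), 1e-6))
  polish_ok <- drift <= (config$return_window[2] - 1) / 2
  stable <- polish_ok &&
    all(x[dyn] >= config$return_window[1] * target[dyn] &
          x[dyn] <= config$return_window[2] * target[dyn])
  list(root = x, stable = stable, diverged = FALSE, endpoint = endpoint)
}

#' Monte-Carlo basin-stability estimate of a parameter ensemble
#'
#' For each sampled parameter set, integrates from `n_initial_states`
#' perturbed starts and records the fraction that return to within the
#' window of the target fixed point; reports per-set fractions with their
#' mean and standard error.
#'
#' @param model an [ode_system].
#' @param ensemble matrix/data frame of parameter sets (linear scale,
#'   model-ordered columns), or a `teaps` fit (its accepted sets are used).
#' @param config a [basin_config].
#' @param target target fixed point (all-ones default).
#' @return object of class `basin_estimate`: `per_set_ratio`, `mean`, `sem`,
#'   `n_sets`, `n_states`.
#' @export
estimate_basin_stability <- function(model, ensemble,
                                     config = basin_config(),
                                     target = rep(1, model$n_phase)) {
  if (inherits(ensemble, "teaps")) ensemble <- accepted_sets(ensemble)
  P <- as.matrix(ensemble)
  if (!is.null(colnames(P)) && all(model$params %in% colnames(P)))
    P <- P[, model$params, drop = FALSE]
  stopifnot(nrow(P) >= 1L)
  set.seed(config$seed)
  take <- if (nrow(P) > config$n_param_samples)
    sample(nrow(P), config$n_param_samples) else seq_len(nrow(P))
  dyn <- which(!model$constant_mask)
  h <- config$perturb_half_width
  ratios <- numeric(length(take))
  for (si in seq_along(take)) {
    mu <- P[take[si], ]
    set.seed((config$seed + 1009L * si) %% .Machine$integer.max)
    n_ok <- 0L
    for (st in seq_len(config$n_initial_states)) {
      x0 <- target
      x0[dyn] <- target[dyn] * (1 + stats::runif(length(dyn), -h, h))
      r <- converge_to_fixed_point(model, mu, x0, config, target)
      n_ok <- n_ok + as.integer(r$stable)
    }
    ratios[si] <- n_ok / config$n_initial_states
  }
  structure(list(per_set_ratio = ratios, mean = mean(ratios),
                 sem = if (length(ratios) > 1L)
                   stats::sd(ratios) / sqrt(length(ratios)) else 0,
                 n_sets = length(ratios),
                 n_states = config$n_initial_states),
            class = "basin_estimate")
}

#' @export
print.basin_estimate <- function(x, ...) {
  cat(sprintf("basin stability: %.3f +/- %.3f (SEM; %d sets x %d states)\n",
              x$mean, x$sem, x$n_sets, x$n_states))
  invisible(x)
}

#' Basin-stability trace across the TEAPS stages
#'
#' Re-estimates basin stability for every stored stage snapshot of a TEAPS
#' fit, the data behind stage-progression plots (stability should rise as
#' loose cluster-Newton candidates are refined by the globalization stage).
#'
#' @param fit a `teaps` object run with `keep_history = TRUE`.
#' @param config a [basin_config] (use modest sample counts: every snapshot
#'   triggers `n_param_samples * n_initial_states` integrations).
#' @return data frame with columns `outer`, `stage`, `mean`, `sem`, `n_sets`.
#' @export
basin_trace <- function(fit, config = basin_config()) {
  stopifnot(inherits(fit, "teaps"), length(fit$snapshots) > 0)
  model <- fit$model
  rows <- lapply(fit$snapshots, function(sn) {
    est <- estimate_basin_stability(model, 10^sn$pool, config)
    data.frame(outer = sn$outer, stage = sn$stage, mean = est$mean,
               sem = est$sem, n_sets = est$n_sets)
  })
  do.call(rbind, rows)
}

#' Two-species limit-cycle fixture
#'
#' A planar system with an unstable focus at (1, 1) surrounded by a stable
#' limit cycle of radius sqrt(a): in centered coordinates u = x - 1,
#' du1/dt = a u1 - w u2 - u1 (u1^2 + u2^2), du2/dt = w u1 + a u2 -
#' u2 (u1^2 + u2^2). Orbits near the fixed point spiral out to sustained
#' oscillation, so its basin stability in a +/-15% window is essentially
#' zero — the canonical counterexample the BSR constraint is meant to
#' exclude.
#'
#' @return an [ode_system] with parameters `a` (radial growth rate) and `w`
#'   (angular frequency).
#' @export
limit_cycle_model <- function() {
  ode_system(
    "LC2", c("x1", "x2"), c("a", "w"),
    rhs = list(
      quote(a * (x1 - 1) - w * (x2 - 1) -
              (x1 - 1) * ((x1 - 1)^2 + (x2 - 1)^2)),
      quote(w * (x1 - 1) + a * (x2 - 1) -
              (x2 - 1) * ((x1 - 1)^2 + (x2 - 1)^2))))
}
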