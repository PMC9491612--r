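#' Specification of the biologically-stable-and-resilient (BSR) target
#'
#' Bundles the target fixed point, the relaxation-rate bound, the schedule of
#' observation-region half-widths, and the numerical tolerances used when a
#' parameter set is judged against the BSR condition.
#'
#' @param x_star target fixed point. `NULL` (default) means all-ones of the
#'   model's phase dimension, resolved when the spec meets a model.
#' @param lambda_target negative real; the slowest admissible relaxation rate
#'   at the fixed point, `-1 / t_conv`. Default -0.3 (relaxation visible by
#'   t = 100 in the model's time unit).
#' @param d_schedule strictly increasing half-widths of the observation box
#'   around `x_star`, grown over the globalization subroutines.
#' @param n_obs number of random observation points per sampling.
#' @param weight_w exponent applied to the basin and relaxation terms in the
#'   scalar combination (1-2 sensible; default 2).
#' @param fix_tol acceptance tolerance on the fixed-point residual norm.
#' @param zero_eig_tol eigenvalues with |Re| below this are treated as
#'   structural zeros (neutral directions) and excluded from the relaxation
#'   objective.
#' @param basin_slack contraction slack used by the *search* objective: the
#'   penalized quantity is ReLU(max eig M(x) - basin_slack). At flux-balanced
#'   fixed points of positive-feedback and conserved-cycle motifs a principal
#'   block of M = Df + Df' is exactly singular, so a strict max-eig <= 0
#'   plateau does not exist and a slack-free objective would contract the
#'   whole ensemble to one trade-off point. The default 0.1 =
#'   |lambda_target|/3 requires any unavoidable local expansion to stay well
#'   below the required relaxation rate. The [o_basin] diagnostic itself is
#'   always the strict ReLU(max eig M).
#' @return object of class `bsr_spec`.
#' @export
bsr_spec <- function(x_star = NULL, lambda_target = -0.3,
                     d_schedule = c(0.004, 0.036, 0.1), n_obs = 20,
                     weight_w = 2, fix_tol = 1e-6, zero_eig_tol = 1e-8,
                     basin_slack = 0.1) {
  stopifnot(lambda_target < 0, all(diff(d_schedule) > 0),
            all(d_schedule > 0), all(d_schedule < 1),
            n_obs >= 1, weight_w >= 1, weight_w <= 2,
            fix_tol > 0, zero_eig_tol > 0, basin_slack >= 0)
  structure(list(x_star = x_star, lambda_target = lambda_target,
                 d_schedule = d_schedule, n_obs = n_obs, weight_w = weight_w,
                 fix_tol = fix_tol, zero_eig_tol = zero_eig_tol,
                 basin_slack = basin_slack),
            class = "bsr_spec")
}

resolve_x_star <- function(spec, model) {
  xs <- spec$x_star
  if (is.null(xs)) xs <- rep(1, model$n_phase)
  stopifnot(length(xs) == model$n_phase)
  as.numeric(xs)
}

#' Sample observation points around the fixed point
#'
#' Draws `n_obs` states with each dynamic coordinate at `x_star + U(-d, d)`.
#' Constant species are pinned to their fixed-point value (their coordinate
#' is an input, not dynamic state).
#'
#' @param model an [ode_system].
#' @param spec a [bsr_spec].
#' @param d observation half-width.
#' @param seed integer seed; same seed gives the identical point set.
#' @return list with `points` (`n_obs` x `n_phase` matrix), `half_width`, `seed`.
#' @export
sample_observation_points <- function(model, spec, d, seed = NULL) {
  stopifnot(d >= 0)
  xs <- resolve_x_star(spec, model)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_phase
  pts <- matrix(rep(xs, each = spec$n_obs), spec$n_obs, n)
  dyn <- which(!model$constant_mask)
  if (length(dyn) && d > 0)
    pts[, dyn] <- pts[, dyn] +
      matrix(stats::runif(spec$n_obs * length(dyn), -d, d),
             spec$n_obs, length(dyn))
  colnames(pts) <- model$species
  list(points = pts, half_width = d, seed = seed)
}

# Deterministic observation lattice for reproducible membership tests:
# the 2^n_dyn corners of the half-width-d box plus its centre.
observation_lattice <- function(model, spec, d) {
  xs <- resolve_x_star(spec, model)
  dyn <- which(!model$constant_mask)
  corners <- as.matrix(expand.grid(rep(list(c(-d, d)), length(dyn))))
  pts <- matrix(rep(xs, each = nrow(corners) + 1L), nrow(corners) + 1L,
                model$n_phase)
  pts[seq_len(nrow(corners)), dyn] <- pts[seq_len(nrow(corners)), dyn] + corners
  colnames(pts) <- model$species
  list(points = pts, half_width = d, seed = NA_integer_)
}

# ---- batched objective kernels ---------------------------------------------
# P: m x n_params matrix, linear scale. All exported single-set operations
# wrap these; the search stages and the brute-force filter call them directly.

o_fix_batch <- function(model, P, x_star) {
  m <- nrow(P)
  X <- matrix(rep(x_star, each = m), m, model$n_phase)
  F <- rhs_eval_batch(model, X, P)
  v <- sqrt(rowSums(F * F))
  v[!is.finite(v)] <- Inf
  v
}

# Max real part among non-zero eigenvalues of the fixed-point Jacobian,
# restricted to dynamic species (the constant rows only contribute structural
# zero eigenvalues, which are excluded anyway). NaN when all eigenvalues are
# zero-classified.
max_re_relax_batch <- function(model, P, x_star, zero_eig_tol) {
  m <- nrow(P)
  dyn <- which(!model$constant_mask)
  X <- matrix(rep(x_star, each = m), m, model$n_phase)
  J <- jac_eval_batch(model, X, P)[dyn, dyn, , drop = FALSE]
  drop(max_re_eig_nonzero_batch(J, zero_eig_tol))
}

o_relax_batch <- function(model, P, spec) {
  xs <- resolve_x_star(spec, model)
  mre <- max_re_relax_batch(model, P, xs, spec$zero_eig_tol)
  v <- pmax(0, mre - spec$lambda_target)
  v[is.nan(mre)] <- 0 # no non-zero eigenvalue to penalize
  v
}

# Largest eigenvalue of M(x) = Df(x) + Df(x)^T over the observation points,
# per parameter set, with M taken over the dynamic species. Contraction of
# neighbouring orbits in the dynamic phase space is what the term certifies;
# constant species are fixed inputs.
max_sym_eig_batch <- function(model, P, obs_points) {
  m <- nrow(P)
  dyn <- which(!model$constant_mask)
  k <- nrow(obs_points)
  X <- obs_points[rep(seq_len(k), times = m), , drop = FALSE]
  Pbig <- P[rep(seq_len(m), each = k), , drop = FALSE]
  J <- jac_eval_batch(model, X, Pbig)[dyn, dyn, , drop = FALSE]
  M <- J + aperm(J, c(2L, 1L, 3L))
  lam <- drop(max_eig_sym_batch(M)) # length k*m, grouped by set
  matrix(lam, k, m)
}

# Largest eigenvalue of M over the observation points, per set (no ReLU).
max_sym_eig_over_obs <- function(model, P, obs) {
  lam <- max_sym_eig_batch(model, P, obs$points)
  v <- lam[1L, ]
  for (i in seq_len(nrow(lam))[-1L]) v <- pmax(v, lam[i, ])
  v
}

o_basin_batch <- function(model, P, obs) {
  v <- pmax(0, max_sym_eig_over_obs(model, P, obs))
  v[!is.finite(v)] <- Inf
  v
}

# Full objective record for a batch of parameter sets. `slack` > 0 applies
# the contraction slack to the combined scalar only; the o_basin column is
# always the strict ReLU of the largest eigenvalue of M.
objective_batch <- function(model, P, spec, obs, slack = 0) {
  xs <- resolve_x_star(spec, model)
  ofix <- o_fix_batch(model, P, xs)
  lam <- max_sym_eig_over_obs(model, P, obs)
  obasin <- pmax(0, lam)
  obasin[!is.finite(obasin)] <- Inf
  obasin_eff <- pmax(0, lam - slack)
  obasin_eff[!is.finite(obasin_eff)] <- Inf
  mre <- max_re_relax_batch(model, P, xs, spec$zero_eig_tol)
  orelax <- pmax(0, mre - spec$lambda_target)
  orelax[is.nan(mre)] <- 0
  comb <- ofix^2 + obasin_eff^spec$weight_w + orelax^spec$weight_w
  data.frame(o_fix = ofix, o_basin = obasin, o_relax = orelax,
             combined = comb, max_re = mre)
}

# ---- single-set exported operations ----------------------------------------

#' Fixed-point residual objective O_fix
#'
#' Euclidean norm of f(x*, mu); zero exactly when mu places the prescribed
#' fixed point.
#'
#' @param model an [ode_system].
#' @param mu named numeric parameter vector, linear scale.
#' @param x_star fixed point (default all-ones).
#' @return nonnegative scalar.
#' @export
o_fix <- function(model, mu, x_star = rep(1, model$n_phase)) {
  P <- matrix(order_params(model, mu), 1L)
  o_fix_batch(model, P, x_star)
}

#' Local-contraction objective O_basin
#'
#' ReLU of the largest eigenvalue of the symmetrized Jacobian
#' M(x) = Df(x) + Df(x)' over the observation points. Zero means every
#' observation point certifies local contraction of neighbouring orbits.
#'
#' @inheritParams o_fix
#' @param obs an observation set from [sample_observation_points].
#' @return nonnegative scalar.
#' @export
o_basin <- function(model, mu, obs) {
  P <- matrix(order_params(model, mu), 1L)
  o_basin_batch(model, P, obs)
}

#' Relaxation-timescale objective O_relax
#'
#' ReLU of (largest non-zero real eigenvalue part of the fixed-point Jacobian
#' minus `lambda_target`). Eigenvalues with |Re| below `zero_eig_tol` are
#' neutral directions and excluded; if every eigenvalue is zero-classified the
#' objective is 0 by convention (nothing to penalize).
#'
#' @inheritParams o_fix
#' @param spec a [bsr_spec].
#' @return nonnegative scalar.
#' @export
o_relax <- function(model, mu, spec = bsr_spec()) {
  P <- matrix(order_params(model, mu), 1L)
  o_relax_batch(model, P, spec)
}

#' Combined BSR objective
#'
#' Evaluates all three components and their combinations: the scalar
#' O_fix^2 + O_basin^w + O_relax^w used by the quasi-Newton stage, and the
#' concatenated residual vector used by the cluster-Newton stage.
#'
#' @inheritParams o_relax
#' @param obs observation set; freshly sampled at `max(spec$d_schedule)` when
#'   omitted.
#' @return list with `o_fix`, `o_basin`, `o_relax`, `combined_scalar`,
#'   `residual_vector`, `max_re`.
#' @export
combined_objective <- function(model, mu, spec = bsr_spec(), obs = NULL) {
  if (is.null(obs))
    obs <- sample_observation_points(model, spec, max(spec$d_schedule))
  P <- matrix(order_params(model, mu), 1L)
  r <- objective_batch(model, P, spec, obs)
  list(o_fix = r$o_fix, o_basin = r$o_basin, o_relax = r$o_relax,
       combined_scalar = r$combined, max_re = r$max_re,
       residual_vector = c(r$o_fix, r$o_basin, r$o_relax))
}

accept_bsr_batch <- function(model, P, spec) {
  xs <- resolve_x_star(spec, model)
  ofix <- o_fix_batch(model, P, xs)
  mre <- max_re_relax_batch(model, P, xs, spec$zero_eig_tol)
  ok <- is.finite(ofix) & ofix < spec$fix_tol & !is.nan(mre) &
    is.finite(mre) & mre < 0
  list(accepted = ok, o_fix = ofix, max_re = mre)
}

#' Final BSR acceptance filter
#'
#' A parameter set is accepted when the fixed-point residual satisfies
#' ||f(x*, mu)||_2 < `fix_tol` and the largest non-zero real eigenvalue part
#' of the fixed-point Jacobian is strictly negative. When every eigenvalue is
#' zero-classified, stability cannot be certified and the set is rejected.
#'
#' @inheritParams o_relax
#' @return list with `accepted` (logical) and diagnostic fields `o_fix`,
#'   `max_re`.
#' @export
accept_bsr <- function(model, mu, spec = bsr_spec()) {
  P <- matrix(order_params(model, mu), 1L)
  r <- accept_bsr_batch(model, P, spec)
  list(accepted = r$accepted, o_fix = r$o_fix, max_re = r$max_re)
}
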