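#' Symbolic ODE systems for stability-constrained parameter search
#'
#' An `ode_system` holds the right-hand side of dx/dt = f(x, mu) as symbolic R
#' expressions, one per species, together with the analytically differentiated
#' Jacobian. Species whose derivative is identically zero (boundary inputs,
#' clamped pools) are flagged in `constant_mask`; they take part in rate laws
#' but are not dynamic state.
#'
#' @param name model identifier used in printing and file output.
#' @param species character vector of species identifiers (state order).
#' @param params character vector of kinetic-parameter identifiers.
#' @param rhs list of unevaluated expressions, one per species, whose free
#'   symbols are all in `species` or `params`.
#' @param reactions optional named list of rate-law expressions (used for SBML
#'   export and error messages); purely informational.
#' @param input_flux names of parameters that act as zeroth-order input fluxes
#'   (they get the wider lower search bound).
#' @return an object of class `ode_system`.
#' @export
ode_system <- function(name, species, params, rhs, reactions = NULL,
                       input_flux = character(0)) {
  stopifnot(length(rhs) == length(species), !anyDuplicated(c(species, params)))
  rhs <- lapply(rhs, function(e) if (is.numeric(e)) as.numeric(e) else e)
  syms <- unique(unlist(lapply(rhs, all.vars)))
  unknown <- setdiff(syms, c(species, params))
  if (length(unknown))
    stop("rhs contains symbols that are neither species nor parameters: ",
         paste(unknown, collapse = ", "))
  if (!all(input_flux %in% params))
    stop("input_flux must name parameters of the model")
  constant_mask <- vapply(rhs, is_zero_expr, logical(1))
  n <- length(species)
  jac <- vector("list", n * n) # column-major [i + (j-1)*n] = d f_i / d species_j
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      jac[[i + (j - 1L) * n]] <-
        if (constant_mask[i]) 0 else stats::D(rhs[[i]], species[j])
    }
  }
  np <- length(params)
  jac_mu <- vector("list", n * np) # column-major: d f_i / d param_j
  for (j in seq_len(np)) {
    for (i in seq_len(n)) {
      jac_mu[[i + (j - 1L) * n]] <-
        if (constant_mask[i]) 0 else stats::D(rhs[[i]], params[j])
    }
  }
  structure(
    list(name = name, species = species, params = params, rhs = rhs,
         jacobian = jac, jacobian_mu = jac_mu, reactions = reactions,
         input_flux = input_flux,
         constant_mask = constant_mask,
         n_phase = n, n_params = length(params)),
    class = "ode_system")
}

is_zero_expr <- function(e) is.numeric(e) && length(e) == 1L && e == 0

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system ", x$name, ">  ", x$n_phase, " species, ",
      x$n_params, " parameters\n", sep = "")
  for (i in seq_len(x$n_phase)) {
    tag <- if (x$constant_mask[i]) "  (constant)" else ""
    cat("  d", x$species[i], "/dt = ", deparse1(x$rhs[[i]]), tag, "\n", sep = "")
  }
  invisible(x)
}

# Evaluate a list of expressions on row-aligned state/parameter matrices.
# X: m x n_phase, P: m x n_params. Scalars recycle over the m rows.
eval_exprs <- function(exprs, X, P, species, params) {
  env <- new.env(parent = baseenv())
  for (j in seq_along(species)) assign(species[j], X[, j], envir = env)
  for (j in seq_along(params))  assign(params[j],  P[, j], envir = env)
  m <- nrow(X)
  out <- matrix(0, m, length(exprs))
  for (k in seq_along(exprs)) out[, k] <- eval(exprs[[k]], env)
  out
}

as_row_matrix <- function(v, n, m = 1L) {
  if (is.matrix(v)) v else matrix(v, m, n, byrow = TRUE)
}

# Batched right-hand-side evaluation: X (m x n_phase), P (m x n_params),
# linear-scale parameters. Returns m x n_phase.
rhs_eval_batch <- function(model, X, P) {
  eval_exprs(model$rhs, X, P, model$species, model$params)
}

# Batched analytic Jacobian: returns an n x n x m array (slice = one point).
jac_eval_batch <- function(model, X, P) {
  n <- model$n_phase
  m <- nrow(X)
  flat <- eval_exprs(model$jacobian, X, P, model$species, model$params)
  arr <- array(t(flat), dim = c(n, n, m)) # flat columns are column-major (i,j)
  arr
}

# Batched analytic parameter Jacobian df/dmu: n_phase x n_params x m array.
jac_mu_eval_batch <- function(model, X, P) {
  flat <- eval_exprs(model$jacobian_mu, X, P, model$species, model$params)
  array(t(flat), dim = c(model$n_phase, model$n_params, nrow(X)))
}

order_params <- function(model, mu) {
  if (is.null(names(mu))) {
    stopifnot(length(mu) == model$n_params)
    return(as.numeric(mu))
  }
  miss <- setdiff(model$params, names(mu))
  if (length(miss)) stop("missing parameter values: ", paste(miss, collapse = ", "))
  as.numeric(mu[model$params])
}

#' Evaluate the right-hand side f(x, mu)
#'
#' @param model an [ode_system].
#' @param x numeric state vector (length `n_phase`).
#' @param mu named (or model-ordered) numeric vector of positive parameters,
#'   linear scale.
#' @return numeric vector of time derivatives, one per species; identically 0
#'   for constant species.
#' @export
rhs_eval <- function(model, x, mu) {
  mu <- order_params(model, mu)
  v <- drop(rhs_eval_batch(model, as_row_matrix(x, model$n_phase),
                           as_row_matrix(mu, model$n_params)))
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))[1L]
    stop("rate-law evaluation failed (non-finite derivative) for species ",
         model$species[bad], " in model ", model$name,
         ": d", model$species[bad], "/dt = ", deparse1(model$rhs[[bad]]))
  }
  names(v) <- model$species
  v
}

#' Evaluate the analytic Jacobian D_f(x)
#'
#' Symbolically differentiated at construction time, numerically evaluated
#' here. Rows belonging to constant species are identically zero.
#'
#' @inheritParams rhs_eval
#' @return `n_phase` x `n_phase` numeric matrix.
#' @export
jacobian_eval <- function(model, x, mu) {
  mu <- order_params(model, mu)
  J <- jac_eval_batch(model, as_row_matrix(x, model$n_phase),
                      as_row_matrix(mu, model$n_params))[, , 1L, drop = FALSE]
  J <- matrix(J, model$n_phase, model$n_phase)
  if (any(!is.finite(J)))
    stop("Jacobian evaluation failed (non-finite entry) in model ", model$name)
  dimnames(J) <- list(model$species, model$species)
  J
}

#' Built-in benchmark models T1-T8
#'
#' Eight small mass-action / Michaelis-Menten reaction networks covering
#' positive feedback (T1), negative feedback (T2), a reversible reaction with
#' a regulatory pool (T3), pathway switching (T4), cooperative branches (T5),
#' two-step signalling cascades (T6, T7) and a multiply-regulated reaction
#' (T8). T3 and T8 each carry one constant species.
#'
#' The distributed form of T2 couples s2 to the production reaction twice and
#' disconnects it from its consumption reaction, contradicting the printed
#' reaction list (re3 = k3*[s2] has nowhere to act); by default the corrected
#' wiring d[s2]/dt = re2 - re3 is returned, the literal form is available via
#' `t2_variant = "printed"`.
#'
#' @param id one of `"T1"` ... `"T8"`.
#' @param t2_variant for T2 only: `"corrected"` (default) or `"printed"`.
#' @return an [ode_system].
#' @export
#' @examples
#' m <- bsr_model("T1")
#' rhs_eval(m, c(1, 1, 1), c(k1 = 1, v2 = 2, km2 = 1, k3 = 1, k4 = 1))
bsr_model <- function(id, t2_variant = c("corrected", "printed")) {
  t2_variant <- match.arg(t2_variant)
  switch(
    id,
    T1 = ode_system(
      "T1", c("s1", "s2", "s3"), c("k1", "v2", "km2", "k3", "k4"),
      rhs = list(
        quote(k1 - v2 * s3 * s1 / (km2 + s1)),
        quote(v2 * s3 * s1 / (km2 + s1) - k3 * s2),
        quote(k3 * s2 - k4 * s3)),
      reactions = list(re1 = quote(k1), re2 = quote(v2 * s3 * s1 / (km2 + s1)),
                       re3 = quote(k3 * s2), re4 = quote(k4 * s3)),
      input_flux = "k1"),
    T2 = ode_system(
      "T2", c("s1", "s2", "s3"), c("k1", "v2", "ki2", "k3", "k4"),
      rhs = if (t2_variant == "corrected") list(
        quote(k1 - v2 * s1 / (1 + s3 / ki2)),
        quote(v2 * s1 / (1 + s3 / ki2) - k3 * s2),
        quote(k3 * s2 - k4 * s3))
      else list(
        quote(k1 - v2 * s1 / (1 + s3 / ki2)),
        quote(v2 * s1 / (1 + s3 / ki2) - k1),
        quote(k3 * s2 - k4 * s3)),
      reactions = list(re1 = quote(k1), re2 = quote(v2 * s1 / (1 + s3 / ki2)),
                       re3 = quote(k3 * s2), re4 = quote(k4 * s3)),
      input_flux = "k1"),
    T3 = ode_system(
      "T3", c("s1", "s2", "s3"), c("k1", "k2", "v3", "km3", "k4"),
      rhs = list(
        quote(k1 + v3 * s3 * s2 / (km3 + s2) - k2 * s1),
        quote(k2 * s1 - v3 * s3 * s2 / (km3 + s2) - k4 * s2),
        0),
      reactions = list(re1 = quote(k1), re2 = quote(k2 * s1),
                       re3 = quote(v3 * s3 * s2 / (km3 + s2)),
                       re4 = quote(k4 * s2)),
      input_flux = "k1"),
    T4 = ode_system(
      "T4", c("s1", "s2", "s3"), c("k1", "v2", "ki2", "v3", "ki3", "k4", "k5"),
      rhs = list(
        quote(k1 - v2 * s1 / (1 + s3 / ki2) - v3 * s1 / (1 + s2 / ki3)),
        quote(v2 * s1 / (1 + s3 / ki2) - k4 * s2),
        quote(v3 * s1 / (1 + s2 / ki3) - k5 * s3)),
      reactions = list(re1 = quote(k1), re2 = quote(v2 * s1 / (1 + s3 / ki2)),
                       re3 = quote(v3 * s1 / (1 + s2 / ki3)),
                       re4 = quote(k4 * s2), re5 = quote(k5 * s3)),
      input_flux = "k1"),
    T5 = ode_system(
      "T5", c("s1", "s2", "s3"), c("k1", "k2", "v3", "ki3", "k4", "k5"),
      rhs = list(
        quote(k1 - k2 * s1 * s3 - v3 * s1 / (1 + s2 / ki3)),
        quote(k2 * s1 * s3 - k4 * s2),
        quote(v3 * s1 / (1 + s2 / ki3) - k5 * s3)),
      reactions = list(re1 = quote(k1), re2 = quote(k2 * s1 * s3),
                       re3 = quote(v3 * s1 / (1 + s2 / ki3)),
                       re4 = quote(k4 * s2), re5 = quote(k5 * s3)),
      input_flux = "k1"),
    T6 = ode_system(
      "T6", c("s1", "s2", "s3", "s4"), c("k1", "k2", "v3", "km3", "k4"),
      rhs = list(
        quote(k2 * s2 - k1 * s1),
        quote(k1 * s1 - k2 * s2),
        quote(k4 * s4 - v3 * s2 * s3 / (km3 + s3)),
        quote(v3 * s2 * s3 / (km3 + s3) - k4 * s4)),
      reactions = list(re1 = quote(k1 * s1), re2 = quote(k2 * s2),
                       re3 = quote(v3 * s2 * s3 / (km3 + s3)),
                       re4 = quote(k4 * s4))),
    T7 = ode_system(
      "T7", c("s1", "s2", "s3", "s4"), c("k1", "v2", "km2", "v3", "km3", "k4"),
      rhs = list(
        quote(v2 * s4 * s2 / (km2 + s2) - k1 * s1),
        quote(k1 * s1 - v2 * s4 * s2 / (km2 + s2)),
        quote(k4 * s4 - v3 * s2 * s3 / (km3 + s3)),
        quote(v3 * s2 * s3 / (km3 + s3) - k4 * s4)),
      reactions = list(re1 = quote(k1 * s1),
                       re2 = quote(v2 * s4 * s2 / (km2 + s2)),
                       re3 = quote(v3 * s2 * s3 / (km3 + s3)),
                       re4 = quote(k4 * s4))),
    T8 = ode_system(
      "T8", c("s1", "s2", "s3", "s4"),
      c("k0", "v1", "km1", "fb3", "fb4", "v2", "km2", "v3", "km3"),
      rhs = list(
        quote(k0 - v1 * s1 / (km1 + s1) * 1 / (1 + fb3 * s3 - fb4 * s4)),
        quote(v1 * s1 / (km1 + s1) * 1 / (1 + fb3 * s3 - fb4 * s4) -
                v2 * s2 / (km2 + s2)),
        quote(v2 * s2 / (km2 + s2) - v3 * s3 / (km3 + s3)),
        0),
      reactions = list(
        re0 = quote(k0),
        re1 = quote(v1 * s1 / (km1 + s1) * 1 / (1 + fb3 * s3 - fb4 * s4)),
        re2 = quote(v2 * s2 / (km2 + s2)),
        re3 = quote(v3 * s3 / (km3 + s3))),
      input_flux = "k0"),
    stop("unknown model id: ", id)
  )
}

#' Names of the built-in benchmark models
#' @return character vector `c("T1", ..., "T8")`.
#' @export
builtin_models <- function() paste0("T", 1:8)

#' Log-scale search box for a model's parameters
#'
#' The default box spans 5e-3 to 5e4 for every kinetic parameter except
#' zeroth-order input fluxes, which start at 5e-1.
#'
#' @param model an [ode_system].
#' @param lower,upper box bounds for ordinary parameters (linear scale).
#' @param input_lower lower bound used for input-flux parameters.
#' @return list with named numeric vectors `lower` and `upper`.
#' @export
parameter_space <- function(model, lower = 5e-3, upper = 5e4,
                            input_lower = 5e-1) {
  stopifnot(lower > 0, upper > lower, input_lower > 0)
  lo <- rep(lower, model$n_params)
  names(lo) <- model$params
  lo[model$input_flux] <- input_lower
  up <- rep(upper, model$n_params)
  names(up) <- model$params
  list(lower = lo, upper = up)
}
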