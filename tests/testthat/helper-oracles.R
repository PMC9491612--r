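# Central finite-difference Jacobian oracle, independent of the analytic path.
fd_jacobian <- function(model, x, mu, h = 1e-6) {
  n <- model$n_phase
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (rhs_eval(model, xp, mu) - rhs_eval(model, xm, mu)) / (2 * h)
  }
  J
}

# A linear relaxation fixture dx/dt = -k (x - 1) in one species.
linear_model <- function() {
  ode_system("lin1", "x", "k", list(quote(-k * (x - 1))))
}

# Expanding counterpart dx/dt = +k (x - 1).
repelling_model <- function() {
  ode_system("rep1", "x", "k", list(quote(k * (x - 1))))
}

# Planar rotation about (1,1): antisymmetric Jacobian, M identically zero.
rotation_model <- function() {
  ode_system("rot2", c("x1", "x2"), "w",
             list(quote(-w * (x2 - 1)), quote(w * (x1 - 1))))
}

# Damped coupled linear system with strictly negative-definite M:
# dx/dt = -A (x - 1) with A = [[2, 0.3], [0.3, 1]] (symmetric PD).
contracting_model <- function() {
  ode_system("con2", c("x1", "x2"), c("a11", "a12", "a22"),
             list(quote(-(a11 * (x1 - 1) + a12 * (x2 - 1))),
                  quote(-(a12 * (x1 - 1) + a22 * (x2 - 1)))))
}

random_params <- function(model, seed, lo = 0.1, hi = 10) {
  set.seed(seed)
  mu <- stats::runif(model$n_params, lo, hi)
  names(mu) <- model$params
  mu
}
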