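#' Configuration of a TEAPS run
#'
#' @param spec a [bsr_spec] describing the BSR target.
#' @param space search box from [parameter_space]; `NULL` resolves the default
#'   box for the model at run time.
#' @param n_initial size of each fresh cluster-Newton cloud.
#' @param n_collect collection target of the cluster-Newton stage: iteration
#'   stops once this many candidates satisfy the moderate condition. Keep it
#'   comparable to `n_initial`: the collected pool is (approximately) the
#'   projection of the uniform initial cloud onto the solution region, and a
#'   small target truncates that coverage to the regions that converge first.
#' @param cnm_threshold combined-objective level below which a cloud member
#'   counts as a "moderate" (loose) candidate and is collected; the strict
#'   optimization happens in the globalization stage.
#' @param cnm_max_iter cap on cluster-Newton iterations per outer round.
#' @param n_noise_loops noise-add/re-optimize repetitions per observation
#'   half-width stage.
#' @param noise_sigma_log10 standard deviation (log10 units) of the expansion
#'   noise; halved at each successive loop within a stage. The default of one
#'   decade is set by the search-box scale (seven decades): re-optimization
#'   pulls each perturbed copy back onto the allowable set, so large kicks
#'   relocate members across the region instead of merely dithering them,
#'   which is what lets the ensemble fill broad allowable regions.
#' @param pool_max ceiling on the working pool carried between stages;
#'   trimming subsamples uniformly within the moderate tier to preserve
#'   spatial coverage.
#' @param lbfgs_maxit,lbfgs_memory iteration cap and history length of the
#'   quasi-Newton subroutine.
#' @param twist_theta_max largest direction-twist angle in degrees; each
#'   quasi-Newton iteration draws Uniform(0, theta_max * 0.5^(iter-1)). The
#'   final sweep of the last stage runs untwisted.
#' @param wilcoxon_alpha per-parameter rank-sum significance level of the
#'   stopping rule.
#' @param containment_frac fraction of newly found values that must fall
#'   inside the historical range for the stopping rule.
#' @param max_outer_iters cap on outer (fresh-cloud) rounds.
#' @param seed integer seed; the whole run is reproducible from it.
#' @param keep_history store per-stage snapshots of the pool (needed for
#'   basin-stability traces).
#' @return object of class `teaps_config`.
#' @export
teaps_config <- function(spec = bsr_spec(), space = NULL,
                         n_initial = 500L, n_collect = 400L,
                         cnm_threshold = 0.5, cnm_max_iter = 40L,
                         n_noise_loops = 3L, noise_sigma_log10 = 1.0,
                         pool_max = 400L, lbfgs_maxit = 30L,
                         lbfgs_memory = 6L, twist_theta_max = 30,
                         wilcoxon_alpha = 0.1, containment_frac = 0.99,
                         max_outer_iters = 4L, seed = 1L,
                         keep_history = TRUE) {
  stopifnot(n_initial >= 2, n_collect >= 1, cnm_threshold > 0,
            wilcoxon_alpha > 0, wilcoxon_alpha < 1,
            containment_frac > 0, containment_frac < 1,
            max_outer_iters >= 1, noise_sigma_log10 >= 0)
  structure(list(spec = spec, space = space, n_initial = as.integer(n_initial),
                 n_collect = as.integer(n_collect),
                 cnm_threshold = cnm_threshold,
                 cnm_max_iter = as.integer(cnm_max_iter),
                 n_noise_loops = as.integer(n_noise_loops),
                 noise_sigma_log10 = noise_sigma_log10,
                 pool_max = as.integer(pool_max),
                 lbfgs_maxit = as.integer(lbfgs_maxit),
                 lbfgs_memory = as.integer(lbfgs_memory),
                 twist_theta_max = twist_theta_max,
                 wilcoxon_alpha = wilcoxon_alpha,
                 containment_frac = containment_frac,
                 max_outer_iters = as.integer(max_outer_iters),
                 seed = as.integer(seed), keep_history = keep_history),
            class = "teaps_config")
}

resolve_space <- function(config, model) {
  sp <- config$space
  if (is.null(sp)) sp <- parameter_space(model)
  stopifnot(length(sp$lower) == model$n_params,
            length(sp$upper) == model$n_params)
  sp
}

#' Draw the initial log-uniform parameter cloud
#'
#' @param model an [ode_system].
#' @param config a [teaps_config].
#' @param n cloud size (defaults to `config$n_initial`).
#' @return `n` x `n_params` matrix of log10 parameter values inside the box.
#' @export
init_parameter_cloud <- function(model, config = teaps_config(),
                                 n = config$n_initial) {
  sp <- resolve_space(config, model)
  lo <- log10(sp$lower)
  up <- log10(sp$upper)
  L <- matrix(stats::runif(n * model$n_params), n, model$n_params)
  L <- sweep(sweep(L, 2L, up - lo, "*"), 2L, lo, "+")
  colnames(L) <- model$params
  L
}

clip_box <- function(L, lo, up) {
  for (j in seq_along(lo)) L[, j] <- pmin(pmax(L[, j], lo[j]), up[j])
  L
}

# Objective closure over log10 parameter rows; obs is frozen inside. The
# search stages use the spec's contraction slack in the combined scalar.
make_batch_objective <- function(model, spec, obs) {
  slack <- if (is.null(spec$basin_slack)) 0 else spec$basin_slack
  function(Lmat) objective_batch(model, 10^Lmat, spec, obs, slack = slack)
}

#' Cluster-Newton collection stage
#'
#' Moves the whole cloud toward the zero residual vector (O_fix, O_basin,
#' O_relax) using a shared linear least-squares surrogate per iteration; after
#' each step, members whose combined objective falls below `cnm_threshold` are
#' collected, and iteration stops once `n_collect` candidates are pooled (or
#' the iteration cap is hit). Observation points are resampled each iteration
#' at the smallest half-width of the schedule. A ridge term keeps the
#' surrogate solve well-posed whatever the cloud geometry.
#'
#' @param model an [ode_system].
#' @param config a [teaps_config].
#' @param cloud log10 cloud matrix from [init_parameter_cloud].
#' @return list with `pool` (collected log10 matrix), `objective` (records for
#'   the pool), `iterations`, `hit_max_iter`.
#' @export
cnm_stage <- function(model, config, cloud) {
  spec <- config$spec
  sp <- resolve_space(config, model)
  lo <- log10(sp$lower)
  up <- log10(sp$upper)
  d0 <- spec$d_schedule[1L]
  # residual compression for the surrogate fit: the raw components span many
  # orders of magnitude over the box, which would let the largest residuals
  # dominate the least-squares plane; log1p keeps zero at zero.
  squash <- function(Res) log1p(Res / config$cnm_threshold)
  pool <- list()
  pool_obj <- list()
  n_pooled <- 0L
  it <- 0L
  hit_max <- FALSE
  # Meet the fixed-point condition exactly up front: the minimal-norm
  # Gauss-Newton projection keeps every member close to its original region
  # of the box, so the collected pool inherits the coverage of the uniform
  # cloud. The iterations below then work on the eigenvalue residuals.
  active <- project_fixed_point_pool(model, cloud, spec, lo, up,
                                     tol = 1e-10, maxit = 25L)
  tr_scale <- rep(1, nrow(active)) # per-point trust-region step factor
  R <- NULL
  repeat {
    it <- it + 1L
    obs <- sample_observation_points(model, spec, d0,
                                     seed = sample.int(2^31 - 1L, 1L))
    fb <- make_batch_objective(model, spec, obs)
    R <- fb(active)
    done <- is.finite(R$combined) & R$combined < config$cnm_threshold
    if (any(done)) {
      pool[[length(pool) + 1L]] <- active[done, , drop = FALSE]
      pool_obj[[length(pool_obj) + 1L]] <- R[done, , drop = FALSE]
      n_pooled <- n_pooled + sum(done)
      active <- active[!done, , drop = FALSE]
      R <- R[!done, , drop = FALSE]
      tr_scale <- tr_scale[!done]
    }
    if (n_pooled >= config$n_collect || nrow(active) < 2L) break
    if (it >= config$cnm_max_iter) { hit_max <- TRUE; break }
    Res <- as.matrix(R[, c("o_fix", "o_basin", "o_relax")])
    bad <- !is.finite(rowSums(Res))
    if (any(bad)) { # resample hopeless members instead of carrying Inf
      active[bad, ] <- init_parameter_cloud(model, config, n = sum(bad))
      tr_scale[bad] <- 1
      Rb <- fb(active[bad, , drop = FALSE])
      R[bad, ] <- Rb
      Res[bad, ] <- as.matrix(Rb[, c("o_fix", "o_basin", "o_relax")])
    }
    # shared linear surrogate of the compressed residuals (log10 coords)
    Sq <- squash(Res)
    Lc <- scale(active, center = TRUE, scale = FALSE)
    Sc <- scale(Sq, center = TRUE, scale = FALSE)
    G <- crossprod(Lc) + diag(1e-8 * max(1, sum(diag(crossprod(Lc)))),
                              ncol(Lc))
    B <- solve(G, crossprod(Lc, Sc))           # p x 3 sensitivity surrogate
    BtB <- crossprod(B)
    BtB <- BtB + diag(1e-8 * max(diag(BtB), 1e-4), 3L) # relative ridge
    step <- -Sq %*% solve(BtB, t(B))           # minimal-norm step to zero
    nrm <- sqrt(rowSums(step^2))
    cap <- 2 # log10 units per iteration
    step <- step * (tr_scale * ifelse(nrm > cap, cap / nrm, 1))
    cand <- clip_box(active + step, lo, up)
    Rc <- fb(cand)
    better <- is.finite(Rc$combined) & Rc$combined <= R$combined
    active[better, ] <- cand[better, , drop = FALSE]
    R[better, ] <- Rc[better, , drop = FALSE]
    tr_scale[better] <- pmin(1, tr_scale[better] * 2)
    tr_scale[!better] <- tr_scale[!better] / 2
    stuck <- which(tr_scale < 1 / 64)
    if (length(stuck)) {
      # surrogate steps have stopped helping these members; place their
      # fixed-point residual exactly (a minimal-norm move that keeps the
      # member close to its region of the box) and let the next iteration
      # judge the remaining eigenvalue terms
      active[stuck, ] <- project_fixed_point_pool(
        model, active[stuck, , drop = FALSE], spec, lo, up,
        tol = 1e-10, maxit = 20L)
      Rs <- fb(active[stuck, , drop = FALSE])
      R[stuck, ] <- Rs
      tr_scale[stuck] <- 1
    }
  }
  pool <- if (length(pool)) do.call(rbind, pool)
          else matrix(numeric(0), 0L, model$n_params,
                      dimnames = list(NULL, model$params))
  list(pool = pool,
       objective = if (length(pool_obj)) do.call(rbind, pool_obj) else NULL,
       iterations = it, hit_max_iter = hit_max)
}

# Rotate direction within span(dir, random) by angle theta (radians).
twist_direction <- function(dir, theta) {
  nd <- sqrt(sum(dir^2))
  if (nd == 0 || theta == 0) return(dir)
  u <- dir / nd
  r <- stats::rnorm(length(dir))
  w <- r - sum(r * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) return(dir)
  w <- w / nw
  nd * (cos(theta) * u + sin(theta) * w)
}

# Lock-step projected L-BFGS over many starting points sharing one frozen
# objective. All function and finite-difference gradient evaluations of the
# whole pool are batched, which is what makes a pure-R quasi-Newton sweep
# affordable; the per-set two-loop recursions are tiny.
lbfgs_pool <- function(fbatch_value, L0, lo, up, maxit = 30L, memory = 6L,
                       twist_theta_max = 0, twist_decay = 0.5,
                       fd_step = 1e-4, armijo_c1 = 1e-4, max_ls = 30L,
                       eval_chunk = 4000L) {
  Lmat <- clip_box(as.matrix(L0), lo, up)
  n <- nrow(Lmat)
  p <- ncol(Lmat)
  fchunked <- function(M) {
    if (nrow(M) <= eval_chunk) return(fbatch_value(M))
    out <- numeric(nrow(M))
    for (st in seq(1L, nrow(M), by = eval_chunk)) {
      en <- min(st + eval_chunk - 1L, nrow(M))
      out[st:en] <- fbatch_value(M[st:en, , drop = FALSE])
    }
    out
  }
  n_eval <- 0L
  grad_batch <- function(M, rows) { # central differences, one batched call
    k <- length(rows)
    big <- M[rep(rows, each = 2L * p), , drop = FALSE]
    colidx <- rep(rep(seq_len(p), each = 2L), k)
    ii <- cbind(seq_len(2L * p * k), colidx)
    big[ii] <- big[ii] + rep(c(fd_step, -fd_step), p * k)
    v <- fchunked(big)
    n_eval <<- n_eval + nrow(big)
    vm <- matrix(v, 2L * p, k)
    t((vm[seq(1L, 2L * p, 2L), , drop = FALSE] -
         vm[seq(2L, 2L * p, 2L), , drop = FALSE]) / (2 * fd_step))
  }
  fvals <- fchunked(Lmat)
  n_eval <- n_eval + n
  best_L <- Lmat
  best_f <- fvals
  G <- matrix(NA_real_, n, p)
  ok0 <- which(is.finite(fvals))
  if (length(ok0)) G[ok0, ] <- grad_batch(Lmat, ok0)
  Smem <- array(0, c(n, p, memory))
  Ymem <- array(0, c(n, p, memory))
  rho <- matrix(0, n, memory)
  mlen <- integer(n)
  active <- is.finite(fvals) & rowSums(!is.finite(G)) == 0L
  failed <- rep(FALSE, n)
  it <- 0L
  while (it < maxit && any(active)) {
    it <- it + 1L
    idx <- which(active)
    D <- matrix(0, n, p)
    for (i in idx) {
      q <- G[i, ]
      k <- mlen[i]
      if (k > 0L) {
        a <- numeric(k)
        for (j in k:1) {
          a[j] <- rho[i, j] * sum(Smem[i, , j] * q)
          q <- q - a[j] * Ymem[i, , j]
        }
        gam <- sum(Smem[i, , k] * Ymem[i, , k]) / sum(Ymem[i, , k]^2)
        q <- q * max(gam, 1e-12)
        for (j in 1:k) {
          b <- rho[i, j] * sum(Ymem[i, , j] * q)
          q <- q + (a[j] - b) * Smem[i, , j]
        }
      }
      d <- -q
      if (twist_theta_max > 0) {
        cap <- twist_theta_max * pi / 180 * twist_decay^(it - 1L)
        d <- twist_direction(d, stats::runif(1L, 0, cap))
      }
      if (sum(d * G[i, ]) >= 0) d <- -G[i, ] # safeguard descent
      D[i, ] <- d
    }
    slope <- rowSums(D * G)
    # without curvature history the raw gradient can be huge; start those
    # backtracking searches from a unit-length trial step
    alpha <- rep(1, n)
    fresh <- idx[mlen[idx] == 0L]
    if (length(fresh))
      alpha[fresh] <- pmin(1, 1 / apply(abs(D[fresh, , drop = FALSE]), 1L, max))
    newL <- Lmat
    newF <- fvals
    moved <- rep(FALSE, n)
    weakF <- rep(NA_real_, n)
    weakL <- Lmat
    searching <- active
    for (ls in seq_len(max_ls)) {
      ids <- which(searching)
      if (!length(ids)) break
      cand <- clip_box(Lmat[ids, , drop = FALSE] +
                         alpha[ids] * D[ids, , drop = FALSE], lo, up)
      fc <- fchunked(cand)
      n_eval <- n_eval + length(ids)
      okA <- is.finite(fc) & fc <= fvals[ids] + armijo_c1 * alpha[ids] * slope[ids]
      okW <- is.finite(fc) & fc < fvals[ids] & !okA
      hit <- ids[okA]
      newL[hit, ] <- cand[okA, , drop = FALSE]
      newF[hit] <- fc[okA]
      moved[hit] <- TRUE
      searching[hit] <- FALSE
      w <- ids[okW & is.na(weakF[ids])]
      if (length(w)) {
        weakL[w, ] <- cand[okW & is.na(weakF[ids]), , drop = FALSE]
        weakF[w] <- fc[okW & is.na(weakF[ids])]
      }
      rest <- ids[!okA]
      alpha[rest] <- alpha[rest] / 2
    }
    # near ReLU kinks / eigenvalue crossings the finite-difference slope is
    # unreliable; settle for any strict decrease found during backtracking
    rem <- which(active & !moved & !is.na(weakF))
    if (length(rem)) {
      newL[rem, ] <- weakL[rem, , drop = FALSE]
      newF[rem] <- weakF[rem]
      moved[rem] <- TRUE
    }
    stuck <- which(active & !moved)
    for (i in stuck) {
      if (mlen[i] > 0L) mlen[i] <- 0L # stale memory: retry as steepest descent
      else { active[i] <- FALSE; failed[i] <- TRUE }
    }
    mv <- which(moved)
    if (length(mv)) {
      Gn <- grad_batch(newL, mv)
      for (jj in seq_along(mv)) {
        i <- mv[jj]
        svec <- newL[i, ] - Lmat[i, ]
        yvec <- Gn[jj, ] - G[i, ]
        sy <- sum(svec * yvec)
        if (is.finite(sy) &&
            sy > 1e-12 * sqrt(sum(svec^2) * sum(yvec^2))) {
          if (mlen[i] < memory) {
            mlen[i] <- mlen[i] + 1L
            pos <- mlen[i]
          } else {
            Smem[i, , seq_len(memory - 1L)] <- Smem[i, , 2:memory]
            Ymem[i, , seq_len(memory - 1L)] <- Ymem[i, , 2:memory]
            rho[i, seq_len(memory - 1L)] <- rho[i, 2:memory]
            pos <- memory
          }
          Smem[i, , pos] <- svec
          Ymem[i, , pos] <- yvec
          rho[i, pos] <- 1 / sy
        }
        Lmat[i, ] <- newL[i, ]
        fvals[i] <- newF[i]
        G[i, ] <- Gn[jj, ]
        if (fvals[i] < best_f[i]) {
          best_f[i] <- fvals[i]
          best_L[i, ] <- Lmat[i, ]
        }
        if (!all(is.finite(G[i, ])) || max(abs(svec)) < 1e-12 ||
            max(abs(G[i, ])) < 1e-12) active[i] <- FALSE
      }
    }
  }
  list(par = best_L, value = best_f, iterations = it, evals = n_eval,
       line_search_failed = failed)
}

#' Twisted quasi-Newton optimization of the combined BSR objective
#'
#' Minimizes O_fix^2 + O_basin^w + O_relax^w in log10 parameter space under
#' the box constraints, with the observation set frozen for the whole run so
#' the objective is deterministic for the line search. The search direction
#' of each iteration is rotated by a random angle (bounded by
#' `twist_theta_max`, decaying geometrically) within the plane spanned by the
#' descent direction and a random vector; a zero twist gives plain projected
#' L-BFGS. Gradients are central finite differences (the eigenvalue terms are
#' only piecewise smooth, so analytic derivatives are unavailable at
#' crossings anyway). Returns the best iterate seen; a line-search failure
#' returns the best-so-far with a flag.
#'
#' @param model an [ode_system].
#' @param config a [teaps_config].
#' @param mu0 starting point: log10 parameter vector (model order).
#' @param d observation half-width for this subroutine.
#' @param obs frozen observation set (sampled at `d` if omitted).
#' @param twist logical; `FALSE` forces an untwisted run.
#' @return list with `par` (log10), `objective` (component record at `par`),
#'   `value`, `iterations`, `evals`, `line_search_failed`.
#' @export
m_lbfgs_optimize <- function(model, config, mu0, d, obs = NULL, twist = TRUE) {
  spec <- config$spec
  sp <- resolve_space(config, model)
  if (is.null(obs))
    obs <- sample_observation_points(model, spec, d,
                                     seed = sample.int(2^31 - 1L, 1L))
  fb <- make_batch_objective(model, spec, obs)
  fv <- function(Lmat) fb(Lmat)$combined
  res <- lbfgs_pool(fv, matrix(mu0, 1L), log10(sp$lower), log10(sp$upper),
                    maxit = config$lbfgs_maxit, memory = config$lbfgs_memory,
                    twist_theta_max = if (twist) config$twist_theta_max else 0)
  list(par = res$par[1L, ], value = res$value[1L],
       objective = fb(res$par[1L, , drop = FALSE]),
       iterations = res$iterations, evals = res$evals,
       line_search_failed = res$line_search_failed[1L])
}

# Optimize the rows of a pool with a shared frozen observation set. Members
# that already sit on the zero plateau of the (slacked) objective are left
# untouched: re-optimizing them under a fresh observation draw would ratchet
# the whole ensemble toward the corner of the feasible region where every
# constraint binds, collapsing the coverage the noise loops create.
sweep_pool <- function(model, config, pool, d, twist, polish_fix = 0.1) {
  if (!nrow(pool)) return(pool)
  spec <- config$spec
  sp <- resolve_space(config, model)
  obs <- sample_observation_points(model, spec, d,
                                   seed = sample.int(2^31 - 1L, 1L))
  fb <- make_batch_objective(model, spec, obs)
  fv <- function(Lmat) fb(Lmat)$combined
  R0 <- fb(pool)
  # converged = the contraction and relaxation terms are on their zero
  # plateau and the fixed-point residual is small enough for the final
  # Gauss-Newton projection to absorb; grinding o_fix further here would
  # only re-expose members to the boundary ratchet
  converged <- is.finite(R0$combined) & R0$o_fix <= polish_fix &
    (R0$combined - R0$o_fix^2) <= 1e-14
  need <- which(!converged)
  if (!length(need)) return(pool)
  res <- lbfgs_pool(fv, pool[need, , drop = FALSE],
                    log10(sp$lower), log10(sp$upper),
                    maxit = config$lbfgs_maxit, memory = config$lbfgs_memory,
                    twist_theta_max = if (twist) config$twist_theta_max else 0)
  pool[need, ] <- res$par
  pool
}

# Projection of each pool row onto the fixed-point manifold f(x*, mu) = 0.
# The fixed point is an exact constraint, so it is enforced exactly rather
# than through the penalty (whose gradient balance would leave a residual).
# When the analytic reduction applies (built-in models, all-ones target),
# the constrained parameters are solved in closed form and the free
# coordinates stay untouched -- the same manifold measure the reference
# searches sample. Rows the reduction cannot place (nonpositive solutions,
# box violations) and models without a reduction fall back to a
# minimal-norm Gauss-Newton iteration in log10 coordinates.
project_fixed_point_pool <- function(model, Lmat, spec, lo, up,
                                     tol = 1e-9, maxit = 40L) {
  if (!nrow(Lmat)) return(Lmat)
  if (is.null(spec$x_star)) {
    red <- tryCatch(fixed_point_reduction(model), error = function(e) NULL)
    if (!is.null(red)) {
      ex <- red$expand(10^Lmat[, red$free, drop = FALSE])
      Lnew <- suppressWarnings(log10(ex$P[, model$params, drop = FALSE]))
      in_box <- ex$valid
      for (j in seq_along(lo))
        in_box <- in_box & is.finite(Lnew[, j]) &
          Lnew[, j] >= lo[j] - 1e-12 & Lnew[, j] <= up[j] + 1e-12
      Lmat[in_box, ] <- Lnew[in_box, , drop = FALSE]
      rest <- which(!in_box)
      if (length(rest))
        Lmat[rest, ] <- project_fixed_point_gn(model, Lmat[rest, , drop = FALSE],
                                               spec, lo, up, tol, maxit)
      return(Lmat)
    }
  }
  project_fixed_point_gn(model, Lmat, spec, lo, up, tol, maxit)
}

project_fixed_point_gn <- function(model, Lmat, spec, lo, up,
                                   tol = 1e-9, maxit = 40L) {
  if (!nrow(Lmat)) return(Lmat)
  xs <- resolve_x_star(spec, model)
  dyn <- which(!model$constant_mask)
  active <- rep(TRUE, nrow(Lmat))
  for (it in seq_len(maxit)) {
    idx <- which(active)
    if (!length(idx)) break
    P <- 10^Lmat[idx, , drop = FALSE]
    X <- matrix(rep(xs, each = length(idx)), length(idx), model$n_phase)
    Fv <- rhs_eval_batch(model, X, P)[, dyn, drop = FALSE]
    nrm <- sqrt(rowSums(Fv * Fv))
    done <- !is.finite(nrm) | nrm <= tol
    active[idx[done]] <- FALSE
    keep <- which(!done)
    if (!length(keep)) next
    A <- jac_mu_eval_batch(model, X[keep, , drop = FALSE],
                           P[keep, , drop = FALSE])
    for (jj in seq_along(keep)) {
      i <- idx[keep[jj]]
      Aj <- A[dyn, , jj, drop = FALSE]
      dim(Aj) <- c(length(dyn), model$n_params)
      Aj <- Aj * matrix(P[keep[jj], ] * log(10), length(dyn),
                        model$n_params, byrow = TRUE) # d f / d log10(mu)
      AAt <- Aj %*% t(Aj)
      AAt <- AAt + diag(1e-10 * max(1, max(abs(AAt))), nrow(AAt))
      delta <- tryCatch(-drop(t(Aj) %*% solve(AAt, Fv[keep[jj], ])),
                        error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) {
        active[i] <- FALSE
      } else {
        Lmat[i, ] <- pmin(pmax(Lmat[i, ] + delta, lo), up)
      }
    }
  }
  Lmat
}

pool_records <- function(model, config, pool, d_eval) {
  spec <- config$spec
  obs <- sample_observation_points(model, spec, d_eval,
                                   seed = sample.int(2^31 - 1L, 1L))
  rec <- objective_batch(model, 10^pool, spec, obs)
  rec$accepted <- is.finite(rec$o_fix) & rec$o_fix < spec$fix_tol &
    !is.nan(rec$max_re) & is.finite(rec$max_re) & rec$max_re < 0
  rec
}

trim_pool <- function(pool, rec, pool_max, moderate = Inf) {
  n <- nrow(pool)
  if (n <= pool_max) return(list(pool = pool, rec = rec))
  # uniform subsampling within the moderate tier preserves spatial coverage;
  # preferring low objective values (or the o_fix-polished members) would
  # collapse the ensemble onto whatever part of the region polished first
  mod <- which(is.finite(rec$combined) &
                 (rec$combined < moderate | rec$accepted))
  oth <- setdiff(seq_len(n), mod)
  keep <- if (length(mod) > pool_max) sample(mod, pool_max) else mod
  room <- pool_max - length(keep)
  if (room > 0L && length(oth))
    keep <- c(keep, oth[order(rec$combined[oth])][seq_len(min(room, length(oth)))])
  list(pool = pool[keep, , drop = FALSE], rec = rec[keep, , drop = FALSE])
}

#' Globalized quasi-Newton expansion stage
#'
#' For each observation half-width of the schedule: optimize every pool
#' member ([m_lbfgs_optimize]), then repeat `n_noise_loops` times: perturb all
#' members with log10-Gaussian noise (sigma halving per loop), re-optimize the
#' perturbed copies, and keep the parents together with children that improved
#' on their parent or pass the final acceptance filter (so noise can never
#' lose a solution, while accepted children expand the covered region). The
#' very last sweep of the last stage runs with the twist disabled. Duplicates
#' are removed and the pool is trimmed to `pool_max` with preference for
#' accepted members.
#'
#' @param model an [ode_system].
#' @param config a [teaps_config].
#' @param pool collected log10 matrix (e.g. from [cnm_stage]).
#' @param snapshot optional callback `function(stage_label, pool, rec)` run
#'   after each stage (used for basin-stability traces).
#' @return list with `pool`, `rec` (objective + acceptance records aligned to
#'   `pool` rows, evaluated at the final half-width).
#' @export
g_lbfgs_stage <- function(model, config, pool, snapshot = NULL) {
  spec <- config$spec
  d_final <- max(spec$d_schedule)
  nd <- length(spec$d_schedule)
  for (si in seq_len(nd)) {
    d <- spec$d_schedule[si]
    pool <- sweep_pool(model, config, pool, d, twist = TRUE)
    rec <- pool_records(model, config, pool, d_final)
    loops <- config$n_noise_loops
    sp <- resolve_space(config, model)
    lo <- log10(sp$lower); up <- log10(sp$upper)
    for (loop in seq_len(max(0L, loops))) {
      sigma <- config$noise_sigma_log10 * 0.5^(loop - 1L)
      child <- pool + matrix(stats::rnorm(length(pool), 0, sigma),
                             nrow(pool), ncol(pool))
      child <- clip_box(child, lo, up)
      # place the fixed point exactly, then judge: children that land inside
      # the allowable set are genuine expansion samples; children outside
      # are discarded -- re-optimizing them would only deposit another copy
      # on the boundary nearest their parent, piling density there
      child <- project_fixed_point_pool(model, child, spec, lo, up,
                                        tol = spec$fix_tol / 100)
      # membership is judged at the final half-width: children admitted
      # under an early (small-d) geometry would only be dragged boundary-ward
      # when later stages re-expose them to the full observation region
      obs_k <- sample_observation_points(model, spec, d_final,
                                         seed = sample.int(2^31 - 1L, 1L))
      pre <- objective_batch(model, 10^child, spec, obs_k,
                             slack = spec$basin_slack)
      keep <- is.finite(pre$combined) & pre$combined <= config$cnm_threshold
      if (any(keep)) {
        child <- sweep_pool(model, config, child[keep, , drop = FALSE], d,
                            twist = TRUE)
        crec <- pool_records(model, config, child, d_final)
        pool <- rbind(pool, child)
        rec <- rbind(rec, crec)
        dup <- duplicated(round(pool, 10L))
        pool <- pool[!dup, , drop = FALSE]
        rec <- rec[!dup, , drop = FALSE]
        tr <- trim_pool(pool, rec, config$pool_max, config$cnm_threshold)
        pool <- tr$pool; rec <- tr$rec
      }
    }
    if (!is.null(snapshot)) snapshot(paste0("g-lbfgs-", si), pool, rec)
  }
  # final untwisted polish at the largest half-width, then exact enforcement
  # of the fixed-point constraint (Gauss-Newton projection)
  pool <- sweep_pool(model, config, pool, d_final, twist = FALSE)
  sp <- resolve_space(config, model)
  pool <- project_fixed_point_pool(model, pool, spec,
                                   log10(sp$lower), log10(sp$upper),
                                   tol = spec$fix_tol / 100)
  rec <- pool_records(model, config, pool, d_final)
  dup <- duplicated(round(pool, 10L))
  pool <- pool[!dup, , drop = FALSE]
  rec <- rec[!dup, , drop = FALSE]
  if (!is.null(snapshot)) snapshot("final", pool, rec)
  list(pool = pool, rec = rec)
}

#' Two-condition stopping rule of the outer iteration
#'
#' Stops when, for every parameter, (1) a Wilcoxon rank-sum test between the
#' values found up to the previous round and the same values augmented with
#' the newest round is non-significant at `wilcoxon_alpha`, and (2) at least
#' `containment_frac` of the newest values lie within the historical
#' min-max range.
#'
#' @param config a [teaps_config].
#' @param history matrix of per-parameter values (rows = sets) found in
#'   earlier rounds (log10 scale).
#' @param new_values matrix of values from the latest round.
#' @return logical: `TRUE` means stop; attributes `p_values` and
#'   `containment` carry the per-parameter diagnostics.
#' @export
stopping_check <- function(config, history, new_values) {
  history <- as.matrix(history)
  new_values <- as.matrix(new_values)
  stopifnot(nrow(history) > 0, nrow(new_values) > 0,
            ncol(history) == ncol(new_values))
  p <- ncol(history)
  pv <- numeric(p)
  cont <- numeric(p)
  for (j in seq_len(p)) {
    h <- history[, j]
    nv <- new_values[, j]
    pv[j] <- tryCatch(
      suppressWarnings(stats::wilcox.test(h, c(h, nv), exact = FALSE)$p.value),
      error = function(e) 1)
    if (!is.finite(pv[j])) pv[j] <- 1 # identical constant samples
    cont[j] <- mean(nv >= min(h) & nv <= max(h))
  }
  stop_now <- all(pv >= config$wilcoxon_alpha) &&
    all(cont >= config$containment_frac)
  structure(stop_now, p_values = pv, containment = cont)
}

#' Run the full TEAPS search
#'
#' Repeats rounds of fresh-cloud cluster-Newton collection ([cnm_stage])
#' followed by globalized quasi-Newton expansion ([g_lbfgs_stage]), merging
#' the accepted parameter sets, until the two-condition stopping rule
#' ([stopping_check]) fires or `max_outer_iters` rounds have run. The whole
#' run is reproducible from `config$seed`.
#'
#' @param model an [ode_system] (built-in via [bsr_model] or imported SBML).
#' @param config a [teaps_config].
#' @return object of class `teaps`; see [print.teaps], [summary.teaps],
#'   [plot.teaps], [as.data.frame.teaps]. Key fields: `ensemble` (data frame
#'   of parameter sets in linear scale with objective components, stage
#'   labels and acceptance flags), `snapshots` (per-stage log10 pools when
#'   `keep_history`), `stopping` (per-round diagnostics), `n_accepted`.
#' @export
teaps <- function(model, config = teaps_config()) {
  stopifnot(inherits(model, "ode_system"), inherits(config, "teaps_config"))
  set.seed(config$seed)
  snapshots <- list()
  merged <- list()
  stopping <- list()
  stopped <- FALSE
  n_outer <- 0L
  for (outer in seq_len(config$max_outer_iters)) {
    n_outer <- outer
    snap_fun <- if (config$keep_history) {
      function(stage, pool, rec) {
        snapshots[[length(snapshots) + 1L]] <<-
          list(outer = outer, stage = stage, pool = pool, rec = rec)
      }
    } else NULL
    cloud <- init_parameter_cloud(model, config)
    cs <- cnm_stage(model, config, cloud)
    if (config$keep_history && nrow(cs$pool)) {
      rec0 <- pool_records(model, config, cs$pool, max(config$spec$d_schedule))
      snapshots[[length(snapshots) + 1L]] <-
        list(outer = outer, stage = "cnm", pool = cs$pool, rec = rec0)
    }
    if (!nrow(cs$pool)) next
    gs <- g_lbfgs_stage(model, config, cs$pool, snapshot = snap_fun)
    merged[[outer]] <- list(pool = gs$pool, rec = gs$rec)
    hist_mat <- do.call(rbind, lapply(merged[seq_len(outer - 1L)],
                                      function(m) if (is.null(m)) NULL else m$pool))
    if (outer > 1L && !is.null(hist_mat) && nrow(hist_mat) > 0 &&
        nrow(gs$pool) > 0) {
      sc <- stopping_check(config, hist_mat, gs$pool)
      stopping[[length(stopping) + 1L]] <-
        data.frame(outer = outer, param = model$params,
                   p_value = attr(sc, "p_values"),
                   containment = attr(sc, "containment"))
      if (isTRUE(c(sc))) { stopped <- TRUE; break }
    }
  }
  pools <- do.call(rbind, lapply(merged, function(m) if (is.null(m)) NULL else m$pool))
  recs <- do.call(rbind, lapply(merged, function(m) if (is.null(m)) NULL else m$rec))
  warn_empty <- FALSE
  if (is.null(pools) || nrow(pools) == 0L || !any(recs$accepted)) {
    warn_empty <- TRUE
    warning("TEAPS finished without any accepted parameter set")
  }
  if (is.null(pools)) {
    pools <- matrix(numeric(0), 0L, model$n_params,
                    dimnames = list(NULL, model$params))
    recs <- pool_records(model, config, pools, max(config$spec$d_schedule))
  }
  dup <- duplicated(round(pools, 10L))
  pools <- pools[!dup, , drop = FALSE]
  recs <- recs[!dup, , drop = FALSE]
  ens <- as.data.frame(10^pools)
  names(ens) <- model$params
  ens$o_fix <- recs$o_fix
  ens$o_basin <- recs$o_basin
  ens$o_relax <- recs$o_relax
  ens$max_re <- recs$max_re
  ens$accepted <- recs$accepted
  ens$stage <- ifelse(recs$accepted, "final", "g-lbfgs")
  structure(list(model = model, config = config, ensemble = ens,
                 snapshots = snapshots,
                 stopping = if (length(stopping)) do.call(rbind, stopping) else NULL,
                 n_outer = n_outer, stopped_early = stopped,
                 n_accepted = sum(recs$accepted), empty = warn_empty),
            class = "teaps")
}

#' Accepted parameter sets of a TEAPS fit
#' @param fit a `teaps` object.
#' @param log10 return log10 values instead of linear.
#' @return matrix (sets x parameters) of accepted parameter values.
#' @export
accepted_sets <- function(fit, log10 = FALSE) {
  stopifnot(inherits(fit, "teaps"))
  M <- as.matrix(fit$ensemble[fit$ensemble$accepted, fit$model$params,
                              drop = FALSE])
  if (log10) log10(M) else M
}
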