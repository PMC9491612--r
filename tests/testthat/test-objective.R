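spec0 <- bsr_spec()

test_that("observation points stay in the box, honour the seed, and pin constants", {
  m <- bsr_model("T1")
  obs <- sample_observation_points(m, spec0, d = 0.1, seed = 42)
  expect_equal(dim(obs$points), c(spec0$n_obs, 3))
  expect_true(all(obs$points >= 0.9 & obs$points <= 1.1))
  obs2 <- sample_observation_points(m, spec0, d = 0.1, seed = 42)
  expect_identical(obs$points, obs2$points)
  # degenerate interval
  obs0 <- sample_observation_points(m, spec0, d = 0, seed = 1)
  expect_true(all(obs0$points == 1))
  # constant species are pinned to the fixed point
  m3 <- bsr_model("T3")
  obs3 <- sample_observation_points(m3, spec0, d = 0.1, seed = 7)
  expect_true(all(obs3$points[, "s3"] == 1))
})

test_that("o_fix is the unsquared Euclidean residual norm", {
  m <- bsr_model("T1")
  # analytically constrained parameters place the fixed point exactly
  red <- fixed_point_reduction(m)
  P <- red$expand(cbind(v2 = 2, km2 = 1))$P
  expect_equal(o_fix(m, P[1, ]), 0)
  expect_equal(o_fix(m, c(k1 = 1, v2 = 1, km2 = 1, k3 = 0.5, k4 = 0.5)), 0.5)
  # norm homogeneity on a linear model: scaling f by c scales o_fix by |c|
  lin <- linear_model()
  expect_equal(o_fix(lin, c(k = 3), x_star = 1.5),
               3 * o_fix(lin, c(k = 1), x_star = 1.5))
})

test_that("o_basin matches closed forms on scalar and planar fixtures", {
  spec1 <- bsr_spec(n_obs = 7)
  lin <- linear_model()
  obs <- sample_observation_points(lin, spec1, d = 0.1, seed = 1)
  expect_equal(o_basin(lin, c(k = 2), obs), 0) # M = -2k < 0 everywhere
  rep_ <- repelling_model()
  obs_r <- sample_observation_points(rep_, spec1, d = 0.1, seed = 1)
  expect_equal(o_basin(rep_, c(k = 1), obs_r), 2) # M = +2 everywhere
  rot <- rotation_model()
  obs_rot <- sample_observation_points(rot, spec1, d = 0.1, seed = 1)
  expect_equal(o_basin(rot, c(w = 5), obs_rot), 0) # antisymmetric J, M == 0
})

test_that("o_basin is permutation-invariant and non-increasing under point removal", {
  m <- bsr_model("T1")
  mu <- random_params(m, 11, lo = 0.3, hi = 3)
  obs <- sample_observation_points(m, spec0, d = 0.1, seed = 3)
  v <- o_basin(m, mu, obs)
  obs_perm <- obs
  obs_perm$points <- obs$points[rev(seq_len(nrow(obs$points))), ]
  expect_equal(o_basin(m, mu, obs_perm), v)
  obs_less <- obs
  obs_less$points <- obs$points[-1, ]
  expect_lte(o_basin(m, mu, obs_less), v)
})

test_that("o_relax penalizes slow relaxation and excludes zero eigenvalues", {
  lin <- linear_model()
  expect_equal(o_relax(lin, c(k = 1), spec0), 0)      # eigen -1 vs -0.3
  expect_equal(o_relax(lin, c(k = 0.1), spec0), 0.2,  # eigen -0.1
               tolerance = 1e-12)
  # diag(0, -1): the zero eigenvalue is excluded, max nonzero Re = -1
  two <- ode_system("z2", c("x1", "x2"), "k",
                    list(0, quote(-k * (x2 - 1))))
  expect_equal(o_relax(two, c(k = 1), spec0), 0)
  # all eigenvalues zero-classified: nothing to penalize, by convention 0
  allz <- ode_system("z1", "x1", "k", list(0))
  expect_equal(o_relax(allz, c(k = 1), spec0), 0)
})

test_that("combined objective fills all fields with the stated arithmetic", {
  m <- bsr_model("T1")
  mu <- c(k1 = 1, v2 = 1, km2 = 1, k3 = 0.5, k4 = 0.5)
  obs <- sample_observation_points(m, spec0, d = 0.1, seed = 5)
  r <- combined_objective(m, mu, spec0, obs)
  expect_equal(r$residual_vector, c(r$o_fix, r$o_basin, r$o_relax))
  expect_equal(r$combined_scalar,
               r$o_fix^2 + r$o_basin^spec0$weight_w + r$o_relax^spec0$weight_w)
  # all components zero => combined zero
  lin <- linear_model()
  obs_l <- sample_observation_points(lin, spec0, d = 0.1, seed = 5)
  rl <- combined_objective(lin, c(k = 1), spec0, obs_l)
  expect_equal(rl$combined_scalar, 0)
  expect_equal(rl$residual_vector, c(0, 0, 0))
})

test_that("combined objective is monotone in each component", {
  # increasing any component never decreases the combined scalar
  w <- spec0$weight_w
  comb <- function(f, b, r) f^2 + b^w + r^w
  base <- comb(0.3, 0.2, 0.1)
  expect_gte(comb(0.4, 0.2, 0.1), base)
  expect_gte(comb(0.3, 0.3, 0.1), base)
  expect_gte(comb(0.3, 0.2, 0.2), base)
})

test_that("objective components are continuous in mu (spot check)", {
  m <- bsr_model("T1")
  mu <- c(k1 = 0.9, v2 = 2, km2 = 1.5, k3 = 0.8, k4 = 1.1)
  obs <- sample_observation_points(m, spec0, d = 0.1, seed = 9)
  base <- combined_objective(m, mu, spec0, obs)
  for (j in seq_along(mu)) {
    mu2 <- mu
    mu2[j] <- mu2[j] * (1 + 1e-7)
    r2 <- combined_objective(m, mu2, spec0, obs)
    expect_lt(abs(r2$o_fix - base$o_fix), 1e-5)
    expect_lt(abs(r2$o_basin - base$o_basin), 1e-5)
    expect_lt(abs(r2$o_relax - base$o_relax), 1e-5)
  }
})

test_that("accept_bsr applies the fixed-point and eigenvalue-sign filter", {
  lin <- linear_model()
  expect_true(accept_bsr(lin, c(k = 1), spec0)$accepted)
  rep_ <- repelling_model()
  expect_false(accept_bsr(rep_, c(k = 1), spec0)$accepted)
  # all-zero spectrum: stability cannot be certified
  allz <- ode_system("z1", "x1", "k", list(0))
  expect_false(accept_bsr(allz, c(k = 1), spec0)$accepted)
  # T1 with the constrained example parameters: decided by the numeric
  # eigenvalues of the derived 3x3 Jacobian
  m <- bsr_model("T1")
  red <- fixed_point_reduction(m)
  mu <- red$expand(cbind(v2 = 2, km2 = 1))$P[1, ]
  ev <- eigen(jacobian_eval(m, c(1, 1, 1), mu))$values
  nz <- ev[abs(Re(ev)) > spec0$zero_eig_tol]
  expect_equal(accept_bsr(m, mu, spec0)$accepted, max(Re(nz)) < 0)
})
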