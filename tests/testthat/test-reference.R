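test_that("fixed-point reduction zeroes the residual for every built-in model", {
  for (id in builtin_models()) {
    m <- bsr_model(id)
    red <- fixed_point_reduction(m)
    expect_setequal(c(red$free, red$constrained), m$params)
    set.seed(match(id, builtin_models()))
    FV <- 10^matrix(runif(100 * length(red$free), -3.3, 4.7),
                    100, length(red$free))
    ex <- red$expand(FV)
    if (any(ex$valid)) {
      P <- ex$P[ex$valid, , drop = FALSE]
      ofix <- teaps:::o_fix_batch(m, P, rep(1, m$n_phase))
      scale <- pmax(1, apply(P, 1, max))
      expect_lt(max(ofix / scale), 1e-10)
    }
    # invalid rows are exactly the rows with a nonpositive solved parameter
    expect_true(all(ex$valid | apply(ex$P, 1, function(r)
      any(!is.finite(r) | r <= 0))))
  }
  expect_equal(fixed_point_reduction(bsr_model("T1"))$free, c("v2", "km2"))
  expect_error(fixed_point_reduction(linear_model()), "no analytic")
})

test_that("T1 reduction gives the closed form k1 = k3 = k4 = v2/(km2+1)", {
  red <- fixed_point_reduction(bsr_model("T1"))
  ex <- red$expand(cbind(v2 = c(2, 5), km2 = c(1, 3)))
  expect_equal(unname(ex$P[, "k1"]), c(1, 1.25))
  expect_equal(ex$P[, "k1"], ex$P[, "k3"])
  expect_equal(ex$P[, "k1"], ex$P[, "k4"])
})

test_that("brute force honours the candidate budget when filters are off", {
  m <- bsr_model("T1")
  bf <- brute_force_search(m, grid_spec(points_total = 500, seed = 3),
                           apply_bsr_filter = FALSE)
  expect_equal(nrow(bf$params), 500)
  expect_equal(bf$n_candidates, 500)
  # grid mode generates (floor(budget^(1/d)))^d points
  bf_g <- brute_force_search(m, grid_spec(points_total = 100, mode = "grid"),
                             apply_bsr_filter = FALSE)
  expect_equal(nrow(bf_g$params), 100) # 10^2 for d = 2
})

test_that("an unattainable relaxation target empties the reference set", {
  m <- bsr_model("T1")
  bf <- brute_force_search(m, grid_spec(points_total = 2000, seed = 3),
                           spec = bsr_spec(lambda_target = -1e6))
  expect_equal(bf$n_accepted, 0L)
})

test_that("T8 pinning removes the input flux from the compared space", {
  m <- bsr_model("T8")
  bf <- brute_force_search(m, grid_spec(points_total = 3000, seed = 5,
                                        fixed_params = c(k0 = 0.5)))
  expect_false("k0" %in% bf$free)
  expect_equal(length(bf$free), 5L)
  if (bf$n_accepted > 0) expect_true(all(bf$params[, "k0"] == 0.5))
  expect_error(brute_force_search(m, grid_spec(points_total = 10,
                                               fixed_params = c(v1 = 1))),
               "fixed_params")
})

test_that("membership oracle: accepted reference points pass accept_bsr", {
  spec <- bsr_spec()
  for (id in c("T1", "T2", "T6")) {
    m <- bsr_model(id)
    bf <- brute_force_search(m, grid_spec(points_total = 2e4, seed = 9), spec)
    if (bf$n_accepted == 0) next
    chk <- teaps:::accept_bsr_batch(m, bf$params, spec)
    expect_true(all(chk$accepted), label = paste("oracle agreement", id))
  }
})

test_that("grid and random modes approach the same density as budgets grow", {
  m <- bsr_model("T2") # largest accepted fraction: stable densities
  spec <- bsr_spec()
  g <- density_grid(dims = c("v2", "ki2"), n_per_dim = 12)
  js_at <- function(budget) {
    bfr <- brute_force_search(m, grid_spec(points_total = budget, seed = 21),
                              spec)
    bfg <- brute_force_search(m, grid_spec(points_total = budget,
                                           mode = "grid"), spec)
    js_divergence(kde_density(bfr$free_values, g),
                  kde_density(bfg$free_values, g))
  }
  js_small <- js_at(2e3)
  js_big <- js_at(4e4)
  expect_lt(js_big, js_small)
  expect_lt(js_big, 0.05)
})
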