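test_that("built-in models expose the printed structure", {
  m1 <- bsr_model("T1")
  expect_s3_class(m1, "ode_system")
  expect_equal(m1$species, c("s1", "s2", "s3"))
  expect_equal(m1$params, c("k1", "v2", "km2", "k3", "k4"))
  expect_false(any(m1$constant_mask))
  expect_equal(bsr_model("T3")$constant_mask, c(FALSE, FALSE, TRUE))
  expect_equal(bsr_model("T8")$constant_mask, c(FALSE, FALSE, FALSE, TRUE))
  for (id in builtin_models()) {
    m <- bsr_model(id)
    expect_equal(length(m$rhs), m$n_phase)
  }
  expect_error(bsr_model("T9"), "unknown model")
})

test_that("rhs_eval reproduces hand-computed rates and zero rows", {
  m <- bsr_model("T1")
  expect_equal(unname(rhs_eval(m, c(1, 1, 1),
                               c(k1 = 1, v2 = 2, km2 = 1, k3 = 1, k4 = 1))),
               c(0, 0, 0))
  expect_equal(unname(rhs_eval(m, c(1, 1, 1),
                               c(k1 = 1, v2 = 1, km2 = 1, k3 = 0.5, k4 = 0.5))),
               c(0.5, 0, 0))
  # constant species give identically zero derivative at arbitrary states
  m3 <- bsr_model("T3")
  v <- rhs_eval(m3, c(0.3, 2.7, 5), random_params(m3, 1))
  expect_identical(unname(v["s3"]), 0)
  m8 <- bsr_model("T8")
  mu8 <- random_params(m8, 2, lo = 0.2, hi = 2)
  mu8["fb4"] <- 0.1 # keep the regulation denominator positive
  expect_identical(unname(rhs_eval(m8, c(1.4, 0.6, 1.1, 0.9), mu8)["s4"]), 0)
})

test_that("rate-law singularities raise an evaluation error naming the species", {
  m <- bsr_model("T1")
  expect_error(rhs_eval(m, c(-1, 1, 1), c(k1 = 1, v2 = 2, km2 = 1,
                                          k3 = 1, k4 = 1)),
               "ds1/dt")
})

test_that("analytic Jacobian matches the derived matrix and finite differences", {
  m <- bsr_model("T1")
  J <- jacobian_eval(m, c(1, 1, 1), c(k1 = 1, v2 = 2, km2 = 1, k3 = 1, k4 = 1))
  expect_equal(unname(J),
               rbind(c(-0.5, 0, -1), c(0.5, -1, 1), c(0, 1, -1)))
  # scalar linear system
  lin <- ode_system("lin", "x", "k", list(quote(-k * (x - 1))))
  expect_equal(unname(jacobian_eval(lin, 1.3, c(k = 2))),
               matrix(-2, 1, 1))
  # property: agreement with central finite differences on random interior
  # points, every built-in model
  for (id in builtin_models()) {
    mod <- bsr_model(id)
    for (rep in 1:3) {
      set.seed(100 + rep)
      x <- runif(mod$n_phase, 0.7, 1.3)
      mu <- random_params(mod, 200 + rep, lo = 0.3, hi = 3)
      if (id == "T8") mu["fb4"] <- 0.05
      J <- jacobian_eval(mod, x, mu)
      expect_equal(unname(J), fd_jacobian(mod, x, mu), tolerance = 1e-5,
                   label = paste("jacobian", id))
    }
  }
  # constant-species rows are identically zero
  expect_equal(unname(jacobian_eval(bsr_model("T3"), c(1, 1, 1),
                                    random_params(bsr_model("T3"), 3))[3, ]),
               c(0, 0, 0))
})

test_that("T2 variants differ exactly in the s2 balance", {
  mc <- bsr_model("T2")
  mp <- bsr_model("T2", t2_variant = "printed")
  mu <- random_params(mc, 4)
  x <- c(1.2, 0.8, 1.1)
  vc <- rhs_eval(mc, x, mu)
  vp <- rhs_eval(mp, x, mu)
  expect_equal(vc[["s1"]], vp[["s1"]])
  expect_equal(vc[["s3"]], vp[["s3"]])
  # corrected: re2 - re3; printed: re2 - re1
  re2 <- mu[["v2"]] * x[1] / (1 + x[3] / mu[["ki2"]])
  expect_equal(vc[["s2"]], re2 - mu[["k3"]] * x[2])
  expect_equal(vp[["s2"]], re2 - mu[["k1"]])
})

test_that("parameter_space widens the input-flux lower bound only", {
  sp <- parameter_space(bsr_model("T1"))
  expect_equal(unname(sp$lower["k1"]), 5e-1)
  expect_equal(unname(sp$lower["v2"]), 5e-3)
  expect_true(all(sp$upper == 5e4))
  sp8 <- parameter_space(bsr_model("T8"))
  expect_equal(unname(sp8$lower["k0"]), 5e-1)
  # T6/T7 have no zeroth-order input flux
  expect_true(all(parameter_space(bsr_model("T6"))$lower == 5e-3))
})

test_that("ode_system rejects unknown symbols and bad input_flux", {
  expect_error(ode_system("bad", "x", "k", list(quote(-k * y))),
               "neither species nor parameters")
  expect_error(ode_system("bad", "x", "k", list(quote(-k * x)),
                          input_flux = "nope"), "input_flux")
})
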