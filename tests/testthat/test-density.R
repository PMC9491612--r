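test_that("kde_density normalizes and concentrates mass where the samples are", {
  g <- density_grid(1e-3, 1e3, dims = c("a", "b"), n_per_dim = 15)
  set.seed(1)
  X <- 10^cbind(a = rnorm(50, 1, 0.3), b = rnorm(50, -1, 0.3))
  d <- kde_density(X, g)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  expect_true(all(d$density >= 0))
  # a single repeated point puts the argmax at the nearest grid cell
  X1 <- matrix(rep(c(10, 0.1), each = 30), 30, 2,
               dimnames = list(NULL, c("a", "b")))
  dd <- suppressWarnings(kde_density(X1, g))
  idx <- arrayInd(which.max(dd$density), c(15, 15))
  expect_equal(g$axes$a[idx[1]], g$axes$a[which.min(abs(g$axes$a - 1))])
  expect_equal(g$axes$b[idx[2]], g$axes$b[which.min(abs(g$axes$b + 1))])
})

test_that("Silverman bandwidth matches the 1-D closed form", {
  set.seed(7)
  x <- rnorm(200, 0, 0.8)
  bw <- teaps:::silverman_bw(matrix(x, ncol = 1))
  expect_equal(bw, (4 / (3 * 200))^(1 / 5) * sd(x), tolerance = 1e-12)
})

test_that("zero-variance dimensions get a floored bandwidth with a warning", {
  g <- density_grid(1e-2, 1e2, dims = c("a", "b"), n_per_dim = 10)
  X <- cbind(a = rep(1, 20), b = 10^runif(20, -1, 1))
  expect_warning(d <- kde_density(X, g), "floored")
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
})

test_that("cosine similarity follows the printed formula", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("JS divergence follows the printed formula in nats", {
  expect_equal(js_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  A <- c(0.7, 0.2, 0.1)
  B <- c(0.1, 0.3, 0.6)
  expect_equal(js_divergence(A, B), js_divergence(B, A))
  expect_equal(js_divergence(A, B, base = 2), js_divergence(A, B) / log(2))
  expect_error(js_divergence(c(1, 1), c(0.5, 0.5)), "normalized")
})

test_that("kde profiles are self-similar under both indices", {
  g <- density_grid(1e-2, 1e2, dims = c("a", "b"), n_per_dim = 10)
  set.seed(2)
  X <- 10^matrix(runif(60, -1, 1), 30, 2, dimnames = list(NULL, c("a", "b")))
  d <- kde_density(X, g)
  expect_equal(cosine_similarity(d, d), 1)
  expect_equal(js_divergence(d, d), 0)
})

test_that("random comparator built from the reference itself scores near zero", {
  g <- density_grid(1e-2, 1e2, dims = c("a", "b"), n_per_dim = 10)
  set.seed(3)
  X <- 10^matrix(rnorm(400, 0, 0.5), 200, 2, dimnames = list(NULL, c("a", "b")))
  d <- kde_density(X, g)
  rc <- random_comparator_ci(d, d, n_reps = 50, seed = 4)
  # TEAPS-vs-reference here IS the reference: cosine 1, js 0
  expect_equal(rc$cosine, 1)
  expect_equal(rc$js, 0)
  # CI endpoints bracket the point estimate
  expect_lte(rc$cosine_ci[1], rc$cosine_log10_ratio)
  expect_gte(rc$cosine_ci[2], rc$cosine_log10_ratio)
})

test_that("full-rank PCA is orthonormal and ranks axis widths sensibly", {
  set.seed(5)
  X <- 10^cbind(a = rnorm(300, 0, 1), b = rnorm(300, 0, 1),
                c = rnorm(300, 0, 1))
  rep_iso <- pca_full(X)
  L <- rep_iso$loadings
  expect_equal(unname(L %*% t(L)), diag(3), tolerance = 1e-10)
  expect_lt(diff(range(rep_iso$axis_ranges)) / mean(rep_iso$axis_ranges), 0.5)
  # a cloud confined to a line has one dominant axis
  t_ <- rnorm(300)
  Xl <- 10^cbind(a = t_, b = 2 * t_ + rnorm(300, 0, 0.01),
                 c = -t_ + rnorm(300, 0, 0.01))
  rep_line <- pca_full(Xl)
  expect_gt(rep_line$axis_ranges[1] / rep_line$axis_ranges[2], 20)
})

test_that("PCI collapses to the axis index and averages uniform loadings", {
  fake <- list(loadings = rbind(c(1, 0), c(0, 1), c(0, 1)) * 0,
               params = c("p1", "p2"))
  # p1 loads only on axis 3
  fake$loadings <- rbind(c(0, 1), c(0, 1), c(1, 0))
  expect_equal(unname(pci(fake)["p1"]), 3)
  # uniform |loadings| over n axes -> (n+1)/2
  n <- 5
  fake2 <- list(loadings = matrix(1 / n, n, 2), params = c("p1", "p2"))
  expect_equal(unname(pci(fake2)), rep((n + 1) / 2, 2))
  # bounds for arbitrary loadings
  set.seed(8)
  fake3 <- list(loadings = matrix(rnorm(16), 4, 4), params = paste0("p", 1:4))
  v <- pci(fake3)
  expect_true(all(v >= 1 & v <= 4))
})
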