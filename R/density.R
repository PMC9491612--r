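#' Tensor grid over log10 parameter space
#'
#' @param lower,upper bounds (linear scale) shared by every dimension, or
#'   vectors per dimension.
#' @param dims character vector of dimension (parameter) names.
#' @param n_per_dim lattice points per dimension.
#' @return object of class `density_grid`: list with `axes` (list of log10
#'   coordinate vectors), `dims`, `n_cells`.
#' @export
density_grid <- function(lower = 5e-4, upper = 5e4, dims, n_per_dim = 20L) {
  d <- length(dims)
  lo <- log10(rep_len(lower, d))
  up <- log10(rep_len(upper, d))
  axes <- lapply(seq_len(d), function(j) seq(lo[j], up[j],
                                             length.out = n_per_dim))
  names(axes) <- dims
  structure(list(axes = axes, dims = dims,
                 n_cells = n_per_dim^d), class = "density_grid")
}

silverman_bw <- function(X) {
  # multivariate Silverman plug-in: sigma_j * (4/((p+2) n))^(1/(p+4));
  # reduces to (4/(3n))^(1/5) sigma in one dimension
  n <- nrow(X)
  p <- ncol(X)
  s <- apply(X, 2L, stats::sd)
  s * (4 / ((p + 2) * n))^(1 / (p + 4))
}

#' Kernel density estimate of a parameter ensemble on a shared grid
#'
#' Product-Gaussian KDE in log10 space with per-dimension Silverman
#' bandwidths, evaluated on the tensor grid and normalized to sum one. The
#' flattened density vector is indexed in column-major (first axis fastest)
#' order, so two profiles on the same grid are directly comparable
#' component-wise.
#'
#' @param X matrix of parameter sets (rows) in *linear* scale, or log10 scale
#'   with `log10_input = TRUE`; columns must match `grid$dims`.
#' @param grid a [density_grid].
#' @param log10_input whether `X` is already log10-transformed.
#' @param bandwidths optional per-dimension bandwidth override (log10 units).
#' @return object of class `density_profile`: list with `density` (normalized
#'   vector of length `grid$n_cells`), `grid`, `bandwidths`, `n_sets`.
#' @export
kde_density <- function(X, grid, log10_input = FALSE, bandwidths = NULL) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && all(grid$dims %in% colnames(X)))
    X <- X[, grid$dims, drop = FALSE]
  stopifnot(ncol(X) == length(grid$dims), nrow(X) >= 2L)
  if (!log10_input) {
    stopifnot(all(X > 0))
    X <- log10(X)
  }
  if (is.null(bandwidths)) {
    bandwidths <- silverman_bw(X)
    # floor degenerate bandwidths at 1e-3 log10 units, or half the grid
    # spacing if that is larger (a kernel much narrower than the grid pitch
    # puts zero mass on every lattice point)
    step <- vapply(grid$axes, function(a)
      if (length(a) > 1L) a[2] - a[1] else 1, numeric(1))
    floor_bw <- pmax(1e-3, step / 2)
    degen <- !is.finite(bandwidths) | bandwidths < floor_bw
    if (any(!is.finite(bandwidths) | bandwidths < 1e-3))
      warning("zero-variance dimension(s) ",
              paste(grid$dims[!is.finite(bandwidths) | bandwidths < 1e-3],
                    collapse = ", "),
              ": bandwidth floored")
    bandwidths[degen] <- floor_bw[degen]
  }
  d <- length(grid$axes)
  n <- nrow(X)
  # per-dimension kernel matrices: axis points x samples
  K <- lapply(seq_len(d), function(j)
    outer(grid$axes[[j]], X[, j],
          function(g, x) stats::dnorm((g - x) / bandwidths[j])))
  dens <- 0
  for (s in seq_len(n)) {
    v <- K[[1L]][, s]
    if (d > 1L) for (j in 2:d) v <- outer(v, K[[j]][, s])
    dens <- dens + as.vector(v)
  }
  # clip denormal tail mass: values this far below the peak are pure
  # floating-point residue and poison the log terms of the JS divergence
  dens[dens < max(dens) * 1e-15] <- 0
  tot <- sum(dens)
  if (!is.finite(tot) || tot <= 0) stop("degenerate density (zero mass)")
  structure(list(density = dens / tot, grid = grid,
                 bandwidths = bandwidths, n_sets = n),
            class = "density_profile")
}

as_density_vector <- function(x) {
  if (inherits(x, "density_profile")) x$density else as.numeric(x)
}

#' Cosine similarity between two nonnegative density vectors
#'
#' sum(A*B) / sqrt(sum(A^2) sum(B^2)); 1 for identical directions, 0 for
#' disjoint supports.
#'
#' @param A,B density vectors (or [kde_density] profiles) of equal length.
#' @return scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(A, B) {
  A <- as_density_vector(A)
  B <- as_density_vector(B)
  stopifnot(length(A) == length(B), all(A >= 0), all(B >= 0))
  na <- sqrt(sum(A * A))
  nb <- sqrt(sum(B * B))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector")
  sum(A * B) / (na * nb)
}

#' Jensen-Shannon divergence between two normalized density vectors
#'
#' (1/2) sum A log(A / ((A+B)/2)) + (1/2) sum B log(B / ((A+B)/2)), with
#' 0 * log 0 = 0. Natural logarithm by default (maximum log 2); `base = 2`
#' rescales to bits.
#'
#' @param A,B normalized density vectors (or [kde_density] profiles).
#' @param base logarithm base.
#' @return nonnegative scalar.
#' @export
js_divergence <- function(A, B, base = exp(1)) {
  A <- as_density_vector(A)
  B <- as_density_vector(B)
  stopifnot(length(A) == length(B), all(A >= 0), all(B >= 0))
  if (abs(sum(A) - 1) > 1e-8 || abs(sum(B) - 1) > 1e-8)
    stop("js_divergence expects vectors normalized to sum 1")
  M <- (A + B) / 2
  term <- function(P) {
    i <- P > 0
    sum(P[i] * log(P[i] / M[i]))
  }
  (term(A) + term(B)) / (2 * log(base))
}

#' Random-comparator similarity ratios
#'
#' Builds comparator vectors whose components are drawn (with replacement)
#' from the reference density's empirical value distribution, destroying its
#' spatial structure while matching its value histogram; reports log10 ratios
#' of the search-vs-reference similarity to the comparator-vs-reference
#' similarity. Positive cosine ratios and negative JS ratios mean the search
#' ensemble beats the random comparator.
#'
#' @param bf_density reference (brute-force) [kde_density] profile.
#' @param teaps_density search-ensemble profile on the same grid.
#' @param n_reps comparator draws for the confidence interval.
#' @param seed RNG seed.
#' @return list with `cosine` (TEAPS-vs-reference), `js`, and per-metric
#'   `log10_ratio` / 95% `ci` entries.
#' @export
random_comparator_ci <- function(bf_density, teaps_density, n_reps = 200L,
                                 seed = 1L) {
  A <- as_density_vector(bf_density)
  Tv <- as_density_vector(teaps_density)
  stopifnot(length(A) == length(Tv))
  set.seed(seed)
  cosTB <- cosine_similarity(Tv, A)
  jsTB <- js_divergence(Tv, A)
  lcos <- numeric(n_reps)
  ljs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    comp <- sample(A, length(A), replace = TRUE)
    comp_n <- comp / sum(comp)
    lcos[r] <- log10(cosTB / cosine_similarity(comp, A))
    ljs[r] <- log10(jsTB / js_divergence(comp_n, A))
  }
  list(cosine = cosTB, js = jsTB,
       cosine_log10_ratio = mean(lcos),
       cosine_ci = stats::quantile(lcos, c(0.025, 0.975), names = FALSE),
       js_log10_ratio = mean(ljs),
       js_ci = stats::quantile(ljs, c(0.025, 0.975), names = FALSE))
}

#' Full-rank principal component analysis of a parameter ensemble
#'
#' Centered PCA in log10 space with as many axes as parameters, used to find
#' the widest and narrowest directions of the allowable parameter space.
#'
#' @param X ensemble matrix (rows = sets), linear scale unless
#'   `log10_input = TRUE`.
#' @param log10_input whether `X` is already log10-transformed.
#' @return object of class `pca_report`: `loadings` (axes x parameters,
#'   orthonormal rows), `scores`, `axis_ranges` (score max - min per axis),
#'   `sdev`, `pci` (per-parameter principal central axis index).
#' @export
pca_full <- function(X, log10_input = FALSE) {
  X <- as.matrix(X)
  if (!log10_input) {
    stopifnot(all(X > 0))
    X <- log10(X)
  }
  p <- ncol(X)
  if (nrow(X) <= p)
    warning("fewer sets than parameters + 1: PCA is rank-truncated")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  loadings <- t(pr$rotation) # rows = axes
  scores <- pr$x
  axis_ranges <- apply(scores, 2L, function(s) diff(range(s)))
  rep <- structure(list(loadings = loadings, scores = scores,
                        axis_ranges = axis_ranges, sdev = pr$sdev,
                        center = pr$center,
                        params = colnames(X)), class = "pca_report")
  rep$pci <- pci(rep)
  rep
}

#' Principal central axis index (PCI)
#'
#' Weighted average axis number for each parameter, weighted by its relative
#' absolute loading on each axis: PCI(i) = sum_k c_ki k / sum_k c_ki with
#' c_ki = |l_ki| / sum_m |l_km|. Parameters with small PCI load on the
#' leading (broad) axes of the ensemble; large PCI marks parameters confined
#' to the narrow trailing axes.
#'
#' @param report a [pca_full] report (its `loadings` are used).
#' @return named numeric vector in `[1, n_axes]`.
#' @export
pci <- function(report) {
  L <- abs(report$loadings)
  C <- L / rowSums(L) # c_{k,i}: normalized within each axis k
  k <- seq_len(nrow(L))
  out <- colSums(C * k) / colSums(C)
  names(out) <- report$params
  out
}

#' @export
print.pca_report <- function(x, ...) {
  cat("<pca_report> ", nrow(x$loadings), " axes x ", length(x$params),
      " parameters\n", sep = "")
  cat("axis score ranges: ", paste(round(x$axis_ranges, 3), collapse = ", "),
      "\n", sep = "")
  cat("PCI: ", paste(sprintf("%s=%.2f", x$params, x$pci), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile> ", length(x$density), " grid cells over (",
      paste(x$grid$dims, collapse = ", "), "), ", x$n_sets, " sets\n",
      "  bandwidths (log10): ",
      paste(sprintf("%.3g", x$bandwidths), collapse = ", "), "\n", sep = "")
  invisible(x)
}
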