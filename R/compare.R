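default_grid_points <- function(d, cell_budget = 2e5, max_per_dim = 20L) {
  # keep the tensor grid tractable in higher free dimensions
  max(4L, min(max_per_dim, floor(cell_budget^(1 / d))))
}

#' Compare a TEAPS ensemble against the brute-force reference distribution
#'
#' Runs (or reuses) the brute-force search, estimates normalized KDE density
#' profiles of both ensembles over the free (analytically reduced)
#' parameters on one shared grid, and reports cosine similarity, JS
#' divergence and the random-comparator log10 ratios.
#'
#' @param model a built-in [ode_system].
#' @param fit a `teaps` object or a matrix/data frame of accepted parameter
#'   sets (linear scale, full parameter columns).
#' @param reference an existing [brute_force_search] result, or `NULL` to
#'   compute one from `gridspec`.
#' @param gridspec [grid_spec] for the reference search when computed here.
#' @param spec [bsr_spec] used by the reference search.
#' @param n_per_dim KDE grid resolution per free dimension; default keeps the
#'   total cell count near 2e5.
#' @param comparator_reps random-comparator repetitions.
#' @param seed seed for the comparator draws.
#' @return object of class `teaps_comparison`: data-frame-like list with the
#'   similarity indices, comparator ratios and confidence intervals, counts,
#'   and the two density profiles.
#' @export
compare_to_reference <- function(model, fit, reference = NULL,
                                 gridspec = grid_spec(), spec = bsr_spec(),
                                 n_per_dim = NULL, comparator_reps = 200L,
                                 seed = 1L) {
  sets <- if (inherits(fit, "teaps")) accepted_sets(fit) else as.matrix(fit)
  if (!nrow(sets)) stop("no accepted parameter sets to compare")
  if (is.null(reference))
    reference <- brute_force_search(model, gridspec, spec)
  if (!reference$n_accepted)
    stop("reference search found no BSR points for model ", model$name)
  free <- reference$free
  stopifnot(all(free %in% colnames(sets)))
  if (is.null(n_per_dim)) n_per_dim <- default_grid_points(length(free))
  grid <- density_grid(reference$bounds[1], reference$bounds[2],
                       dims = free, n_per_dim = n_per_dim)
  d_teaps <- kde_density(sets[, free, drop = FALSE], grid)
  d_bf <- kde_density(reference$free_values, grid)
  rc <- random_comparator_ci(d_bf, d_teaps, n_reps = comparator_reps,
                             seed = seed)
  structure(list(model = model$name, free = free,
                 n_teaps = nrow(sets), n_reference = reference$n_accepted,
                 n_per_dim = n_per_dim,
                 cosine = rc$cosine, js = rc$js,
                 cosine_log10_ratio = rc$cosine_log10_ratio,
                 cosine_ci = rc$cosine_ci,
                 js_log10_ratio = rc$js_log10_ratio, js_ci = rc$js_ci,
                 teaps_density = d_teaps, reference_density = d_bf),
            class = "teaps_comparison")
}

#' @export
print.teaps_comparison <- function(x, ...) {
  cat("Density comparison for model ", x$model, " over (",
      paste(x$free, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  %d search sets vs %d reference sets, %d grid points/dim\n",
              x$n_teaps, x$n_reference, x$n_per_dim))
  cat(sprintf("  cosine similarity: %.4f   (log10 ratio to random: %.3f [%.3f, %.3f])\n",
              x$cosine, x$cosine_log10_ratio, x$cosine_ci[1], x$cosine_ci[2]))
  cat(sprintf("  JS divergence:     %.4f   (log10 ratio to random: %.3f [%.3f, %.3f])\n",
              x$js, x$js_log10_ratio, x$js_ci[1], x$js_ci[2]))
  invisible(x)
}

#' @export
as.data.frame.teaps_comparison <- function(x, ...) {
  data.frame(model = x$model, cosine = x$cosine,
             cosine_log10_ratio = x$cosine_log10_ratio,
             cosine_ci_lo = x$cosine_ci[1], cosine_ci_hi = x$cosine_ci[2],
             js = x$js, js_log10_ratio = x$js_log10_ratio,
             js_ci_lo = x$js_ci[1], js_ci_hi = x$js_ci[2],
             n_teaps = x$n_teaps, n_reference = x$n_reference)
}
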