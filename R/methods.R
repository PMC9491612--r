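#' @export
print.teaps <- function(x, ...) {
  cat("TEAPS search on model ", x$model$name, "\n", sep = "")
  cat("  outer rounds: ", x$n_outer,
      if (x$stopped_early) " (stopping rule fired)" else " (round cap)",
      "\n", sep = "")
  cat("  parameter sets: ", nrow(x$ensemble), " kept, ",
      x$n_accepted, " accepted (BSR filter: ||f(x*)|| < ",
      format(x$config$spec$fix_tol), ", max nonzero Re lambda* < 0)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.teaps <- function(object, ...) {
  acc <- accepted_sets(object, log10 = TRUE)
  qs <- if (nrow(acc)) t(apply(acc, 2L, stats::quantile,
                               probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
        else NULL
  out <- list(model = object$model$name, n_sets = nrow(object$ensemble),
              n_accepted = object$n_accepted, n_outer = object$n_outer,
              stopped_early = object$stopped_early,
              log10_quantiles = qs,
              objective_summary = summary(object$ensemble[
                c("o_fix", "o_basin", "o_relax", "max_re")]))
  class(out) <- "summary.teaps"
  out
}

#' @export
print.summary.teaps <- function(x, ...) {
  cat("TEAPS search on model ", x$model, ": ", x$n_accepted, "/", x$n_sets,
      " sets accepted over ", x$n_outer, " outer round(s)",
      if (x$stopped_early) ", stopping rule fired" else "", "\n", sep = "")
  if (!is.null(x$log10_quantiles)) {
    cat("\nlog10 parameter quantiles (accepted sets):\n")
    print(round(x$log10_quantiles, 3))
  }
  cat("\nobjective components:\n")
  print(x$objective_summary)
  invisible(x)
}

#' Marginal log10 histograms of the accepted ensemble
#'
#' One panel per parameter over its search-box range, the usual first look at
#' which parameters the stability constraint pins down and which stay broad.
#'
#' @param x a `teaps` object.
#' @param breaks passed to [graphics::hist].
#' @param ... further arguments passed to [graphics::hist].
#' @export
plot.teaps <- function(x, breaks = 30, ...) {
  acc <- accepted_sets(x, log10 = TRUE)
  if (!nrow(acc)) {
    warning("no accepted sets to plot")
    return(invisible(x))
  }
  sp <- resolve_space(x$config, x$model)
  p <- ncol(acc)
  old <- graphics::par(mfrow = grDevices::n2mfrow(p),
                       mar = c(4, 3.5, 2, 0.5))
  on.exit(graphics::par(old))
  for (j in seq_len(p)) {
    graphics::hist(acc[, j], breaks = breaks, main = colnames(acc)[j],
                   xlab = "log10 value",
                   xlim = log10(c(sp$lower[j], sp$upper[j])), ...)
  }
  invisible(x)
}

#' @export
as.data.frame.teaps <- function(x, ...) x$ensemble
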