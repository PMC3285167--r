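#' Plot a work ensemble (replicate work functions)
#'
#' One colored work-versus-control-parameter curve per replicate with their
#' Jarzynski average overlaid in black.
#'
#' @param x A [work_ensemble()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.work_ensemble <- function(x, ...) {
  graphics::matplot(x$lambda_grid, x$works, type = "l", lty = 1,
                    col = grDevices::rainbow(ncol(x$works), v = 0.8),
                    xlab = expression(lambda ~ "(Å)"),
                    ylab = "work (kcal/mol)", ...)
  graphics::lines(x$lambda_grid, jarzynski_average(x), lwd = 2)
  invisible(x)
}

#' Plot a PMF estimate
#'
#' Raw Jarzynski average (black), bias-corrected estimate (solid red) and
#' its RMSE band (dashed red).
#'
#' @param x A [pmf_from_ensemble()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pmf_estimate <- function(x, ...) {
  rng <- range(x$raw_jarzynski, x$bias_corrected - x$rmse_band,
               x$bias_corrected + x$rmse_band)
  graphics::plot(x$lambda_grid, x$raw_jarzynski, type = "l", ylim = rng,
                 xlab = expression(lambda ~ "(Å)"),
                 ylab = expression(Delta * F ~ "(kcal/mol)"), ...)
  graphics::lines(x$lambda_grid, x$bias_corrected, col = "red", lwd = 2)
  graphics::lines(x$lambda_grid, x$bias_corrected + x$rmse_band,
                  col = "red", lty = 2)
  graphics::lines(x$lambda_grid, x$bias_corrected - x$rmse_band,
                  col = "red", lty = 2)
  invisible(x)
}
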