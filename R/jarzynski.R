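#' Jarzynski exponential work average
#'
#' The Jarzynski equality, \eqn{e^{-\beta\Delta F} = \langle e^{-\beta W}
#' \rangle}, recovers the equilibrium free-energy difference from an
#' ensemble of nonequilibrium work realizations. With N replicates the
#' estimator is \eqn{\Delta F_{JE}(\lambda) = -k_BT \ln \frac1N \sum_i
#' e^{-W_i(\lambda)/k_BT}}, evaluated here with log-sum-exp so that work
#' values of thousands of kT neither overflow nor underflow. Exponential
#' averaging weights low-work (high-probability) trajectories most; the
#' finite-N estimate is biased above the true \eqn{\Delta F} (see
#' [bias_correction()]).
#'
#' @param ensemble A [work_ensemble()], or a grid x N work matrix if
#'   `temperature` is supplied.
#' @param temperature Temperature in K (taken from the ensemble if missing).
#' @return Numeric vector \eqn{\Delta F_{JE}(\lambda)} (kcal/mol) on the
#'   ensemble's grid.
#' @export
jarzynski_average <- function(ensemble, temperature = NULL) {
  if (inherits(ensemble, "work_ensemble")) {
    works <- ensemble$works
    temperature <- temperature %||% ensemble$temperature
  } else {
    works <- as.matrix(ensemble)
    if (is.null(temperature)) stopf("temperature required with a bare matrix")
  }
  if (any(!is.finite(works))) {
    bad <- which(!is.finite(works), arr.ind = TRUE)
    stopf("non-finite work value(s), e.g. replicate %d at grid point %d",
          bad[1, 2], bad[1, 1])
  }
  if (temperature <= 0) stopf("temperature must be > 0")
  ktemp <- kT(temperature)
  apply(works, 1, function(w) -ktemp * logmeanexp(-w / ktemp))
}

# exact finite-N bias and RMSE of the Jarzynski estimator under the
# Gaussian work model (variance 2*w_dis*kT^2, fluctuation-dissipation),
# as interpolating spline functions of the dissipated work in kT units.
# For moderate N the expectation is computed numerically on a frozen
# standard-normal design (private RNG stream, so results are deterministic
# functions of their inputs); for large N the delta-method asymptote
# B = (e^{2w}-1)/(2N), Var = (e^{2w}-1)/N is used.
.bias_cache <- new.env(parent = emptyenv())

gauss_bias_fns <- function(N, n_boot = 3000L, w_max = 8) {
  if (N >= 2000L) {
    return(list(
      bias = function(w) (exp(2 * pmax(w, 0)) - 1) / (2 * N),
      rmse = function(w) sqrt((exp(2 * pmax(w, 0)) - 1) / N),
      w_max = Inf))
  }
  key <- sprintf("N%d_M%d", N, n_boot)
  cached <- .bias_cache[[key]]
  if (!is.null(cached) && cached$w_max >= w_max) return(cached)
  w_max <- max(w_max, if (!is.null(cached)) cached$w_max else 0)
  Z <- with_private_rng(914202L, matrix(stats::rnorm(N * n_boot), N, n_boot))
  w_grid <- seq(0, w_max, length.out = 81L)
  b <- r <- numeric(length(w_grid))
  for (i in seq_along(w_grid)) {
    w <- w_grid[i]
    if (w == 0) { b[i] <- 0; r[i] <- 0; next }
    fhat <- -log(colMeans(exp(-(w + sqrt(2 * w) * Z))))
    b[i] <- mean(fhat)
    r[i] <- sqrt(mean((fhat - b[i])^2))
  }
  fns <- list(
    bias = stats::splinefun(w_grid, b, method = "natural"),
    rmse = stats::splinefun(w_grid, r, method = "natural"),
    w_max = w_max)
  .bias_cache[[key]] <- fns
  fns
}

#' Finite-sample bias correction and error band for the Jarzynski average
#'
#' The N-replicate Jarzynski average overestimates \eqn{\Delta F} by a
#' truncation bias that grows with the dissipated work
#' \eqn{\hat W_{dis} = \bar W - \Delta F_{JE}}. This routine subtracts the
#' expected bias of the estimator under a fluctuation--dissipation
#' consistent Gaussian work model (work variance \eqn{2 k_BT\, W_{dis}}),
#' evaluating the model's exact finite-N expectation numerically for
#' moderate N and its large-N asymptote otherwise, with the dissipated work
#' estimated self-consistently from the corrected value. The mean-square
#' error of the corrected estimate is computed from the same model and
#' returned as an RMSE band. The correction vanishes as
#' \eqn{N \to \infty} and as \eqn{\hat W_{dis} \to 0}.
#'
#' @param raw Raw Jarzynski average \eqn{\Delta F_{JE}(\lambda)} (kcal/mol).
#' @param mean_work Mean work \eqn{\bar W(\lambda)} (kcal/mol), same length.
#' @param n Number of replicates N (must be >= 2).
#' @param temperature Temperature (K).
#' @param n_boot Size of the frozen design used by the numerical
#'   expectation.
#' @param self_consistent Iterate the dissipated-work estimate
#'   \eqn{\hat W_{dis} = \bar W - \Delta F_{BC}} to convergence (default).
#' @return List with `bias_corrected`, `rmse_band`, `correction` (all
#'   kcal/mol) and `w_dis_kT` (self-consistent dissipated work, kT units).
#' @export
bias_correction <- function(raw, mean_work, n, temperature,
                            n_boot = 3000L, self_consistent = TRUE) {
  if (n < 2) stopf("insufficient replicates for bias correction (N = %d)", n)
  if (length(raw) != length(mean_work))
    stopf("raw and mean_work lengths differ")
  ktemp <- kT(temperature)
  w <- pmax((mean_work - raw) / ktemp, 0)   # dissipated work, kT units
  fns <- gauss_bias_fns(n, n_boot, w_max = max(1, 1.5 * max(w)))
  b <- rep(0, length(w))
  if (self_consistent) {
    for (it in 1:50) {
      wb <- w + b
      if (max(wb) > fns$w_max)
        fns <- gauss_bias_fns(n, n_boot, w_max = 1.5 * max(wb))
      b_new <- pmax(fns$bias(wb), 0)
      if (max(abs(b_new - b)) < 1e-9) { b <- b_new; break }
      b <- b_new
    }
  } else {
    b <- pmax(fns$bias(w), 0)
  }
  b[w == 0] <- 0
  rmse <- pmax(fns$rmse(w + b), 0)
  rmse[w == 0] <- 0
  list(bias_corrected = raw - ktemp * b,
       rmse_band = ktemp * rmse,
       correction = -ktemp * b,
       w_dis_kT = w + b)
}

#' Assemble a PMF estimate from a work ensemble
#'
#' Computes, on the ensemble's control-parameter grid, the raw Jarzynski
#' average, the bias-corrected average, its RMSE band, the mean work and the
#' dissipated work. The PMF is referenced to zero at `lambda0` (the start of
#' steering, whichever direction that is).
#'
#' @param ensemble A [work_ensemble()].
#' @param n_boot Design size for the bias backend.
#' @param self_consistent See [bias_correction()].
#' @return An object of class `pmf_estimate` with fields `lambda_grid`,
#'   `raw_jarzynski`, `bias_corrected`, `rmse_band`, `mean_work`,
#'   `dissipated_work`, `n_replicates`, `temperature`.
#' @export
pmf_from_ensemble <- function(ensemble, n_boot = 3000L,
                              self_consistent = TRUE) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  raw <- jarzynski_average(ensemble)
  mw <- rowMeans(ensemble$works)
  N <- ncol(ensemble$works)
  if (N >= 2) {
    bc <- bias_correction(raw, mw, N, ensemble$temperature, n_boot,
                          self_consistent)
  } else {
    bc <- list(bias_corrected = raw, rmse_band = rep(NA_real_, length(raw)))
  }
  structure(list(lambda_grid = ensemble$lambda_grid,
                 raw_jarzynski = raw,
                 bias_corrected = bc$bias_corrected,
                 rmse_band = bc$rmse_band,
                 mean_work = mw,
                 dissipated_work = mw - raw,
                 n_replicates = N,
                 temperature = ensemble$temperature),
            class = "pmf_estimate")
}

#' @export
print.pmf_estimate <- function(x, ...) {
  ktemp <- kT(x$temperature)
  n <- length(x$lambda_grid)
  cat(sprintf("PMF estimate (N = %d, T = %g K), lambda %g -> %g\n",
              x$n_replicates, x$temperature, x$lambda_grid[1],
              x$lambda_grid[n]))
  cat(sprintf("  endpoint dF: raw %.4g, corrected %.4g +/- %.3g kcal/mol (%.3g kT)\n",
              x$raw_jarzynski[n], x$bias_corrected[n], x$rmse_band[n],
              x$bias_corrected[n] / ktemp))
  invisible(x)
}

#' Forward and reverse barrier heights from a PMF estimate
#'
#' The forward barrier is the maximum of the bias-corrected PMF over the
#' steered range minus its value at the steering start; the reverse barrier
#' is the same maximum minus the value at the far endpoint. For a monotone
#' profile the far endpoint is the maximum and one barrier is zero.
#'
#' @param pmf A [pmf_from_ensemble()] result.
#' @param curve Which curve to read barriers from (default the
#'   bias-corrected PMF).
#' @return An object of class `barrier_report`: `forward_barrier`,
#'   `reverse_barrier` (kcal/mol), `barrier_position` (lambda at the
#'   maximum), `steering_direction`.
#' @export
barrier_heights <- function(pmf, curve = c("bias_corrected",
                                           "raw_jarzynski")) {
  stopifnot(inherits(pmf, "pmf_estimate"))
  curve <- match.arg(curve)
  f <- pmf[[curve]]
  n <- length(f)
  imax <- which.max(f)
  direction <- if (pmf$lambda_grid[n] >= pmf$lambda_grid[1])
    "increasing" else "decreasing"
  structure(list(forward_barrier = f[imax] - f[1],
                 reverse_barrier = f[imax] - f[n],
                 barrier_position = pmf$lambda_grid[imax],
                 steering_direction = direction,
                 curve = curve),
            class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf(
    "barriers (%s): forward %.4g, reverse %.4g kcal/mol at lambda = %.4g\n",
    x$curve, x$forward_barrier, x$reverse_barrier, x$barrier_position))
  invisible(x)
}
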