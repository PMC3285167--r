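#' Define a replicate steering protocol
#'
#' A steering protocol drags a control parameter \eqn{\lambda} linearly from
#' `lambda0` to `lambda1` over `n_steps` integrator steps and is repeated
#' over `n_replicates` independent replicates, each started from a distinct
#' snapshot of a restrained equilibrium run and integrated with its own RNG
#' seed. For `control = "cv"` the control parameter is the target of a stiff
#' harmonic restraint on the system's LCOD coordinate and the accumulated
#' work is \eqn{W = \int (\partial U/\partial\lambda)\,d\lambda} with
#' \eqn{\partial U/\partial\lambda = -k(\xi - \lambda)}; for
#' `control = "stiffness"` \eqn{\lambda} is the harmonic-well stiffness and
#' \eqn{\partial U/\partial\lambda = (x - x_c)^2/2}. Work is accumulated by
#' a midpoint rule in \eqn{\lambda} per step.
#'
#' @param system A [make_system()] object.
#' @param lambda0,lambda1 Control-parameter endpoints (defaults: the
#'   system's). `lambda1 < lambda0` steers right-to-left.
#' @param n_steps Integrator steps per replicate.
#' @param dt Time step (ps).
#' @param k Restraint spring constant, kcal/(mol A^2) (`control = "cv"`).
#' @param n_replicates Number of replicates N.
#' @param seeds Integer vector of N pairwise-distinct replicate seeds, or
#'   `NULL` to derive them from `seed_base`.
#' @param seed_base Base for derived seeds (`seed_base + 1:N`).
#' @param snapshot_interval Steps between snapshots in the restrained
#'   pre-run.
#' @param sample_interval Steps between recorded points of the work/CV
#'   series (the reporting grid).
#' @param control `"cv"` or `"stiffness"` (default: the system's).
#' @param integrator `"overdamped"` or `"baoab"`.
#' @return An object of class `steering_protocol`.
#' @export
steering_protocol <- function(system, lambda0 = system$lambda0,
                              lambda1 = system$lambda1, n_steps = 10000L,
                              dt = system$dt, k = 1000,
                              n_replicates = 30L, seeds = NULL,
                              seed_base = 0L, snapshot_interval = 500L,
                              sample_interval = max(1L, n_steps %/% 200L),
                              control = system$control,
                              integrator = "overdamped") {
  stopifnot(inherits(system, "model_system"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  if (is.null(seeds)) seeds <- as.integer(seed_base) + seq_len(n_replicates)
  seeds <- as.integer(seeds)
  if (length(seeds) != n_replicates)
    stopf("need exactly %d seeds, got %d", n_replicates, length(seeds))
  if (anyDuplicated(seeds))
    stopf("replicate seeds must be pairwise distinct")
  if (k <= 0) stopf("spring constant k must be > 0")
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (dt <= 0) stopf("dt must be > 0")
  if (!control %in% c("cv", "stiffness")) stopf("unknown control mode")
  structure(list(system = system, lambda0 = lambda0, lambda1 = lambda1,
                 n_steps = as.integer(n_steps), dt = dt, k = k,
                 n_replicates = n_replicates, seeds = seeds,
                 snapshot_interval = as.integer(snapshot_interval),
                 sample_interval = as.integer(sample_interval),
                 control = control, integrator = integrator),
            class = "steering_protocol")
}

#' @export
print.steering_protocol <- function(x, ...) {
  cat(sprintf(
    "steering protocol: %s %g -> %g, %d steps x %g ps, k = %g, N = %d\n",
    x$control, x$lambda0, x$lambda1, x$n_steps, x$dt, x$k, x$n_replicates))
  invisible(x)
}

#' Generate replicate starting states from a restrained equilibrium run
#'
#' Runs equilibrium dynamics with the control parameter held at `lambda0`
#' (for CV control, under the same harmonic restraint used for steering) and
#' writes a snapshot every `snapshot_interval` steps. Snapshots sample the
#' restrained equilibrium ensemble, so all replicates start from the same
#' ensemble.
#'
#' @param system A [make_system()] object.
#' @param protocol A [steering_protocol()].
#' @param run_steps Length of the restrained pre-run in steps.
#' @param snapshot_interval Steps between snapshots (default: protocol's).
#' @param seed RNG seed for the pre-run.
#' @return List of starting coordinate vectors (class `snapshot_set`), with
#'   attributes `cv` (CV at each snapshot) and `run` (the pre-run
#'   trajectory). `floor(run_steps / snapshot_interval)` snapshots.
#' @export
generate_snapshots <- function(system, protocol, run_steps = 50000L,
                               snapshot_interval = protocol$snapshot_interval,
                               seed = 0L) {
  stopifnot(inherits(protocol, "steering_protocol"))
  n_snap <- run_steps %/% snapshot_interval
  if (n_snap < 1L)
    stopf("insufficient snapshots: run of %d steps yields none at interval %d",
          run_steps, snapshot_interval)
  x0 <- system$x0
  if (identical(protocol$control, "cv"))
    x0[system$potential$atom] <- system$cv_to_x(protocol$lambda0)
  traj <- if (identical(protocol$control, "cv")) {
    engine_trajectory(system, x0, n_steps = n_snap * snapshot_interval,
                      dt = protocol$dt, sample_interval = snapshot_interval,
                      control_mode = 1L, k_restraint = protocol$k,
                      lambda0 = protocol$lambda0, lambda1 = protocol$lambda0,
                      integrator = protocol$integrator, seed = seed)
  } else {
    sys0 <- system
    sys0$potential$params[1] <- protocol$lambda0
    engine_trajectory(sys0, x0, n_steps = n_snap * snapshot_interval,
                      dt = protocol$dt, sample_interval = snapshot_interval,
                      control_mode = 0L, integrator = protocol$integrator,
                      seed = seed)
  }
  # drop the t = 0 frame: snapshots are at interval, 2*interval, ...
  idx <- seq_len(n_snap) + 1L
  snaps <- lapply(idx, function(i) traj$coords[i, , 1])
  structure(snaps, class = "snapshot_set",
            cv = traj$cv[idx], run = traj, seed = seed)
}

#' Run one steered replicate
#'
#' Integrates one replicate of the steering protocol from a given starting
#' state, accumulating work against the moving control parameter. The final
#' control value `lambda1` is reached exactly; `W(lambda0) = 0`.
#'
#' @param state Starting coordinates (a vector of atom x positions, e.g. one
#'   element of [generate_snapshots()]).
#' @param protocol A [steering_protocol()].
#' @param seed Integer replicate seed.
#' @return List with `lambda` (reporting grid), `work` (kcal/mol),
#'   `cv` (achieved CV), `time` (ps) and the full `trajectory`.
#' @export
run_replicate <- function(state, protocol, seed) {
  stopifnot(inherits(protocol, "steering_protocol"))
  system <- protocol$system
  mode <- if (identical(protocol$control, "cv")) 1L else 2L
  traj <- tryCatch(
    engine_trajectory(system, state, n_steps = protocol$n_steps,
                      dt = protocol$dt,
                      sample_interval = protocol$sample_interval,
                      control_mode = mode, k_restraint = protocol$k,
                      lambda0 = protocol$lambda0, lambda1 = protocol$lambda1,
                      integrator = protocol$integrator, seed = seed),
    error = function(e)
      stopf("replicate with seed %d failed: %s", seed, conditionMessage(e)))
  list(lambda = traj$lambda, work = traj$work, cv = traj$cv,
       time = traj$times, trajectory = traj)
}

#' Run a replicate work ensemble
#'
#' Steers `protocol$n_replicates` replicates, each from its own snapshot and
#' seed, and collects the work-versus-control-parameter functions on the
#' common reporting grid.
#'
#' @param protocol A [steering_protocol()].
#' @param snapshots A `snapshot_set` from [generate_snapshots()] with at
#'   least N members; N of them are used, evenly spaced across the set.
#' @return An object of class `work_ensemble`: `lambda_grid`, `works`
#'   (grid x N matrix, kcal/mol), `achieved_cv` (grid x N), `temperature`,
#'   `seeds`, `snapshot_index`, `protocol`.
#' @export
run_ensemble <- function(protocol, snapshots) {
  stopifnot(inherits(protocol, "steering_protocol"))
  N <- protocol$n_replicates
  if (length(snapshots) < N)
    stopf("need at least %d snapshots, have %d", N, length(snapshots))
  if (anyDuplicated(protocol$seeds))
    stopf("replicate seeds must be pairwise distinct")
  snap_idx <- unique(round(seq(1L, length(snapshots), length.out = N)))
  if (length(snap_idx) < N)  # more replicates than snapshots spacing allows
    snap_idx <- seq_len(N)
  reps <- lapply(seq_len(N), function(i)
    run_replicate(snapshots[[snap_idx[i]]], protocol, protocol$seeds[i]))
  lambda_grid <- reps[[1]]$lambda
  works <- vapply(reps, `[[`, numeric(length(lambda_grid)), "work")
  cvs <- vapply(reps, `[[`, numeric(length(lambda_grid)), "cv")
  work_ensemble(lambda_grid, works, achieved_cv = cvs,
                temperature = protocol$system$temperature,
                protocol = protocol, seeds = protocol$seeds,
                snapshot_index = snap_idx)
}

#' Construct / validate a work ensemble
#'
#' @param lambda_grid Control-parameter grid, strictly monotone in the
#'   steering direction (a constant grid is allowed only for null steering,
#'   `lambda0 == lambda1`).
#' @param works grid x N matrix of accumulated work (kcal/mol); the first
#'   row (at `lambda0`) must be zero for every replicate.
#' @param achieved_cv Optional grid x N matrix of realized CV values.
#' @param temperature Temperature (K).
#' @param protocol,seeds,snapshot_index Optional provenance.
#' @return An object of class `work_ensemble`.
#' @export
work_ensemble <- function(lambda_grid, works, achieved_cv = NULL,
                          temperature, protocol = NULL, seeds = NULL,
                          snapshot_index = NULL) {
  works <- as.matrix(works)
  if (nrow(works) != length(lambda_grid))
    stopf("works must have one row per lambda grid point")
  if (any(!is.finite(works)))
    stopf("non-finite work values (replicate %s)",
          paste(unique(which(!is.finite(works), arr.ind = TRUE)[, 2]),
                collapse = ", "))
  if (any(works[1, ] != 0))
    stopf("W(lambda0) must be 0 for every replicate")
  d <- diff(lambda_grid)
  if (length(d) && !(all(d > 0) || all(d < 0) || all(d == 0)))
    stopf("lambda_grid must be strictly monotone in the steering direction")
  structure(list(lambda_grid = lambda_grid, works = works,
                 achieved_cv = achieved_cv, temperature = temperature,
                 protocol = protocol, seeds = seeds,
                 snapshot_index = snapshot_index),
            class = "work_ensemble")
}

#' @export
print.work_ensemble <- function(x, ...) {
  cat(sprintf(
    "work ensemble: %d replicates on %d-point grid (lambda %g -> %g), T = %g K\n",
    ncol(x$works), length(x$lambda_grid), x$lambda_grid[1],
    x$lambda_grid[length(x$lambda_grid)], x$temperature))
  invisible(x)
}

#' Steering-quality diagnostics
#'
#' Checks how faithfully the achieved CV tracked the moving target: per
#' replicate, the maximum lag |achieved - target|, the fraction of frames
#' within four equilibrium restraint widths \eqn{\sigma = \sqrt{k_BT/k}},
#' the largest inter-frame CV jump, and the slope of a linear fit of
#' achieved versus target. A replicate is flagged `discontinuous` if its
#' largest jump exceeds `jump_factor` restraint widths (catch-up jumps after
#' a soft spring lags), and `lagging` if fewer than `lag_quantile` of its
#' frames are within four widths.
#'
#' @param ensemble A [work_ensemble()] with `achieved_cv` (CV control only).
#' @param jump_factor Discontinuity threshold in units of the equilibrium
#'   restraint width (default 10).
#' @param lag_quantile Minimum well-tracked frame fraction (default 0.95).
#' @return A data.frame (class `steering_diagnostics`), one row per
#'   replicate, with attribute `restraint_width`.
#' @export
steering_diagnostics <- function(ensemble, jump_factor = 10,
                                 lag_quantile = 0.95) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  if (is.null(ensemble$achieved_cv))
    stopf("ensemble carries no achieved-CV record")
  prot <- ensemble$protocol
  if (!is.null(prot) && !identical(prot$control, "cv"))
    stopf("tracking diagnostics apply to CV-controlled steering only")
  k <- if (!is.null(prot)) prot$k else 1000
  width <- sqrt(kT(ensemble$temperature) / k)
  lam <- ensemble$lambda_grid
  out <- do.call(rbind, lapply(seq_len(ncol(ensemble$achieved_cv)),
    function(j) {
      cv <- ensemble$achieved_cv[, j]
      lag <- abs(cv - lam)
      jump <- if (length(cv) > 1) max(abs(diff(cv))) else 0
      slope <- if (stats::var(lam) > 0)
        unname(stats::coef(stats::lm.fit(cbind(1, lam), cv))[2]) else NA_real_
      data.frame(replicate = j, max_lag = max(lag),
                 frac_within_4w = mean(lag <= 4 * width),
                 max_jump = jump, slope = slope)
    }))
  rownames(out) <- NULL
  out$discontinuous <- out$max_jump > jump_factor * width
  out$lagging <- out$frac_within_4w < lag_quantile
  attr(out, "restraint_width") <- width
  class(out) <- c("steering_diagnostics", "data.frame")
  out
}
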