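#' Analytic model systems for steered-dynamics benchmarking
#'
#' Each system is a small set of atoms on the x axis with an analytic site
#' potential, a default LCOD collective variable, Langevin parameters and a
#' known free-energy oracle. They stand in for a full molecular engine when
#' exercising the steering and Jarzynski machinery:
#'
#' * `dragged_harmonic_trap` -- a free particle on a uniform landscape whose
#'   distance to a fixed anchor is steered by the harmonic restraint; the
#'   exact free-energy difference of any translation is 0.
#' * `stiffness_switch` -- a particle in a harmonic well whose stiffness is
#'   the control parameter, switched from `k1` to `k2`; exact
#'   \eqn{\Delta F = (k_B T/2)\ln(k_2/k_1)} (1 kT for \eqn{k_2 = e^2 k_1}).
#' * `quartic_double_well` -- distance CV steered across a quartic double
#'   well \eqn{V_0((x-c)^2/a^2 - 1)^2}; the exact PMF equals the potential.
#' * `three_atom_transfer` -- collinear donor--H--acceptor with a double-well
#'   hydrogen potential supporting rare unforced transfer events; the
#'   proton-transfer CV is \eqn{d(D,H) - d(A,H)}.
#'
#' @param name One of `"dragged_harmonic_trap"`, `"stiffness_switch"`,
#'   `"quartic_double_well"`, `"three_atom_transfer"`.
#' @param ... Named parameter overrides (see Details).
#' @details Overridable parameters (with defaults) include `temperature`
#'   (300 K), `gamma` (friction, kcal ps mol^-1 A^-2), `dt` (ps), and the
#'   per-system potential parameters: `k1`, `k2` (stiffness switch,
#'   kcal/(mol A^2)); `V0`, `center`, `half_width` (double wells, kcal/mol
#'   and angstrom); `d_da`, `r0` (three-atom donor--acceptor separation and
#'   bonded H distance, angstrom).
#' @return An object of class `model_system`.
#' @export
make_system <- function(name, ...) {
  ov <- list(...)
  base <- switch(
    name,
    dragged_harmonic_trap = list(
      x0 = c(0, 5), mobile = c(FALSE, TRUE),
      potential = list(id = 0L, atom = 2L, params = numeric()),
      cv = lcod_spec(rbind(c(1, 2)), 1),
      cv_to_x = function(cv) cv,   # x of mobile atom for CV value
      control = "cv", lambda0 = 5, lambda1 = 7,
      gamma = 1, dt = 1e-4),
    stiffness_switch = list(
      x0 = c(-10, 0), mobile = c(FALSE, TRUE),
      k1 = 1, k2 = exp(2),
      potential = list(id = 1L, atom = 2L, params = c(1, 0)),
      cv = lcod_spec(rbind(c(1, 2)), 1),
      cv_to_x = function(cv) cv - 10,
      control = "stiffness", lambda0 = 1, lambda1 = exp(2),
      gamma = 0.5, dt = 5e-3),
    quartic_double_well = list(
      x0 = c(0, 3), mobile = c(FALSE, TRUE),
      V0 = 3, center = 4, half_width = 1,
      potential = list(id = 2L, atom = 2L, params = c(3, 4, 1)),
      cv = lcod_spec(rbind(c(1, 2)), 1),
      cv_to_x = function(cv) cv,
      control = "cv", lambda0 = 3, lambda1 = 5,
      gamma = 1, dt = 1e-4),
    three_atom_transfer = list(
      x0 = c(0, 1, 2.8), mobile = c(FALSE, TRUE, FALSE),
      V0 = 3.5, d_da = 2.8, r0 = 1,
      potential = list(id = 2L, atom = 2L, params = c(3.5, 1.4, 0.4)),
      cv = lcod_spec(rbind(c(1, 2), c(3, 2)), c(1, -1)),
      cv_to_x = function(cv) (cv + 2.8) / 2,
      control = "cv", lambda0 = -0.8, lambda1 = 0.8,
      gamma = 1, dt = 5e-4),
    stopf("unknown model system '%s'", name)
  )
  base$name <- name
  base$temperature <- 300
  base$mass <- 0.03  # kcal ps^2 mol^-1 A^-2 (~12.5 g/mol), BAOAB only
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]

  # propagate potential-parameter overrides into the packed vector
  if (name == "stiffness_switch")
    base$potential$params <- c(base$k1, 0)
  if (name == "quartic_double_well")
    base$potential$params <- c(base$V0, base$center, base$half_width)
  if (name == "three_atom_transfer") {
    d <- base$d_da; r0 <- base$r0
    if (r0 >= d / 2) stopf("r0 must be < d_da/2")
    base$potential$params <- c(base$V0, d / 2, d / 2 - r0)
    base$x0 <- c(0, r0, d)
    base$cv_to_x <- local({d0 <- d; function(cv) (cv + d0) / 2})
    base$lambda0 <- 2 * r0 - d      # CV at the donor-bound minimum
    base$lambda1 <- d - 2 * r0      # CV at the acceptor-bound minimum
  }
  if (base$temperature < 0) stopf("temperature must be >= 0")
  if (base$gamma <= 0) stopf("friction gamma must be > 0")
  base$n_atoms <- length(base$x0)
  structure(base, class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("model system '%s': %d atom(s), T = %g K, gamma = %g\n",
              x$name, x$n_atoms, x$temperature, x$gamma))
  invisible(x)
}

# potential energy of the system's site potential as a function of the
# mobile-atom x coordinate (used by oracles and pure-R stepping)
potential_energy_fn <- function(system, lambda = NULL) {
  p <- system$potential
  switch(as.character(p$id),
    "0" = function(x) rep(0, length(x)),
    "1" = {
      kap <- if (identical(system$control, "stiffness") && !is.null(lambda))
        lambda else p$params[1]
      cen <- p$params[2]
      function(x) 0.5 * kap * (x - cen)^2
    },
    "2" = {
      V0 <- p$params[1]; cen <- p$params[2]; a <- p$params[3]
      function(x) V0 * (((x - cen) / a)^2 - 1)^2
    })
}

#' One Langevin integrator update (reference implementation)
#'
#' A single overdamped Euler--Maruyama or BAOAB update for one mobile
#' coordinate, matching the compiled engine's update rule. Mainly useful for
#' step-level testing; long runs should use [simulate_system()].
#'
#' @param state List with `x` (position, angstrom) and optionally `v`
#'   (velocity, angstrom/ps, BAOAB only).
#' @param system A [make_system()] object (supplies `gamma`, `temperature`,
#'   `mass`).
#' @param dt Time step (ps).
#' @param force Function of position returning the total conservative force
#'   (kcal/(mol A)), including any restraint contribution.
#' @param integrator `"overdamped"` or `"baoab"`.
#' @return Updated `state`. Identical RNG state gives identical updates.
#' @export
langevin_step <- function(state, system, dt, force,
                          integrator = c("overdamped", "baoab")) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stopf("dt must be > 0")
  ktemp <- kT(system$temperature)
  g <- system$gamma
  x <- state$x
  if (!is.finite(x)) stopf("integration failure: non-finite position on entry")
  if (integrator == "overdamped") {
    x <- x + dt * force(x) / g
    if (ktemp > 0) x <- x + sqrt(2 * ktemp * dt / g) * stats::rnorm(1)
    state$x <- x
  } else {
    m <- system$mass
    v <- state$v %||% 0
    v <- v + 0.5 * dt * force(x) / m
    x <- x + 0.5 * dt * v
    c1 <- exp(-g * dt)
    v <- c1 * v
    if (ktemp > 0) v <- v + sqrt(ktemp / m * (1 - c1^2)) * stats::rnorm(1)
    x <- x + 0.5 * dt * v
    v <- v + 0.5 * dt * force(x) / m
    state$x <- x; state$v <- v
  }
  if (!is.finite(state$x))
    stopf("integration failure: non-finite position after step")
  state
}

# low-level bridge to the compiled engine; returns a trajectory object
engine_trajectory <- function(system, x0, n_steps, dt, sample_interval,
                              control_mode, k_restraint = 0, lambda0 = 0,
                              lambda1 = 0, flat_well = NULL,
                              integrator = "overdamped", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fw_center <- -1L; fw_sat <- integer(); fw_radius <- 1; fw_k <- 0
  if (!is.null(flat_well)) {
    fw_center <- flat_well$center_atom - 1L
    fw_sat <- flat_well$satellite_atoms - 1L
    fw_radius <- flat_well$radius
    fw_k <- flat_well$k_wall
  }
  out <- engine_run(
    x0 = x0, mobile = system$mobile,
    potential_id = system$potential$id,
    potential_atom = system$potential$atom - 1L,
    potential_params = as.numeric(system$potential$params),
    control_mode = control_mode,
    pair_a = system$cv$pairs[, 1] - 1L, pair_b = system$cv$pairs[, 2] - 1L,
    coeff = system$cv$coefficients,
    k_restraint = k_restraint, lambda0 = lambda0, lambda1 = lambda1,
    fw_center = fw_center, fw_sat = fw_sat, fw_radius = fw_radius,
    fw_k = fw_k,
    n_steps = as.integer(n_steps), dt = dt,
    temperature = system$temperature, gamma = system$gamma,
    mass = system$mass,
    integrator_id = if (identical(integrator, "baoab")) 1L else 0L,
    sample_interval = as.integer(sample_interval))
  n_frames <- length(out$time)
  coords <- array(0, dim = c(n_frames, system$n_atoms, 3L))
  coords[, , 1] <- out$positions
  structure(list(times = out$time, coords = coords, cv = out$cv,
                 lambda = out$lambda, work = out$work,
                 restraint_energy = out$restraint_energy,
                 sampling_interval = dt * sample_interval,
                 system = system$name, seed = seed),
            class = "trajectory")
}

#' Simulate a model system
#'
#' Runs Langevin dynamics on a model system, optionally under a fixed
#' harmonic CV restraint, recording frames every `sample_interval` steps.
#'
#' @param system A [make_system()] object.
#' @param n_steps Number of integrator steps.
#' @param dt Time step in ps (default: the system's `dt`).
#' @param seed Integer RNG seed; equal seeds give bit-identical trajectories.
#' @param sample_interval Steps between recorded frames.
#' @param restrain_at Optional CV value; if given, a harmonic restraint of
#'   stiffness `k` holds the CV there throughout (work is identically zero).
#' @param k Restraint stiffness when `restrain_at` is used.
#' @param x0 Optional starting coordinates (defaults to the system's).
#' @param integrator `"overdamped"` (default) or `"baoab"`.
#' @return A `trajectory` object: `times` (ps), `coords`
#'   (frames x atoms x 3, angstrom), `cv`, `work`, `restraint_energy`.
#' @export
simulate_system <- function(system, n_steps, dt = system$dt, seed = NULL,
                            sample_interval = 10L, restrain_at = NULL,
                            k = 1000, x0 = system$x0,
                            integrator = "overdamped") {
  stopifnot(inherits(system, "model_system"))
  if (is.null(restrain_at)) {
    engine_trajectory(system, x0, n_steps, dt, sample_interval,
                      control_mode = 0L, integrator = integrator, seed = seed)
  } else {
    engine_trajectory(system, x0, n_steps, dt, sample_interval,
                      control_mode = 1L, k_restraint = k,
                      lambda0 = restrain_at, lambda1 = restrain_at,
                      integrator = integrator, seed = seed)
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms, %.4g ps (interval %.4g ps)\n",
              length(x$times), dim(x$coords)[2], max(x$times),
              x$sampling_interval))
  invisible(x)
}

#' Exact free-energy difference for a model system
#'
#' Deterministic oracle: the free-energy difference between the restrained
#' (or parameterized) equilibrium states at two control-parameter values,
#' \eqn{F(\lambda) = -k_BT \ln \int e^{-\beta(U(x) + u_r(x;\lambda))} dx},
#' computed by quadrature of the Boltzmann density (closed form where one
#' exists). For CV-controlled systems `k` is the restraint stiffness;
#' `k = Inf` gives the stiff-spring limit \eqn{U(x(\lambda))} difference.
#'
#' @param system A [make_system()] object (1-D mobile coordinate).
#' @param lambda_from,lambda_to Control-parameter endpoints (defaults: the
#'   system's `lambda0`, `lambda1`).
#' @param k Restraint stiffness for CV-controlled systems (default `Inf`).
#' @return Free-energy difference in kcal/mol.
#' @export
exact_free_energy <- function(system, lambda_from = system$lambda0,
                              lambda_to = system$lambda1, k = Inf) {
  stopifnot(inherits(system, "model_system"))
  if (sum(system$mobile) != 1L)
    stopf("unsupported oracle: system is not one-dimensional")
  ktemp <- kT(system$temperature)
  if (identical(system$control, "stiffness"))
    return(0.5 * ktemp * log(lambda_to / lambda_from))
  U <- potential_energy_fn(system)
  if (!is.finite(k)) {
    return(U(system$cv_to_x(lambda_to)) - U(system$cv_to_x(lambda_from)))
  }
  z <- function(lam) {
    xc <- system$cv_to_x(lam)
    # the restraint acts on the CV, which is linear in x: d(cv)/dx = s
    s <- 1 / abs(system$cv_to_x(lam + 1) - system$cv_to_x(lam))
    w <- sqrt(ktemp / k) / s
    f <- function(x) exp(-(U(x) + 0.5 * k * (s * (x - xc))^2) / ktemp)
    stats::integrate(f, xc - 12 * w - 3, xc + 12 * w + 3,
                     rel.tol = 1e-10)$value
  }
  -ktemp * (log(z(lambda_to)) - log(z(lambda_from)))
}

#' Exact potential of mean force along the CV
#'
#' For the 1-D systems the marginal Boltzmann density along the CV is
#' \eqn{p(\xi) \propto e^{-\beta U(x(\xi))}} (the CV is linear in the mobile
#' coordinate, so the Jacobian is constant), hence the PMF equals the site
#' potential up to an additive constant.
#'
#' @param system A [make_system()] object.
#' @param grid CV values at which to evaluate.
#' @param reference CV value where the PMF is zeroed (default `grid[1]`).
#' @return Numeric PMF values (kcal/mol).
#' @export
exact_pmf <- function(system, grid, reference = grid[1]) {
  stopifnot(inherits(system, "model_system"))
  if (identical(system$control, "stiffness"))
    stopf("unsupported oracle: PMF along the CV is not defined for a stiffness-controlled system")
  U <- potential_energy_fn(system)
  U(system$cv_to_x(grid)) - U(system$cv_to_x(reference))
}

#' Boltzmann equilibrium density oracle
#'
#' Normalized equilibrium density of the mobile coordinate on a grid, by
#' quadrature; used to validate the sampler.
#'
#' @param system A [make_system()] object.
#' @param x Grid of mobile-coordinate values (angstrom).
#' @return Density values integrating to one over `x` (trapezoid rule).
#' @export
boltzmann_density <- function(system, x) {
  U <- potential_energy_fn(system)
  ktemp <- kT(system$temperature)
  w <- exp(-(U(x) - min(U(x))) / ktemp)
  dx <- diff(x)
  z <- sum((w[-1] + w[-length(w)]) / 2 * dx)
  w / z
}
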