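#' Linear-combination-of-distances (LCOD) collective variable
#'
#' An LCOD collective variable is a signed linear combination of interatomic
#' distances, \eqn{\xi = \sum_i c_i \, \|r_{a_i} - r_{b_i}\|}. It generalizes
#' single-distance reaction coordinates; with pairs (donor, H) and
#' (acceptor, H) and coefficients (+1, -1) it is the standard proton-transfer
#' coordinate, negative while the hydrogen is donor-bound and zero at the
#' donor--acceptor midpoint.
#'
#' @param pairs Two-column integer matrix (or list of length-2 vectors) of
#'   atom index pairs \eqn{(a_i, b_i)}, 1-based.
#' @param coefficients Numeric vector of signed coefficients \eqn{c_i}, one
#'   per pair.
#' @return An object of class `lcod_spec`.
#' @examples
#' # proton-transfer coordinate d(D,H) - d(A,H)
#' lcod_spec(rbind(c(1, 2), c(3, 2)), c(1, -1))
#' @export
lcod_spec <- function(pairs, coefficients) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  coefficients <- as.numeric(coefficients)
  if (nrow(pairs) < 1L) stopf("an LCOD needs at least one atom pair")
  if (nrow(pairs) != length(coefficients))
    stopf("pairs (%d) and coefficients (%d) differ in length",
          nrow(pairs), length(coefficients))
  if (anyNA(pairs) || any(pairs < 1L)) stopf("atom indices must be positive integers")
  if (anyNA(coefficients) || !all(is.finite(coefficients)))
    stopf("coefficients must be finite")
  structure(list(pairs = pairs, coefficients = coefficients),
            class = "lcod_spec")
}

#' @export
print.lcod_spec <- function(x, ...) {
  cat("LCOD collective variable:", nrow(x$pairs), "distance term(s)\n")
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %+g * d(%d, %d)\n", x$coefficients[i],
                x$pairs[i, 1], x$pairs[i, 2]))
  invisible(x)
}

check_frame <- function(frame, spec) {
  if (!is.matrix(frame) || ncol(frame) != 3L)
    stopf("frame must be an n x 3 coordinate matrix")
  if (any(spec$pairs > nrow(frame)))
    stopf("LCOD atom index exceeds frame size (%d atoms)", nrow(frame))
  invisible(TRUE)
}

pair_vectors <- function(frame, spec) {
  d <- frame[spec$pairs[, 1], , drop = FALSE] -
       frame[spec$pairs[, 2], , drop = FALSE]
  list(delta = d, dist = sqrt(rowSums(d * d)))
}

#' Evaluate an LCOD collective variable on a coordinate frame
#'
#' @param frame An n x 3 matrix of atomic positions (angstrom).
#' @param spec An [lcod_spec()].
#' @return The CV value in angstrom. Pairs at exactly zero separation
#'   contribute zero, with a warning (their gradient is undefined; see
#'   [lcod_gradient()]).
#' @export
eval_lcod <- function(frame, spec) {
  check_frame(frame, spec)
  pv <- pair_vectors(frame, spec)
  if (any(pv$dist == 0))
    warning("LCOD pair(s) at zero separation contribute 0 to the CV")
  sum(spec$coefficients * pv$dist)
}

#' Analytic gradient of an LCOD collective variable
#'
#' Returns \eqn{\partial \xi / \partial r} as an n x 3 matrix; atoms not in
#' the spec have zero gradient, and repeated atoms accumulate contributions
#' additively (needed for proton-transfer CVs sharing the hydrogen).
#'
#' @inheritParams eval_lcod
#' @return n x 3 gradient matrix (dimensionless, per angstrom of atom motion).
#' @export
lcod_gradient <- function(frame, spec) {
  check_frame(frame, spec)
  pv <- pair_vectors(frame, spec)
  if (any(pv$dist == 0))
    stopf("degenerate geometry: LCOD pair at zero separation has no gradient")
  grad <- matrix(0, nrow(frame), 3L)
  unit <- pv$delta / pv$dist
  for (i in seq_len(nrow(spec$pairs))) {
    a <- spec$pairs[i, 1]; b <- spec$pairs[i, 2]
    g <- spec$coefficients[i] * unit[i, ]
    grad[a, ] <- grad[a, ] + g
    grad[b, ] <- grad[b, ] - g
  }
  grad
}

#' Harmonic path restraint on an LCOD coordinate
#'
#' Restraint energy \eqn{U(r; \lambda) = (k/2)(\xi(r) - \lambda)^2} used to
#' steer the CV along a linear path between `lambda0` and `lambda1`. Very
#' stiff `k` (default 1000 kcal/(mol A^2)) keeps the achieved CV tracking the
#' target so that restraint work is interpretable as work along the CV.
#'
#' @param spec An [lcod_spec()].
#' @param k Spring constant, kcal/(mol A^2).
#' @param lambda0,lambda1 Path endpoints (angstrom).
#' @export
harmonic_path_restraint <- function(spec, k = 1000, lambda0, lambda1) {
  stopifnot(inherits(spec, "lcod_spec"))
  if (!is.numeric(k) || k <= 0) stopf("spring constant k must be > 0")
  if (!is.finite(lambda0) || !is.finite(lambda1))
    stopf("path endpoints must be finite")
  structure(list(spec = spec, k = k, lambda0 = lambda0, lambda1 = lambda1),
            class = "harmonic_path_restraint")
}

#' Energy and forces of a harmonic path restraint
#'
#' @param frame n x 3 coordinate matrix.
#' @param restraint A [harmonic_path_restraint()].
#' @param lambda_t Instantaneous target value of the control parameter.
#' @return List with `energy` (kcal/mol) and `forces` (n x 3, kcal/(mol A)).
#' @export
restraint_energy_force <- function(frame, restraint, lambda_t) {
  stopifnot(inherits(restraint, "harmonic_path_restraint"))
  if (!is.finite(lambda_t)) stopf("lambda_t must be finite")
  cv <- eval_lcod(frame, restraint$spec)
  dev <- cv - lambda_t
  if (dev == 0) {
    return(list(energy = 0, forces = matrix(0, nrow(frame), 3L)))
  }
  grad <- lcod_gradient(frame, restraint$spec)
  list(energy = 0.5 * restraint$k * dev^2,
       forces = -restraint$k * dev * grad)
}

#' Flat-well spherical restraint
#'
#' Zero potential while every satellite atom lies within `radius` of the
#' center atom; harmonic walls of stiffness `k_wall` outside. Used to keep a
#' reagent (e.g. an active-site water) near the reaction center without
#' biasing its interior motion. The energy is continuous and once
#' differentiable at the wall.
#'
#' @param center_atom Index of the central atom.
#' @param satellite_atoms Indices of the restrained atoms.
#' @param radius Well radius (angstrom).
#' @param k_wall Wall stiffness, kcal/(mol A^2).
#' @export
flat_well_restraint <- function(center_atom, satellite_atoms, radius = 3,
                                k_wall = 10) {
  if (radius <= 0) stopf("flat-well radius must be > 0")
  if (k_wall <= 0) stopf("flat-well wall stiffness must be > 0")
  structure(list(center_atom = as.integer(center_atom),
                 satellite_atoms = as.integer(satellite_atoms),
                 radius = radius, k_wall = k_wall),
            class = "flat_well_restraint")
}

#' Energy and forces of a flat-well restraint
#'
#' @param frame n x 3 coordinate matrix.
#' @param restraint A [flat_well_restraint()].
#' @return List with `energy` (kcal/mol) and `forces` (n x 3).
#' @export
flat_well_energy_force <- function(frame, restraint) {
  stopifnot(inherits(restraint, "flat_well_restraint"))
  cen <- restraint$center_atom
  if (cen > nrow(frame) || any(restraint$satellite_atoms > nrow(frame)))
    stopf("flat-well atom index exceeds frame size")
  energy <- 0
  forces <- matrix(0, nrow(frame), 3L)
  for (s in restraint$satellite_atoms) {
    delta <- frame[s, ] - frame[cen, ]
    d <- sqrt(sum(delta^2))
    if (d > restraint$radius) {
      excess <- d - restraint$radius
      energy <- energy + 0.5 * restraint$k_wall * excess^2
      fdir <- -restraint$k_wall * excess * delta / d
      forces[s, ] <- forces[s, ] + fdir
      forces[cen, ] <- forces[cen, ] - fdir
    }
  }
  list(energy = energy, forces = forces)
}
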