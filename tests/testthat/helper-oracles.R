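# Shared oracles and fixture builders. Everything is generated in code at
# test time; seeds are fixed so the suite is deterministic.

kB <- smdpmf::boltzmann_kcal

random_frame <- function(n_atoms, scale = 5) {
  matrix(stats::runif(n_atoms * 3, -scale, scale), n_atoms, 3)
}

# central finite-difference gradient of a scalar function of a frame
fd_gradient <- function(f, frame, h = 1e-6) {
  g <- matrix(0, nrow(frame), 3)
  for (a in seq_len(nrow(frame))) for (d in 1:3) {
    fp <- frame; fp[a, d] <- fp[a, d] + h
    fm <- frame; fm[a, d] <- fm[a, d] - h
    g[a, d] <- (f(fp) - f(fm)) / (2 * h)
  }
  g
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# literal frame-scan reference for sustained-crossing detection: walks the
# series one frame at a time, measuring each excursion beyond the +/-h band
# by explicit forward scan
brute_force_events <- function(values, times, min_dwell = 4L, h = 0.1) {
  n <- length(values)
  sgn <- function(x) if (x >= h) 1L else if (x <= -h) -1L else 0L
  side <- 0L; side_len <- 0L
  rows <- list()
  j <- 1L
  while (j <= n) {
    sj <- sgn(values[j])
    if (sj == 0L) { j <- j + 1L; next }
    len <- 0L
    while (j + len <= n && sgn(values[j + len]) == sj) len <- len + 1L
    sustained <- (len >= min_dwell) || (j + len - 1L == n)
    if (side != 0L && sj != side && sustained)
      rows[[length(rows) + 1L]] <- data.frame(
        crossing_time = times[j], frame = j,
        direction = if (sj == 1L) "forward" else "reverse",
        pre_dwell = side_len, post_dwell = len)
    if (sustained || side == 0L) { side <- sj; side_len <- len }
    j <- j + len
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(crossing_time = numeric(), frame = integer(),
               direction = character(), pre_dwell = integer(),
               post_dwell = integer())
}

# Scripted five-atom trajectories for pathway classification:
# 1 donor acid, 2 acid hydrogen, 3 water oxygen, 4 water hydrogen,
# 5 acceptor. A smooth switch moves a hydrogen between sites at t0.
scripted_trajectory <- function(scenario, n_frames = 201L, dt_frame = 0.5,
                                noise = 0.02, seed = 1234L) {
  set.seed(seed)
  times <- (seq_len(n_frames) - 1L) * dt_frame
  switch_fn <- function(t0, from, to)
    t(vapply(times, function(t) {
      s <- 1 / (1 + exp(-(t - t0) / 0.5))
      from + s * (to - from)
    }, numeric(3)))
  fixed <- function(p) matrix(p, n_frames, 3, byrow = TRUE)
  coords <- array(0, dim = c(n_frames, 5L, 3L))
  coords[, 1, ] <- fixed(c(0, 0, 0))      # donor acid
  coords[, 5, ] <- fixed(c(6, 0, 0))      # acceptor
  if (scenario == "water_mediated") {
    coords[, 3, ] <- fixed(c(3, 0, 0))    # water O between donor and acceptor
    coords[, 2, ] <- switch_fn(40, c(1, 0, 0), c(2.2, 0, 0))   # acid H -> water
    coords[, 4, ] <- switch_fn(42, c(3.8, 0.3, 0), c(5.1, 0, 0)) # water H -> acceptor
  } else if (scenario == "direct") {
    coords[, 3, ] <- fixed(c(1, 5, 0))    # water parked away from the path
    coords[, 2, ] <- switch_fn(50, c(1, 0, 0), c(5.2, 0, 0))   # acid H -> acceptor
    coords[, 4, ] <- fixed(c(1.6, 5.5, 0))
  } else { # "none": everything stays bonded
    coords[, 3, ] <- fixed(c(3, 0, 0))
    coords[, 2, ] <- fixed(c(1, 0, 0))
    coords[, 4, ] <- fixed(c(3.8, 0.3, 0))
  }
  coords <- coords + array(stats::rnorm(length(coords), 0, noise), dim(coords))
  structure(list(times = times, coords = coords,
                 sampling_interval = dt_frame),
            class = "trajectory")
}

transfer_roles <- list(donor = 1, donor_hydrogen = 2, water_oxygen = 3,
                       water_hydrogen = 4, acceptor = 5)

# small stiffness-switch ensemble used by several estimator tests
quick_switch_ensemble <- function(n_replicates = 30L, n_steps = 10000L,
                                  seed_base = 1L, snap_seed = 99L) {
  sys <- make_system("stiffness_switch")
  prot <- steering_protocol(sys, n_steps = n_steps,
                            n_replicates = n_replicates,
                            seed_base = seed_base)
  snaps <- generate_snapshots(sys, prot, run_steps = 20000L,
                              snapshot_interval = 500L, seed = snap_seed)
  run_ensemble(prot, snaps)
}
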