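test_that("transfer coordinate sign convention and LCOD equivalence", {
  # H bonded at 1.0 A to the donor, 2.5 A from the acceptor
  traj <- list(times = 0,
               coords = array(c(0, 1, 3.5, 0, 0, 0, 0, 0, 0),
                              dim = c(1, 3, 3)),
               sampling_interval = 1)
  s <- transfer_coordinate(traj, donor = 1, hydrogen = 2, acceptor = 3)
  expect_equal(s$values, -1.5)

  # symmetric midpoint geometry gives exactly zero
  trajm <- list(times = 0,
                coords = array(c(0, 1.75, 3.5, 0, 0.4, 0, 0, 0, 0),
                               dim = c(1, 3, 3)),
                sampling_interval = 1)
  expect_equal(transfer_coordinate(trajm, 1, 2, 3)$values, 0,
               tolerance = 1e-12)
  expect_error(transfer_coordinate(trajm, 1, 2, 9), "out of range")

  # frame-by-frame equality with eval_lcod on a steered three-atom run
  sys <- make_system("three_atom_transfer")
  run <- simulate_system(sys, n_steps = 2000L, seed = 5L,
                         sample_interval = 20L)
  s3 <- transfer_coordinate(run, 1, 2, 3)
  spec <- lcod_spec(rbind(c(1, 2), c(3, 2)), c(1, -1))
  manual <- vapply(seq_along(run$times), function(i)
    eval_lcod(run$coords[i, , ], spec), numeric(1))
  expect_equal(s3$values, manual, tolerance = 1e-12)
})

test_that("event detection finds sustained crossings only", {
  mk <- function(v) list(times = seq_along(v) - 1, values = v)
  # all-negative series: nothing
  expect_identical(nrow(detect_events(mk(rep(-1, 50)))), 0L)
  # single clean crossing persisting to the end
  v <- c(rep(-1, 20), seq(-1, 1, length.out = 5), rep(1, 20))
  ev <- detect_events(mk(v))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$direction, "forward")
  expect_equal(ev$frame, which(v >= 0.1)[1])
  # three transient recrossings plus one sustained crossing
  v2 <- c(rep(-1, 10), 1, rep(-1, 5), 1, -1, 1, rep(-1, 10), rep(1, 10),
          rep(-0.05, 3))
  ev2 <- detect_events(mk(v2), min_dwell_frames = 4)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$frame, which(seq_along(v2) > 28 & v2 >= 0.1)[1])
})

test_that("event detection matches the brute-force scan on random noisy series", {
  set.seed(91)
  for (rep in 1:1000) {
    n <- sample(20:120, 1)
    # random walk pushed through the band plus noise
    v <- cumsum(stats::rnorm(n, sd = 0.4)) + 0.6 * sin(seq_len(n) / 5)
    tm <- (seq_len(n) - 1) * 0.5
    dwell <- sample(2:6, 1)
    h <- stats::runif(1, 0.05, 0.5)
    got <- detect_events(list(times = tm, values = v), dwell, h)
    ref <- brute_force_events(v, tm, dwell, h)
    expect_identical(nrow(got), nrow(ref))
    if (nrow(got)) {
      expect_equal(got$crossing_time, ref$crossing_time)
      expect_identical(got$direction, ref$direction)
      expect_identical(got$pre_dwell, ref$pre_dwell)
      expect_identical(got$post_dwell, ref$post_dwell)
    }
  }
})

test_that("event detection is invariant to time shifts and prepended quiet frames", {
  set.seed(92)
  v <- c(rep(-0.8, 30), seq(-0.8, 0.9, length.out = 6), rep(0.9, 30)) +
    stats::rnorm(66, sd = 0.02)
  tm <- (seq_along(v) - 1) * 2.5
  e0 <- detect_events(list(times = tm, values = v))
  # uniform time translation
  e1 <- detect_events(list(times = tm + 1000, values = v))
  expect_equal(e1$crossing_time - 1000, e0$crossing_time)
  # frames prepended before the first crossing
  vpre <- c(rep(-0.8, 10), v)
  e2 <- detect_events(list(times = (seq_along(vpre) - 1) * 2.5,
                           values = vpre))
  expect_identical(nrow(e2), nrow(e0))
  expect_identical(e2$direction, e0$direction)
})

test_that("concomitance pairs events within the sampling window", {
  ev <- function(t) data.frame(crossing_time = t)
  # one sampling interval apart (2.5 ps) is concomitant
  p <- concomitance(ev(100.0), ev(102.5), window = 2.5)
  expect_true(p$concomitant)
  expect_false(concomitance(ev(100.0), ev(110.0), window = 2.5)$concomitant)
  expect_identical(nrow(concomitance(ev(100), ev(numeric(0)), 2.5)), 0L)
  expect_error(concomitance(ev(1), ev(2), window = 0), "> 0")
})

test_that("pathway classification separates the three scripted scenarios", {
  labels <- vapply(c("water_mediated", "direct", "none"), function(sc)
    classify_pathway(scripted_trajectory(sc), transfer_roles)$label,
    character(1))
  expect_identical(unname(labels),
                   c("water_mediated", "direct", "none"))

  wm <- classify_pathway(scripted_trajectory("water_mediated"),
                         transfer_roles, window = 2.5)
  expect_false(wm$ambiguous)
  # the two transfers land ~2 ps apart: concomitant at 2.5 ps resolution
  expect_true(any(wm$concomitance$concomitant))
  # provenance: acid H ends on the water, water H ends on the acceptor
  expect_identical(unname(wm$provenance["donor_hydrogen"]), "water_oxygen")
  expect_identical(unname(wm$provenance["water_hydrogen"]), "acceptor")

  dir <- classify_pathway(scripted_trajectory("direct"), transfer_roles)
  expect_identical(unname(dir$provenance["donor_hydrogen"]), "acceptor")

  # classification is deterministic
  wm2 <- classify_pathway(scripted_trajectory("water_mediated"),
                          transfer_roles)
  expect_identical(wm$label, wm2$label)
  expect_equal(wm$events_acid_water, wm2$events_acid_water)
  expect_error(classify_pathway(scripted_trajectory("none"),
                                list(donor = 1)), "roles")
})

test_that("unforced three-atom dynamics shows sustained transfer events", {
  sys <- make_system("three_atom_transfer")
  traj <- simulate_system(sys, n_steps = 5e5, seed = 2L,
                          sample_interval = 500L)
  s <- transfer_coordinate(traj, 1, 2, 3)
  ev <- detect_events(s)
  expect_gt(nrow(ev), 0)
  # directions alternate: every return must come back before going again
  if (nrow(ev) > 1)
    expect_true(all(ev$direction[-1] != ev$direction[-nrow(ev)]))
})
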