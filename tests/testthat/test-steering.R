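test_that("snapshot generation samples the restrained ensemble", {
  sys <- make_system("dragged_harmonic_trap", dt = 5e-5)
  prot <- steering_protocol(sys, n_steps = 1000L, k = 1000,
                            n_replicates = 5L, seed_base = 1L)
  # counting: floor(run_steps / interval)
  sn <- generate_snapshots(sys, prot, run_steps = 1000L,
                           snapshot_interval = 100L, seed = 3L)
  expect_length(sn, 10L)
  expect_error(generate_snapshots(sys, prot, run_steps = 50L,
                                  snapshot_interval = 100L),
               "insufficient snapshots")

  # stiff-spring Gaussian oracle: CV spread ~ sqrt(kT/k) around lambda0
  sn <- generate_snapshots(sys, prot, run_steps = 5e5,
                           snapshot_interval = 50L, seed = 5L)
  cv <- attr(sn, "cv")
  width <- sqrt(kT(300) / 1000)
  expect_gte(mean(abs(cv - 5) <= 3 * width), 0.99)
  expect_equal(stats::var(cv), kT(300) / 1000, tolerance = 0.2)
})

test_that("protocol validation rejects bad replicate setups", {
  sys <- make_system("dragged_harmonic_trap")
  expect_error(steering_protocol(sys, seeds = c(1L, 1L, 2L),
                                 n_replicates = 3L), "distinct")
  expect_error(steering_protocol(sys, k = 0), "> 0")
  expect_error(steering_protocol(sys, n_replicates = 0L), ">= 1")
  prot <- steering_protocol(sys, n_replicates = 3L, seed_base = 10L)
  expect_identical(prot$seeds, c(11L, 12L, 13L))
})

test_that("work vanishes identically for a static restraint target", {
  sys <- make_system("dragged_harmonic_trap")
  prot <- steering_protocol(sys, lambda0 = 5, lambda1 = 5, n_steps = 2000L,
                            n_replicates = 2L, seed_base = 1L)
  r <- run_replicate(sys$x0, prot, 42L)
  expect_true(all(r$work == 0))
  expect_equal(r$lambda, rep(5, length(r$lambda)))
})

test_that("replicate work starts at zero and ends at lambda1 exactly", {
  sys <- make_system("quartic_double_well")
  prot <- steering_protocol(sys, n_steps = 5000L, n_replicates = 3L,
                            seed_base = 2L, sample_interval = 100L)
  r <- run_replicate(sys$x0, prot, 9L)
  expect_identical(r$work[1], 0)
  expect_identical(r$lambda[length(r$lambda)], 5)
  expect_identical(r$lambda[1], 3)
})

test_that("quasi-static pulling converges to the analytic free energy", {
  sys <- make_system("stiffness_switch")
  dF <- exact_free_energy(sys)
  # slow pulling: mean work within 10% of dF = 1 kT
  prot <- steering_protocol(sys, n_steps = 40000L, n_replicates = 8L,
                            seed_base = 3L)
  snaps <- generate_snapshots(sys, prot, run_steps = 8000L,
                              snapshot_interval = 1000L, seed = 6L)
  ens <- run_ensemble(prot, snaps)
  w_end <- ens$works[nrow(ens$works), ]
  expect_equal(mean(w_end), dF, tolerance = 0.1)
})

test_that("ensembles are deterministic, dispersed, and second-law consistent", {
  ens <- quick_switch_ensemble(n_replicates = 10L, seed_base = 21L)
  ens2 <- quick_switch_ensemble(n_replicates = 10L, seed_base = 21L)
  expect_identical(ens$works, ens2$works)
  w_end <- ens$works[nrow(ens$works), ]
  expect_gt(stats::sd(w_end), 0)
  # mean final work >= dF within Monte-Carlo error
  dF <- exact_free_energy(make_system("stiffness_switch"))
  se <- stats::sd(w_end) / sqrt(length(w_end))
  expect_gte(mean(w_end), dF - 3 * se)
})

test_that("forward and reverse schedules satisfy the Crooks-consistency bound", {
  sys <- make_system("stiffness_switch")
  fwd <- steering_protocol(sys, n_steps = 4000L, n_replicates = 10L,
                           seed_base = 31L)
  rev <- steering_protocol(sys, lambda0 = sys$lambda1, lambda1 = sys$lambda0,
                           n_steps = 4000L, n_replicates = 10L,
                           seed_base = 61L)
  sf <- generate_snapshots(sys, fwd, run_steps = 10000L,
                           snapshot_interval = 1000L, seed = 1L)
  sr <- generate_snapshots(sys, rev, run_steps = 10000L,
                           snapshot_interval = 1000L, seed = 2L)
  ef <- run_ensemble(fwd, sf)
  er <- run_ensemble(rev, sr)
  wf <- ef$works[nrow(ef$works), ]
  wr <- er$works[nrow(er$works), ]
  se <- sqrt(stats::var(wf) / 10 + stats::var(wr) / 10)
  # <W_f> + <W_r> >= 0 (total dissipation of the cycle)
  expect_gte(mean(wf) + mean(wr), -3 * se)
})

test_that("diagnostics: stiff springs track, soft springs lag and jump", {
  # idealized perfect tracking: zero lag, slope one
  lam <- seq(1, 2, length.out = 50)
  ideal <- work_ensemble(lam, matrix(0, 50, 3),
                         achieved_cv = cbind(lam, lam, lam),
                         temperature = 300)
  d0 <- steering_diagnostics(ideal)
  expect_equal(d0$max_lag, rep(0, 3))
  expect_equal(d0$slope, rep(1, 3), tolerance = 1e-10)
  expect_false(any(d0$discontinuous))

  # stiff k on the double well: >= 95% of frames within 4 widths
  sys <- make_system("quartic_double_well")
  stiff <- steering_protocol(sys, n_steps = 50000L, n_replicates = 3L,
                             seed_base = 9L, sample_interval = 250L)
  sn <- generate_snapshots(sys, stiff, run_steps = 10000L,
                           snapshot_interval = 1000L, seed = 2L)
  ds <- steering_diagnostics(run_ensemble(stiff, sn))
  expect_true(all(ds$frac_within_4w >= 0.95))
  expect_false(any(ds$discontinuous))

  # deliberately soft k on a deep double well: catch-up jumps flagged
  deep <- make_system("quartic_double_well", V0 = 20)
  soft <- steering_protocol(deep, lambda0 = 3, lambda1 = 7,
                            n_steps = 100000L, dt = 2e-4, k = 50,
                            n_replicates = 5L, seed_base = 1L,
                            sample_interval = 2000L)
  snd <- generate_snapshots(deep, soft, run_steps = 10000L,
                            snapshot_interval = 1000L, seed = 1L)
  dd <- steering_diagnostics(run_ensemble(soft, snd))
  expect_true(any(dd$discontinuous))
  expect_true(all(dd$lagging))
})

test_that("work-ensemble invariants are enforced", {
  lam <- seq(0, 1, length.out = 11)
  W <- matrix(0, 11, 2)
  expect_s3_class(work_ensemble(lam, W, temperature = 300), "work_ensemble")
  Wbad <- W; Wbad[1, 2] <- 0.5
  expect_error(work_ensemble(lam, Wbad, temperature = 300), "W\\(lambda0\\)")
  expect_error(work_ensemble(c(0, 0.5, 0.2), matrix(0, 3, 2),
                             temperature = 300), "monotone")
  Wnf <- W; Wnf[5, 1] <- NaN
  expect_error(work_ensemble(lam, Wnf, temperature = 300), "non-finite")
})

test_that("work-ensemble files round-trip with their metadata", {
  ens <- quick_switch_ensemble(n_replicates = 4L, n_steps = 2000L,
                               seed_base = 41L)
  path <- tempfile(fileext = ".tsv")
  write_work_ensemble(ens, path)
  back <- read_work_ensemble(path)
  expect_equal(back$lambda_grid, ens$lambda_grid, tolerance = 1e-9)
  expect_equal(unname(back$works), unname(ens$works), tolerance = 1e-9)
  expect_identical(back$seeds, ens$seeds)
  expect_equal(back$temperature, 300)
})
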