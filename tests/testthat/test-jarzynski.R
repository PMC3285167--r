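# temperature at which kT = 1 kcal/mol, for closed-form checks
T_unit <- 1 / smdpmf::boltzmann_kcal

test_that("Jarzynski average: closed forms and validation", {
  # N = 1 identity: the estimate equals the single work function
  lam <- seq(0, 1, length.out = 5)
  W1 <- matrix(c(0, 0.5, 1.2, 0.7, 2.0), ncol = 1)
  ens1 <- work_ensemble(lam, W1, temperature = T_unit)
  expect_equal(jarzynski_average(ens1), as.numeric(W1))

  # identical replicates reproduce the common work
  ens3 <- work_ensemble(lam, cbind(W1, W1, W1), temperature = T_unit)
  expect_equal(jarzynski_average(ens3), as.numeric(W1))

  # works {0, ln 3} at kT = 1: -ln((1 + 1/3)/2) = ln(3/2)
  ens2 <- work_ensemble(c(0, 1), rbind(c(0, 0), c(0, log(3))),
                        temperature = T_unit)
  expect_equal(jarzynski_average(ens2)[2], log(3 / 2), tolerance = 1e-12)

  bad <- rbind(c(0, 0), c(1, Inf))
  expect_error(jarzynski_average(bad, temperature = T_unit), "non-finite")
})

test_that("log-sum-exp averaging is stable and agrees with naive at O(1) kT", {
  set.seed(61)
  W <- matrix(stats::rnorm(200, 1, 0.5), 10, 20)
  W[1, ] <- 0
  naive <- apply(W, 1, function(w) -log(mean(exp(-w))))
  expect_equal(jarzynski_average(W, temperature = T_unit), naive,
               tolerance = 1e-12)
  # |W| up to 1e4 kT must not overflow or underflow
  Wbig <- rbind(c(0, 0), c(9000, 10000))
  out <- jarzynski_average(Wbig, temperature = T_unit)
  expect_true(all(is.finite(out)))
  expect_equal(out[2], 9000 + log(2), tolerance = 1e-9)
})

test_that("Jensen bound and outlier damping hold on arbitrary ensembles", {
  set.seed(71)
  for (rep in 1:20) {
    N <- sample(2:40, 1)
    W <- matrix(stats::rnorm(8 * N, sd = 3), 8, N)
    W[1, ] <- 0
    fe <- jarzynski_average(W, temperature = T_unit)
    expect_true(all(fe <= rowMeans(W) + 1e-12))
    # adding a uniformly larger replicate raises the estimate by < ln((N+1)/N)
    W2 <- cbind(W, apply(W, 1, max) + 5)
    fe2 <- jarzynski_average(W2, temperature = T_unit)
    expect_true(all(fe2 - fe <= log((N + 1) / N) + 1e-12))
    expect_true(all(fe2 >= fe - 1e-12))
  }
})

test_that("bias correction vanishes without dissipation and for huge N", {
  lam <- c(0, 1)
  raw <- c(0, 0.8)
  # all works equal: W_dis = 0, correction exactly zero
  bc <- bias_correction(raw, mean_work = raw, n = 12, temperature = T_unit)
  expect_equal(bc$bias_corrected, raw)
  expect_equal(bc$correction, c(0, 0))
  expect_equal(bc$rmse_band, c(0, 0))
  # N = 1e6: correction below 1e-3 kT at moderate dissipation
  bc6 <- bias_correction(raw, raw + 2, n = 1e6, temperature = T_unit)
  expect_lt(max(abs(bc6$bias_corrected - raw)), 1e-3)
  expect_error(bias_correction(raw, raw, n = 1, temperature = T_unit),
               "insufficient replicates")
})

test_that("bias correction shrinks the estimator bias on Gaussian work (MC oracle)", {
  # fluctuation-dissipation consistent Gaussian works, true dF = 0:
  # mean = W_dis = 2 kT, variance = 2 * W_dis = 4 kT^2
  set.seed(81)
  M <- 2000L
  for (N in c(10L, 30L, 100L)) {
    W <- matrix(stats::rnorm(N * M, mean = 2, sd = 2), M, N)
    raw <- apply(W, 1, function(w) -log(mean(exp(-w))))
    bc <- bias_correction(raw, rowMeans(W), N, T_unit)
    expect_gt(mean(raw), 0)                      # raw JE bias is positive
    expect_lt(abs(mean(bc$bias_corrected)), abs(mean(raw)))
  }
})

test_that("PMF assembly recovers oracle free energies within its error band", {
  ens <- quick_switch_ensemble(n_replicates = 30L, seed_base = 1L)
  pmf <- pmf_from_ensemble(ens)
  n <- length(pmf$lambda_grid)
  expect_equal(pmf$raw_jarzynski[1], 0)
  expect_true(all(pmf$dissipated_work >= -1e-12))
  expect_true(all(pmf$rmse_band >= 0))
  dF <- exact_free_energy(make_system("stiffness_switch"))
  expect_equal(pmf$bias_corrected[n], dF, tolerance = 0.15)
})

test_that("barrier extraction handles interior maxima and monotone profiles", {
  mk <- function(vals) {
    p <- list(lambda_grid = seq_along(vals), bias_corrected = vals,
              raw_jarzynski = vals, rmse_band = rep(0, length(vals)),
              mean_work = vals, dissipated_work = rep(0, length(vals)),
              n_replicates = 2L, temperature = 300)
    class(p) <- "pmf_estimate"
    p
  }
  br <- barrier_heights(mk(c(0, 5, 2)))
  expect_equal(br$forward_barrier, 5)
  expect_equal(br$reverse_barrier, 3)
  expect_equal(br$barrier_position, 2)
  mono <- barrier_heights(mk(c(0, 1, 2)))
  expect_equal(mono$forward_barrier, 2)
  expect_equal(mono$reverse_barrier, 0)
})

test_that("raw Jarzynski bias is non-negative on an oracle system (MC)", {
  # repeated small ensembles on the dragged trap: E[dF_JE] >= dF_true = 0
  sys <- make_system("dragged_harmonic_trap")
  prot <- steering_protocol(sys, lambda0 = 5, lambda1 = 6, n_steps = 2000L,
                            n_replicates = 6L, seed_base = 101L,
                            sample_interval = 500L)
  sn <- generate_snapshots(sys, prot, run_steps = 20000L,
                           snapshot_interval = 500L, seed = 4L)
  ests <- vapply(0:9, function(b) {
    pr <- steering_protocol(sys, lambda0 = 5, lambda1 = 6, n_steps = 2000L,
                            n_replicates = 6L, seed_base = 200L + 10L * b,
                            sample_interval = 500L)
    ens <- run_ensemble(pr, sn)
    fe <- jarzynski_average(ens)
    fe[length(fe)]
  }, numeric(1))
  expect_gt(mean(ests), 0)
})
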