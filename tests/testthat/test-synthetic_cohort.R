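test_that("make_paradigm reproduces the default run structure", {
  p <- make_paradigm()
  task <- p$blocks[p$blocks$condition == "task", ]
  expect_equal(nrow(task), 8)
  expect_true(all(task$duration == 36))
  expect_equal(p$total_duration, 402)
  expect_equal(p$n_volumes, 201)
  # onsets are cumulative sums of the preceding durations
  expect_equal(p$blocks$onset,
               cumsum(c(0, p$blocks$duration[-nrow(p$blocks)])))
})

test_that("make_paradigm block arithmetic and validation", {
  # 2 stimuli of (2.5 + 0.5) s -> 6 s block
  p <- make_paradigm(n_task_blocks = 1, stimuli_per_block = 2)
  expect_equal(p$task_block_duration, 2 * (2.5 + 0.5))
  expect_error(make_paradigm(stimuli_per_block = 0), "stimuli_per_block")
  expect_error(make_paradigm(TR = 0), "positive")
  expect_error(make_paradigm(rest_block_duration = -1), "positive")
})

test_that("sample_state_sequence follows the chain and its seed", {
  expect_equal(sum(diff(sample_state_sequence(diag(4), 500, seed = 3)) != 0), 0)

  P <- matrix(1 / 4, 4, 4)
  s <- sample_state_sequence(P, 1e5, seed = 7)
  freq <- tabulate(s, 4) / length(s)
  expect_true(all(abs(freq - 0.25) < 0.01))

  expect_identical(sample_state_sequence(P, 100, seed = 11),
                   sample_state_sequence(P, 100, seed = 11))

  bad <- matrix(c(0.5, 0.5, 0.6, 0.5), 2, 2, byrow = TRUE)
  expect_error(sample_state_sequence(bad, 10, seed = 1), "sum to 1")
})

test_that("simulate_subject reproduces the planted covariance", {
  # single state, no task signal, no noise, long run
  sigma <- default_state_covariances()[[1]]
  gt <- make_ground_truth(n_states = 1, state_covariances = list(sigma),
                          transition_matrix = matrix(1, 1, 1),
                          task_amplitude = 0, noise_sd = 0)
  long <- make_paradigm(n_task_blocks = 1, final_rest_duration = 2e5)
  run <- simulate_subject(long, gt, subject_seed = 5, target_fd = 0)
  expect_gte(nrow(run$ts), 1e5)
  emp <- cor(run$ts)
  expect_lt(max(abs(emp - sigma)), 0.02)
  expect_true(all(run$motion == 0))
})

test_that("simulate_subject is deterministic and validates covariances", {
  p <- make_paradigm()
  gt <- make_ground_truth()
  a <- simulate_subject(p, gt, subject_seed = 9)
  b <- simulate_subject(p, gt, subject_seed = 9)
  expect_identical(a, b)

  sig <- diag(1, 14)
  sig[1, 2] <- sig[2, 1] <- 1.5  # not PD
  bad <- gt
  bad$state_covariances[[2]] <- sig
  expect_error(simulate_subject(p, bad, 1), "state 2")
})

test_that("motion traces hit the target mean FD", {
  m <- dfncstates:::simulate_motion(500, target_fd = 0.04, seed = 2)
  expect_equal(mean(framewise_displacement(m)[-1]), 0.04, tolerance = 1e-10)
})

test_that("simulate_voxel_mixture mixes linearly", {
  maps <- matrix(rnorm(3 * 50), 3, 50)
  tcs <- matrix(rnorm(30 * 3), 30, 3)
  clean <- simulate_voxel_mixture(maps, tcs, noise_sd = 0)
  expect_equal(dim(clean), c(50, 30))
  expect_lte(qr(clean)$rank, 3)

  one <- simulate_voxel_mixture(maps[1, , drop = FALSE],
                                matrix(2, 10, 1), noise_sd = 0)
  expect_equal(one, t(outer(rep(2, 10), maps[1, ])))

  # known mixture recoverable by least squares
  noisy <- simulate_voxel_mixture(maps, tcs, noise_sd = 0)
  rec <- t(qr.coef(qr(t(maps)), noisy))  # time x comps
  expect_equal(rec, tcs, tolerance = 1e-10)

  expect_error(simulate_voxel_mixture(maps, matrix(0, 5, 2)),
               "non-conformable")
})

test_that("simulate_behavior converges to the planted d-prime", {
  b0 <- simulate_behavior(0, n_trials = 1e6, seed = 4)
  expect_lt(abs(b0$d_prime), 0.01)
  b1 <- simulate_behavior(1.5, n_trials = 1e6, seed = 4)
  expect_lt(abs(b1$d_prime - 1.5), 0.02)
  expect_identical(simulate_behavior(1.5, 96, latent = 0.3, seed = 8),
                   simulate_behavior(1.5, 96, latent = 0.3, seed = 8))
  expect_error(simulate_behavior(1.5, 0), "n_trials")
  expect_error(simulate_behavior(Inf, 10), "finite")
})

test_that("the cohort is a pure function of config and seed", {
  cfg <- cohort_config(n_subjects = 3, timeseries = TRUE)
  a <- simulate_cohort(cfg, seed = 21)
  b <- simulate_cohort(cfg, seed = 21)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$runs, b$runs)
  c2 <- simulate_cohort(cfg, seed = 22)
  expect_false(identical(a$behavior$hits, c2$behavior$hits))
})

test_that("cohort files round-trip through the plain-text writers", {
  cfg <- cohort_config(n_subjects = 2)
  co <- simulate_cohort(cfg, seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "paradigm.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ts <- read_timeseries_tsv(file.path(dir, "sub01_task0back_timeseries.tsv"))
  expect_equal(dim(ts), dim(co$runs$sub01_task0back$ts))
  expect_equal(unname(ts), unname(co$runs$sub01_task0back$ts),
               tolerance = 1e-12, ignore_attr = TRUE)
  mo <- read_motion_txt(file.path(dir, "sub01_task0back_motion.txt"))
  expect_equal(mo, co$runs$sub01_task0back$motion, tolerance = 1e-6)
})
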