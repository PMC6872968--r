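# planted super-Gaussian spatial sources mixed into multi-subject data
make_ica_fixture <- function(n_sources = 3, n_voxels = 400, n_subjects = 5,
                             n_time = 60, noise_sd = 0, seed = 71) {
  with_seed_t(seed, {
    S <- matrix(rnorm(n_sources * n_voxels)^3, n_sources, n_voxels)
    subs <- lapply(seq_len(n_subjects), function(i) {
      A <- matrix(rnorm(n_time * n_sources), n_time, n_sources)
      Y <- t(simulate_voxel_mixture(S, A, noise_sd = 0))
      if (noise_sd > 0) Y <- Y + matrix(rnorm(length(Y), sd = noise_sd),
                                        nrow(Y), ncol(Y))
      list(Y = Y, A = A)
    })
    list(S = S, subs = subs)
  })
}

test_that("two-stage PCA is lossless at full rank and validates inputs", {
  fx <- make_ica_fixture(n_sources = 5, n_subjects = 3, seed = 72)
  data <- lapply(fx$subs, `[[`, "Y")
  red <- two_stage_pca(data, n1 = 5, n2 = 5)
  # rank-5 data, n1 = n2 = 5: stage-2 basis spans the data exactly
  Y1 <- sweep(data[[1]], 2, colMeans(data[[1]]))
  proj <- t(red$group) %*% solve(red$group %*% t(red$group)) %*% red$group
  expect_lt(max(abs(Y1 %*% proj - Y1)), 1e-8)
  expect_equal(red$explained, 1, tolerance = 1e-12)

  expect_error(two_stage_pca(data[1]), "2 subjects")
  expect_error(two_stage_pca(data, n1 = 5, n2 = 7), "n2 must")
  expect_error(two_stage_pca(lapply(data, function(y) y[1:4, ]),
                             n1 = 5, n2 = 5), "exceeds")
})

test_that("retained variance matches an eigendecomposition oracle", {
  fx <- make_ica_fixture(n_sources = 6, n_subjects = 4, noise_sd = 0.5,
                         seed = 73)
  data <- lapply(fx$subs, `[[`, "Y")
  n1 <- 8; n2 <- 4
  red <- two_stage_pca(data, n1 = n1, n2 = n2)
  # oracle: redo the two stages with base svd
  reduced <- lapply(data, function(Y) {
    Y <- sweep(Y, 2, colMeans(Y))
    sv <- svd(Y, nu = n1, nv = 0)
    crossprod(sv$u, Y)
  })
  G <- do.call(rbind, reduced)
  ev <- eigen(G %*% t(G), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(red$explained, sum(ev[seq_len(n2)]) / sum(ev),
               tolerance = 1e-8)
})

test_that("reconstruction error is non-increasing in n1", {
  fx <- make_ica_fixture(n_sources = 6, n_subjects = 3, noise_sd = 1,
                         seed = 74)
  data <- lapply(fx$subs, `[[`, "Y")
  recon_err <- function(n1) {
    red <- two_stage_pca(data, n1 = n1, n2 = 3)
    Y <- sweep(data[[1]], 2, colMeans(data[[1]]))
    U <- red$subject_proj[[1]]
    sum((Y - U %*% crossprod(U, Y))^2)
  }
  errs <- vapply(c(3, 6, 12, 24), recon_err, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("repeated-run ICA recovers planted sources with Iq near 1", {
  fx <- make_ica_fixture(seed = 75)
  red <- two_stage_pca(lapply(fx$subs, `[[`, "Y"), n1 = 10, n2 = 3)
  ica <- run_ica_stable(red, n_runs = 10, seed = 76)
  expect_true(all(ica$iq >= 0.95))
  match_r <- apply(abs(cor(t(ica$maps), t(fx$S))), 2, max)
  expect_true(all(match_r >= 0.99))

  # determinism under a fixed master seed
  ica2 <- run_ica_stable(red, n_runs = 10, seed = 76)
  expect_identical(ica$maps, ica2$maps)

  # single run: stability index undefined
  ica1 <- run_ica_stable(red, n_runs = 1, seed = 77)
  expect_true(all(is.na(ica1$iq)))
})

test_that("dual regression recovers subject maps and time courses", {
  fx <- make_ica_fixture(seed = 78)
  red <- two_stage_pca(lapply(fx$subs, `[[`, "Y"), n1 = 10, n2 = 3)
  ica <- run_ica_stable(red, n_runs = 5, seed = 79)
  br <- back_reconstruct(ica, fx$subs[[1]]$Y)
  r_maps <- apply(abs(cor(t(br$maps), t(fx$S))), 2, max)
  r_tc <- apply(abs(cor(br$timecourses, fx$subs[[1]]$A)), 2, max)
  expect_true(all(r_maps >= 0.99))
  expect_true(all(r_tc >= 0.99))
  # sign convention: peak-magnitude element positive
  peaks <- apply(br$maps, 1, function(v) v[which.max(abs(v))])
  expect_true(all(peaks > 0))

  # permuting voxels permutes subject maps identically
  perm <- with_seed_t(80, sample(ncol(fx$S)))
  ica_p <- ica
  ica_p$maps <- ica$maps[, perm]
  br_p <- back_reconstruct(ica_p, fx$subs[[1]]$Y[, perm])
  expect_equal(br_p$maps, br$maps[, perm], tolerance = 1e-8)

  expect_error(back_reconstruct(ica, fx$subs[[1]]$Y[, 1:10]), "voxels")
})

test_that("group maps back-reconstruct to themselves on group-identical data", {
  set.seed(81)
  maps <- matrix(rnorm(3 * 200), 3, 200)
  tc <- matrix(rnorm(50 * 3), 50, 3)
  Y <- tc %*% maps
  br <- back_reconstruct(maps, Y)
  r <- diag(abs(cor(t(br$maps), t(maps))))
  expect_true(all(r > 1 - 1e-10))
})

test_that("component selection applies spectral and mask criteria", {
  TR <- 2
  n <- 200
  tt <- (seq_len(n) - 1) * TR
  slow <- sin(2 * pi * 0.02 * tt)
  fast <- sin(2 * pi * 0.2 * tt)
  tcs <- list(cbind(slow, fast), cbind(slow + rnorm(n, sd = 0.01), fast))
  keep <- select_components(tcs, TR)
  expect_equal(keep, c(TRUE, FALSE))

  # spatial peak inside the exclusion mask rejects the component
  maps <- rbind(c(0.1, 0.2, 5, 0.1), c(4, 0.1, 0.2, 0.1))
  mask <- c(FALSE, FALSE, TRUE, FALSE)
  keep2 <- select_components(list(cbind(slow, slow)), TR, maps = maps,
                             exclusion_mask = mask, power_threshold = NULL)
  expect_equal(keep2, c(FALSE, TRUE))

  # no criteria configured: identity
  keep3 <- select_components(tcs, TR, power_threshold = NULL)
  expect_true(all(keep3))

  expect_warning(select_components(list(cbind(fast, fast)), TR), "every")
})
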