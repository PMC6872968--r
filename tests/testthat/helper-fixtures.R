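# Shared fixtures, all generated in code.

# seed scoping independent of the package's internal helper
with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Windows planted directly in edge space: per run, a Markov label sequence
# over the ground-truth states and Gaussian edge noise around the
# vectorized state correlation matrices. Used wherever the "well
# separated" premise (centroid separation >> within-state dispersion)
# must hold by construction.
make_planted_windows <- function(gt = make_ground_truth(), n_runs = 40,
                                 n_windows = 178, noise_sd = 0.02,
                                 seed = 1) {
  cents <- t(vapply(gt$state_covariances, vectorize_fnc,
                    numeric(choose(nrow(gt$state_covariances[[1]]), 2))))
  n_edges <- ncol(cents)
  X <- matrix(NA_real_, n_runs * n_windows, n_edges)
  lab <- integer(n_runs * n_windows)
  for (r in seq_len(n_runs)) {
    s <- sample_state_sequence(gt$transition_matrix, n_windows,
                               derive_seed_t(seed, r))
    idx <- ((r - 1) * n_windows + 1):(r * n_windows)
    X[idx, ] <- cents[s, , drop = FALSE] +
      with_seed_t(derive_seed_t(seed, r, "noise"),
                  matrix(rnorm(n_windows * n_edges, sd = noise_sd),
                         n_windows, n_edges))
    lab[idx] <- s
  }
  list(X = X, labels = lab, centroids = cents)
}

# test-side seed derivation, independent of the package internals
derive_seed_t <- function(...) {
  h <- 0
  for (ch in utf8ToInt(paste(vapply(list(...), as.character, character(1)),
                             collapse = "/"))) {
    h <- (h * 131 + ch) %% 2147483587
  }
  as.integer(h + 1L)
}

# two clearly separated Gaussian blobs in d dimensions
make_two_blobs <- function(n_per = 50, d = 10, sep = 20, seed = 1) {
  with_seed_t(seed, {
    X <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
    list(X = X, labels = rep(1:2, each = n_per))
  })
}

# tiny paradigm for fast end-to-end runs (still 201 volumes by default)
short_paradigm <- function() make_paradigm()
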