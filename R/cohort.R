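#' Default state-conditional correlation structure
#'
#' Four well-separated 14-component correlation matrices, one per hidden
#' connectivity state. Each state has a compound-symmetric block of
#' correlation `within_r` over its own "active" component set (a different
#' coalition of networks per state) and zero elsewhere, giving unit
#' diagonals, guaranteed positive definiteness (for `within_r < 1`), and
#' pairwise Manhattan separations of 18-29 in edge space at the default
#' `within_r = 0.6`.
#'
#' @param n_components number of components (>= 8).
#' @param within_r correlation inside the active set (0 < within_r < 1).
#' @return list of `n_states = 4` correlation matrices.
#' @export
default_state_covariances <- function(n_components = 14, within_r = 0.6) {
  if (n_components < 8) stop_config("need at least 8 components")
  if (within_r <= 0 || within_r >= 1) stop_config("within_r must be in (0, 1)")
  half <- floor(n_components / 2)
  q <- floor(n_components / 4)
  sets <- list(
    seq_len(half),
    seq(half + 1, n_components),
    c(seq_len(q + 1), seq(half + 1, half + q + 1)),
    c(seq(q + 2, half), seq(half + q + 2, n_components))
  )
  lapply(sets, function(s) {
    m <- diag(1, n_components)
    m[s, s] <- within_r
    diag(m) <- 1
    m
  })
}

#' Ground truth for the synthetic cohort
#'
#' Bundles everything the generator needs: the hidden state-conditional
#' covariances, the Markov transition matrix driving state switching at TR
#' resolution, the task signal amplitude, observation noise, and the
#' planted dwell-behavior coupling.
#'
#' @param n_states number of hidden states (must match the covariance
#'   list).
#' @param state_covariances list of symmetric positive-definite
#'   correlation matrices (unit diagonal), one per state.
#' @param transition_matrix row-stochastic n_states x n_states matrix;
#'   default: stay probability `0.96`, uniform otherwise (mean dwell of
#'   25 TRs = 50 s).
#' @param task_amplitude amplitude of the HRF-convolved task signal added
#'   to `task_components`.
#' @param task_components indices of components carrying the task signal.
#' @param noise_sd white observation noise standard deviation.
#' @param behavior_coupling target Pearson correlation between the
#'   fractional dwell time in `coupled_state` and behavioral d-prime.
#' @param coupled_state hidden state whose dwell time drives behavior.
#' @param seed integer master seed.
#' @return object of class `dfnc_ground_truth` (a validated list).
#' @export
make_ground_truth <- function(n_states = 4,
                              state_covariances = default_state_covariances(),
                              transition_matrix = NULL,
                              task_amplitude = 1,
                              task_components = 1:4,
                              noise_sd = 0.5,
                              behavior_coupling = 0.58,
                              coupled_state = 2,
                              seed = 1) {
  if (length(state_covariances) != n_states) {
    stop_config("state_covariances must have length n_states")
  }
  for (s in seq_len(n_states)) {
    m <- state_covariances[[s]]
    if (!isSymmetric(unname(m))) stop_config("state ", s, " covariance not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) {
      stop_config("state ", s, " covariance must have unit diagonal")
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop_config("state ", s, " covariance is not positive definite")
    }
  }
  if (is.null(transition_matrix)) {
    stay <- 0.96
    transition_matrix <- matrix((1 - stay) / (n_states - 1), n_states, n_states)
    diag(transition_matrix) <- stay
  }
  validate_transition_matrix(transition_matrix, n_states)
  if (abs(behavior_coupling) > 1) stop_config("|behavior_coupling| must be <= 1")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(n_states = n_states,
                 state_covariances = state_covariances,
                 transition_matrix = transition_matrix,
                 task_amplitude = task_amplitude,
                 task_components = task_components,
                 noise_sd = noise_sd,
                 behavior_coupling = behavior_coupling,
                 coupled_state = coupled_state,
                 seed = seed),
            class = "dfnc_ground_truth")
}

validate_transition_matrix <- function(P, k) {
  P <- as.matrix(P)
  if (nrow(P) != k || ncol(P) != k) stop_config("transition matrix must be ", k, " x ", k)
  if (any(P < 0)) stop_config("transition probabilities must be >= 0")
  if (max(abs(rowSums(P) - 1)) > 1e-8) {
    stop_config("transition matrix rows must sum to 1 (tol 1e-8)")
  }
  invisible(P)
}

#' Sample a hidden state sequence from a first-order Markov chain
#'
#' @param transition_matrix row-stochastic k x k matrix.
#' @param n_steps sequence length (>= 1).
#' @param seed integer seed.
#' @param init initial distribution (default uniform).
#' @return integer vector of states in 1..k.
#' @export
sample_state_sequence <- function(transition_matrix, n_steps, seed,
                                  init = NULL) {
  k <- nrow(as.matrix(transition_matrix))
  validate_transition_matrix(transition_matrix, k)
  if (n_steps < 1) stop_config("n_steps must be >= 1")
  init <- init %||% rep(1 / k, k)
  with_seed(seed, {
    s <- integer(n_steps)
    s[1] <- sample.int(k, 1, prob = init)
    if (n_steps > 1) {
      for (t in 2:n_steps) {
        s[t] <- sample.int(k, 1, prob = transition_matrix[s[t - 1], ])
      }
    }
    s
  })
}

# AR(1)-smoothed random-walk realignment parameters rescaled so that the
# mean framewise displacement equals target_fd. Translations in mm,
# rotations in radians (scaled down by the 50 mm lever arm).
simulate_motion <- function(n_volumes, target_fd = 0.04, seed = 1,
                            ar = 0.6, radius = 50) {
  if (target_fd < 0) stop_config("target_fd must be >= 0")
  if (target_fd == 0) return(matrix(0, n_volumes, 6))
  with_seed(seed, {
    inc <- matrix(rnorm(n_volumes * 6), n_volumes, 6)
    for (j in 1:6) {
      for (t in 2:n_volumes) inc[t, j] <- ar * inc[t - 1, j] + inc[t, j]
    }
    inc[, 4:6] <- inc[, 4:6] / radius
    inc[1, ] <- 0
    motion <- apply(inc, 2, cumsum)
    fd <- framewise_displacement(motion, radius = radius)
    scale <- target_fd / mean(fd[-1])
    motion * scale
  })
}

#' Simulate one subject's run
#'
#' The component time series is a state-conditional multivariate Gaussian:
#' at each TR the sample is drawn with the correlation matrix of the
#' current hidden state (switching follows the ground-truth Markov chain),
#' plus an HRF-convolved task boxcar of amplitude `task_amplitude` on the
#' designated components, plus white noise. Motion is an AR(1)-smoothed
#' random walk rescaled to the target mean framewise displacement.
#'
#' @param paradigm a [make_paradigm()] object.
#' @param ground_truth a [make_ground_truth()] object.
#' @param subject_seed integer seed for this run.
#' @param target_fd target mean FD in mm.
#' @return list with `ts` (volumes x components, class-tagged with TR),
#'   `motion` (volumes x 6), `states` (true label per TR).
#' @export
simulate_subject <- function(paradigm, ground_truth, subject_seed,
                             target_fd = 0.04) {
  stopifnot(inherits(paradigm, "dfnc_paradigm"),
            inherits(ground_truth, "dfnc_ground_truth"))
  gt <- ground_truth
  n_vol <- paradigm$n_volumes
  p <- nrow(gt$state_covariances[[1]])
  chols <- lapply(seq_len(gt$n_states), function(s) {
    ch <- tryCatch(chol(gt$state_covariances[[s]]),
                   error = function(e) stop("state ", s,
                     " covariance failed Cholesky decomposition: ",
                     conditionMessage(e), call. = FALSE))
    ch
  })
  states <- sample_state_sequence(gt$transition_matrix, n_vol,
                                  derive_seed(subject_seed, "states"))
  Z <- with_seed(derive_seed(subject_seed, "signal"),
                 matrix(rnorm(n_vol * p), n_vol, p))
  ts <- matrix(0, n_vol, p)
  for (s in seq_len(gt$n_states)) {
    rows <- states == s
    if (any(rows)) ts[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
  }
  if (gt$task_amplitude != 0) {
    reg <- hrf_convolve(paradigm_boxcar(paradigm, n_vol),
                        canonical_hrf(paradigm$TR))
    ts[, gt$task_components] <- ts[, gt$task_components] +
      gt$task_amplitude * reg
  }
  if (gt$noise_sd > 0) {
    ts <- ts + with_seed(derive_seed(subject_seed, "noise"),
                         matrix(rnorm(n_vol * p, sd = gt$noise_sd), n_vol, p))
  }
  colnames(ts) <- sprintf("comp_%02d", seq_len(p))
  motion <- simulate_motion(n_vol, target_fd,
                            seed = derive_seed(subject_seed, "motion"))
  attr(ts, "TR") <- paradigm$TR
  list(ts = ts, motion = motion, states = states)
}

#' Simulate hit/false-alarm counts under the equal-variance model
#'
#' Each subject's sensitivity is `d_prime_true + latent_scale * latent`;
#' with a neutral criterion the hit rate is `pnorm(d/2)` and the
#' false-alarm rate `pnorm(-d/2)`. Counts are binomial draws; on large
#' trial counts the estimated d-prime converges to the planted value.
#'
#' @param d_prime_true baseline sensitivity.
#' @param n_trials total trials per subject; a fraction `signal_fraction`
#'   are signal (target) trials, the rest noise trials.
#' @param latent per-subject standard-normal latent injected into
#'   sensitivity (scalar or vector; drives dwell-behavior coupling).
#' @param latent_scale size of the latent effect in d-prime units.
#' @param seed integer seed.
#' @param signal_fraction fraction of trials that are targets.
#' @return data.frame (one row per latent element): n_signal, n_noise,
#'   hits, false_alarms, d_prime (estimated via [dprime()]).
#' @export
simulate_behavior <- function(d_prime_true, n_trials, latent = 0,
                              latent_scale = 0.5, seed = 1,
                              signal_fraction = 1 / 3) {
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  if (!is.finite(d_prime_true)) stop_config("d_prime_true must be finite")
  n_signal <- max(1L, round(n_trials * signal_fraction))
  n_noise <- max(1L, n_trials - n_signal)
  d_true <- d_prime_true + latent_scale * latent
  with_seed(seed, {
    hits <- rbinom(length(d_true), n_signal, pnorm(d_true / 2))
    fas <- rbinom(length(d_true), n_noise, pnorm(-d_true / 2))
    data.frame(n_signal = n_signal, n_noise = n_noise,
               hits = hits, false_alarms = fas,
               d_prime = dprime(hits, n_signal, fas, n_noise))
  })
}

# Delta-method standard deviation of the estimated d-prime around the
# true value d0 given the trial counts (binomial sampling noise).
dprime_sampling_sd <- function(d0, n_signal, n_noise) {
  ph <- pnorm(d0 / 2)
  pf <- pnorm(-d0 / 2)
  v <- ph * (1 - ph) / (n_signal * stats::dnorm(qnorm(ph))^2) +
    pf * (1 - pf) / (n_noise * stats::dnorm(qnorm(pf))^2)
  sqrt(v)
}

#' Default cohort configuration
#'
#' The stated world the generator emulates: 20 subjects, two auditory
#' tasks (0-back discrimination and 2-back working memory), TR = 2 s,
#' 201 acquired volumes per run (197 after the 4-volume drop), 14
#' components, 4 hidden states, mean FD around 0.04 mm, 96 behavioral
#' trials per run, and a dwell-behavior coupling of 0.58.
#'
#' @param ... overrides for any field.
#' @return named list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_subjects = 20,
    tasks = c("task0back", "task2back"),
    d_prime_true = c(task0back = 2.5, task2back = 1.5),
    n_trials = 96,
    latent_scale = 0.5,
    fd_mean = 0.04,
    fd_sd = 0.01,
    n_drop = 4,
    timeseries = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate a complete multi-subject two-task cohort
#'
#' Runs [simulate_subject()] for every subject x task, then plants the
#' dwell-behavior coupling: each run's fractional dwell time in the
#' coupled state (from the true TR-level state sequence) is standardized
#' within task and mixed with independent noise into the latent that
#' shifts behavioral sensitivity. The mixing weight is inflated
#' analytically for the binomial sampling noise of the d-prime estimate
#' (delta method), so the realized dwell/d-prime correlation targets
#' `behavior_coupling` in expectation. The whole cohort is a pure
#' function of `(config, ground_truth, seed)`.
#'
#' @param config a [cohort_config()] list. Set `timeseries = FALSE` to
#'   skip the (expensive) component time series and motion traces while
#'   keeping state sequences, FD summaries, and behavior.
#' @param paradigm a [make_paradigm()] object.
#' @param ground_truth a [make_ground_truth()] object.
#' @param seed integer master seed.
#' @return object of class `dfnc_cohort`: list with `runs` (named list of
#'   [simulate_subject()] outputs or state sequences), `behavior`
#'   (data.frame: subject, task, counts, d_prime, dwell_true, mean_fd),
#'   `paradigm`, `ground_truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            paradigm = make_paradigm(),
                            ground_truth = make_ground_truth(),
                            seed = 1) {
  gt <- ground_truth
  runs <- list()
  beh_rows <- list()
  for (task_i in seq_along(config$tasks)) {
    task <- config$tasks[task_i]
    dwell <- numeric(config$n_subjects)
    fd_obs <- numeric(config$n_subjects)
    for (subj in seq_len(config$n_subjects)) {
      sseed <- derive_seed(seed, "subject", subj, task)
      target_fd <- with_seed(derive_seed(sseed, "fdtarget"),
                             max(0.005, rnorm(1, config$fd_mean, config$fd_sd)))
      if (isTRUE(config$timeseries)) {
        run <- simulate_subject(paradigm, gt, sseed, target_fd = target_fd)
        fd_obs[subj] <- mean(framewise_displacement(run$motion)[-1])
        runs[[sprintf("sub%02d_%s", subj, task)]] <- run
      } else {
        states <- sample_state_sequence(gt$transition_matrix,
                                        paradigm$n_volumes,
                                        derive_seed(sseed, "states"))
        fd_obs[subj] <- target_fd
        runs[[sprintf("sub%02d_%s", subj, task)]] <- list(states = states)
      }
      dwell[subj] <- mean(runs[[sprintf("sub%02d_%s", subj, task)]]$states ==
                            gt$coupled_state)
    }
    # coupling: latent = a * standardized dwell + sqrt(1 - a^2) * noise,
    # with `a` inflated for d-prime estimation noise so the realized
    # dwell / estimated-d' correlation matches behavior_coupling
    z <- as.numeric(scale(dwell))
    d0 <- config$d_prime_true[[task]]
    n_signal <- max(1L, round(config$n_trials / 3))
    sig_n <- dprime_sampling_sd(d0, n_signal, config$n_trials - n_signal)
    tau <- config$latent_scale
    a <- gt$behavior_coupling * sqrt(tau^2 + sig_n^2) / tau
    a <- max(-1, min(1, a))
    eps <- with_seed(derive_seed(seed, "latentnoise", task),
                     rnorm(config$n_subjects))
    latent <- a * z + sqrt(1 - a^2) * eps
    beh <- simulate_behavior(d0, config$n_trials, latent = latent,
                             latent_scale = tau,
                             seed = derive_seed(seed, "behavior", task))
    beh_rows[[task]] <- cbind(
      data.frame(subject = sprintf("sub%02d", seq_len(config$n_subjects)),
                 task = task, stringsAsFactors = FALSE),
      beh,
      data.frame(dwell_true = dwell, mean_fd = fd_obs))
  }
  structure(list(runs = runs,
                 behavior = do.call(rbind, c(beh_rows, make.row.names = FALSE)),
                 paradigm = paradigm, ground_truth = gt,
                 config = config, seed = seed),
            class = "dfnc_cohort")
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_subjects, "subjects x",
      length(x$config$tasks), "tasks,", x$paradigm$n_volumes,
      "volumes/run, seed", x$seed, "\n")
  invisible(x)
}

#' Write a cohort to disk in plain-text formats
#'
#' Per run: `<run>_timeseries.tsv` (rows = TRs, columns = components),
#' `<run>_motion.txt` (6-column whitespace realignment dialect), and
#' `<run>_states.tsv`. Cohort level: `paradigm.tsv`, `behavior.tsv`, and
#' `ground_truth.json`.
#'
#' @param cohort a [simulate_cohort()] object (with time series).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$runs)) {
    run <- cohort$runs[[nm]]
    if (!is.null(run$ts)) {
      write.table(as.data.frame(run$ts),
                  file.path(dir, paste0(nm, "_timeseries.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(format(run$motion, digits = 8),
                  file.path(dir, paste0(nm, "_motion.txt")),
                  sep = "  ", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    write.table(data.frame(volume = seq_along(run$states),
                           state = run$states),
                file.path(dir, paste0(nm, "_states.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_paradigm_tsv(cohort$paradigm, file.path(dir, "paradigm.tsv"))
  write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(n_states = gt$n_states,
         transition_matrix = gt$transition_matrix,
         state_covariances = gt$state_covariances,
         task_amplitude = gt$task_amplitude,
         task_components = gt$task_components,
         noise_sd = gt$noise_sd,
         behavior_coupling = gt$behavior_coupling,
         coupled_state = gt$coupled_state,
         seed = cohort$seed),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a per-run time-series TSV written by [write_cohort()]
#' @param path TSV path (rows = TRs, header = component names).
#' @param TR repetition time recorded on the returned matrix.
#' @return volumes x components numeric matrix with a `TR` attribute.
#' @export
read_timeseries_tsv <- function(path, TR = 2) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  attr(m, "TR") <- TR
  m
}

#' Read a 6-column realignment-parameter text file
#' @param path whitespace-delimited file with 6 columns.
#' @return volumes x 6 numeric matrix.
#' @export
read_motion_txt <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 6) stop("expected 6 motion columns, got ", ncol(m),
                         call. = FALSE)
  unname(m)
}
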