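#' Mix spatial sources into voxel data
#'
#' Linear mixing fixture for the group decomposition: returns
#' `t(spatial_maps) %*% t(timeseries)` (voxels x time) plus i.i.d.
#' Gaussian noise.
#'
#' @param spatial_maps components x voxels matrix.
#' @param component_ts time x components matrix.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed (used when `noise_sd > 0`).
#' @return voxels x time matrix.
#' @export
simulate_voxel_mixture <- function(spatial_maps, component_ts, noise_sd = 0,
                                   seed = 1) {
  spatial_maps <- as.matrix(spatial_maps)
  component_ts <- as.matrix(component_ts)
  if (ncol(component_ts) != nrow(spatial_maps)) {
    stop("non-conformable: ", ncol(component_ts), " time-series components vs ",
         nrow(spatial_maps), " maps", call. = FALSE)
  }
  out <- t(spatial_maps) %*% t(component_ts)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, matrix(rnorm(length(out), sd = noise_sd),
                                        nrow(out), ncol(out)))
  }
  out
}

#' Two-stage PCA reduction for group ICA
#'
#' Stage 1 reduces each subject's (time x voxels) data to its top `n1`
#' principal temporal components; stage 2 concatenates the reduced data
#' along the time dimension and keeps the top `n2` group components. The
#' stored projections allow reconstruction checks and seeding of the group
#' ICA.
#'
#' @param data_list list of time x voxels matrices, one per subject (>= 2
#'   subjects; each with >= n1 time points).
#' @param n1 per-subject reduction order.
#' @param n2 group reduction order (<= n1).
#' @return object of class `dfnc_pca2`: list with `group` (n2 x voxels),
#'   `subject_proj` (list of time x n1 bases), `group_proj`
#'   ((n_subjects*n1) x n2 basis), `group_values` (stage-2 eigenvalues),
#'   `explained` (fraction of stage-2 variance kept), `n1`, `n2`.
#' @export
two_stage_pca <- function(data_list, n1 = 27, n2 = 18) {
  if (!is.list(data_list) || length(data_list) < 2) {
    stop_config("need at least 2 subjects")
  }
  if (n2 > n1) stop_config("n2 must be <= n1")
  reduced <- vector("list", length(data_list))
  subject_proj <- vector("list", length(data_list))
  for (i in seq_along(data_list)) {
    Y <- as.matrix(data_list[[i]])
    Y <- sweep(Y, 2, colMeans(Y))  # voxelwise demean over time
    if (min(dim(Y)) < n1) {
      stop_config("subject ", i, ": n1 = ", n1,
                  " exceeds data rank bound ", min(dim(Y)))
    }
    sv <- svd(Y, nu = n1, nv = 0)
    subject_proj[[i]] <- sv$u
    reduced[[i]] <- crossprod(sv$u, Y)   # n1 x voxels
  }
  G <- do.call(rbind, reduced)
  sv2 <- svd(G, nu = n2, nv = 0)
  group <- crossprod(sv2$u, G)           # n2 x voxels
  ev <- sv2$d^2
  structure(list(group = group, subject_proj = subject_proj,
                 group_proj = sv2$u, group_values = ev,
                 explained = sum(ev[seq_len(n2)]) / sum(ev),
                 n1 = n1, n2 = n2),
            class = "dfnc_pca2")
}

# Symmetric fixed-point ICA (logcosh negentropy contrast) on the rows of
# X (mixtures x samples). Returns unit-variance source estimates S
# (components x samples) and the unmixing applied to X.
fastica_core <- function(X, n_comp, max_iter = 500, tol = 1e-7) {
  n <- nrow(X)
  X <- sweep(X, 1, rowMeans(X))
  cv <- X %*% t(X) / ncol(X)
  e <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- diag(1 / sqrt(e$values[keep]), n_comp) %*% t(e$vectors[, keep])
  Z <- K %*% X
  W <- matrix(rnorm(n_comp * n_comp), n_comp)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      return(list(S = W %*% Z, W = W %*% K, converged = TRUE, iters = it))
    }
  }
  list(S = W %*% Z, W = W %*% K, converged = FALSE, iters = max_iter)
}

#' Repeated-run ICA with a stability index
#'
#' Runs fixed-point ICA `n_runs` times from different random
#' initializations on the group-reduced data, clusters the pooled source
#' estimates greedily by absolute correlation (one estimate per run per
#' cluster), and returns each cluster's centrotype (the estimate with the
#' highest total intra-cluster similarity). The stability index Iq of a
#' cluster is its mean intra-cluster minus mean extra-cluster absolute
#' correlation; values near 1 mean the component is found reliably in
#' every run.
#'
#' @param reduction a [two_stage_pca()] object (or an n2 x samples
#'   matrix).
#' @param n_runs number of ICA runs (Iq is `NA` when `n_runs = 1`).
#' @param seed integer master seed.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `dfnc_ica`: list with `maps` (components x
#'   samples, unit-norm rows, sign set so the peak-magnitude element is
#'   positive), `iq` (length n2), `n_runs`, `runs_converged`.
#' @export
run_ica_stable <- function(reduction, n_runs = 10, seed = 1,
                           max_iter = 500, tol = 1e-7) {
  X <- if (inherits(reduction, "dfnc_pca2")) reduction$group else
    as.matrix(reduction)
  n_comp <- nrow(X)
  runs <- vector("list", n_runs)
  conv <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- NULL
    for (attempt in 1:3) {
      fit <- with_seed(derive_seed(seed, "ica", r, attempt),
                       fastica_core(X, n_comp, max_iter, tol))
      if (fit$converged) break
      message("ICA run ", r, " attempt ", attempt, " did not converge; ",
              if (attempt < 3) "retrying with a new seed" else "keeping last")
    }
    runs[[r]] <- fit$S
    conv[r] <- fit$converged
  }
  if (!any(conv)) stop("all ICA runs failed to converge", call. = FALSE)
  est <- do.call(rbind, runs)                  # (n_runs*n_comp) x samples
  run_id <- rep(seq_len(n_runs), each = n_comp)
  sim <- abs(cor(t(est)))                      # |r| between all estimates
  diag(sim) <- 0
  assigned <- rep(FALSE, nrow(est))
  clusters <- vector("list", n_comp)
  for (c in seq_len(n_comp)) {
    # seed the cluster with the unassigned estimate best matched across runs
    score <- vapply(seq_len(nrow(est)), function(i) {
      if (assigned[i]) return(-Inf)
      o <- sim[i, ]
      o[assigned] <- 0
      sum(vapply(split(o, run_id), max, numeric(1)))
    }, numeric(1))
    anchor <- which.max(score)
    members <- anchor
    for (r in setdiff(seq_len(n_runs), run_id[anchor])) {
      cand <- which(run_id == r & !assigned)
      if (length(cand)) members <- c(members, cand[which.max(sim[anchor, cand])])
    }
    assigned[members] <- TRUE
    clusters[[c]] <- members
  }
  maps <- matrix(NA_real_, n_comp, ncol(est))
  iq <- rep(NA_real_, n_comp)
  for (c in seq_len(n_comp)) {
    m <- clusters[[c]]
    if (length(m) > 1) {
      intra <- sim[m, m, drop = FALSE]
      centro <- m[which.max(rowSums(intra))]
      others <- setdiff(seq_len(nrow(est)), m)
      iq[c] <- mean(intra[upper.tri(intra)]) - mean(sim[m, others])
    } else {
      centro <- m
    }
    v <- est[centro, ]
    v <- v * sign(v[which.max(abs(v))])
    maps[c, ] <- v / sqrt(sum(v^2))
  }
  if (n_runs == 1) iq[] <- NA_real_
  structure(list(maps = maps, iq = iq, n_runs = n_runs,
                 runs_converged = conv),
            class = "dfnc_ica")
}

#' @export
print.dfnc_ica <- function(x, ...) {
  cat("Group ICA:", nrow(x$maps), "components,", x$n_runs, "runs; Iq:",
      paste(format(x$iq, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Back-reconstruct subject maps and time courses (dual regression)
#'
#' Stage 1 regresses the group spatial maps onto a subject's data to get
#' subject time courses; stage 2 regresses those time courses onto the
#' data to get subject spatial maps. Map signs follow the convention that
#' the peak-magnitude element is positive (time courses flipped to match).
#'
#' @param ica a [run_ica_stable()] object (or components x voxels matrix).
#' @param data time x voxels matrix for one subject.
#' @return list with `timecourses` (time x components) and `maps`
#'   (components x voxels).
#' @export
back_reconstruct <- function(ica, data) {
  S <- if (inherits(ica, "dfnc_ica")) ica$maps else as.matrix(ica)
  data <- as.matrix(data)
  if (ncol(data) != ncol(S)) {
    stop("data has ", ncol(data), " voxels but maps have ", ncol(S),
         call. = FALSE)
  }
  data <- sweep(data, 2, colMeans(data))
  tc <- t(qr.coef(qr(t(S)), t(data)))        # time x components
  maps <- qr.coef(qr(tc), data)              # components x voxels
  for (c in seq_len(nrow(maps))) {
    s <- sign(maps[c, which.max(abs(maps[c, ]))])
    if (s < 0) {
      maps[c, ] <- -maps[c, ]
      tc[, c] <- -tc[, c]
    }
  }
  list(timecourses = tc, maps = maps)
}

#' Select components by low-frequency power and exclusion peaks
#'
#' Keeps components whose subject-averaged fraction of spectral power
#' below `freq_cutoff` is at least `power_threshold`, and whose group map
#' peak does not fall inside an exclusion mask (white matter, ventricles,
#' ... when available). With no criteria configured every component is
#' retained.
#'
#' @param timecourse_list list (one per subject) of time x components
#'   matrices.
#' @param TR repetition time in seconds.
#' @param maps optional components x voxels group maps (for the mask
#'   criterion).
#' @param exclusion_mask optional logical vector over voxels; components
#'   peaking inside it are rejected.
#' @param power_threshold minimum low-frequency power fraction (NULL
#'   disables the spectral criterion).
#' @param freq_cutoff Hz boundary for "low frequency".
#' @return logical selection mask over components (TRUE = keep).
#' @export
select_components <- function(timecourse_list, TR, maps = NULL,
                              exclusion_mask = NULL, power_threshold = 0.5,
                              freq_cutoff = 0.1) {
  n_comp <- ncol(timecourse_list[[1]])
  keep <- rep(TRUE, n_comp)
  if (!is.null(power_threshold)) {
    if (power_threshold < 0 || power_threshold > 1) {
      stop_config("power_threshold must be in [0, 1]")
    }
    frac <- sapply(timecourse_list, function(tc) {
      tc <- sweep(as.matrix(tc), 2, colMeans(tc))
      n <- nrow(tc)
      freqs <- (seq_len(n) - 1) / (n * TR)
      pos <- freqs > 0 & freqs <= 1 / (2 * TR)
      pw <- abs(mvfft(tc))^2
      colSums(pw[pos & freqs <= freq_cutoff, , drop = FALSE]) /
        colSums(pw[pos, , drop = FALSE])
    })
    keep <- keep & rowMeans(as.matrix(frac)) >= power_threshold
  }
  if (!is.null(exclusion_mask) && !is.null(maps)) {
    peaks <- apply(abs(as.matrix(maps)), 1, which.max)
    keep <- keep & !exclusion_mask[peaks]
  }
  if (!any(keep)) warning("selection rejected every component")
  unname(keep)
}
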