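#' L1 (Manhattan) k-means clustering of windowed connectivity
#'
#' City-block k-means (k-medians): windows are assigned to the centroid at
#' minimum Manhattan distance and centroids are updated as element-wise
#' medians. The best of `n_replicates` runs (k-means++-style seeding under
#' L1, distinct sub-seeds) by total within-cluster L1 objective is kept.
#' Cluster labels are made canonical by sorting clusters on descending
#' pooled occupancy, so state 1 is always the most visited state.
#'
#' @param X windows x edges numeric matrix.
#' @param k number of clusters (1 <= k <= nrow(X)).
#' @param max_iter maximum Lloyd iterations per replicate.
#' @param n_replicates restarts; best objective kept.
#' @param seed integer seed controlling all replicates.
#' @return object of class `dfnc_kmeans`: list with `k`, `centroids`
#'   (k x edges), `labels` (length nrow(X)), `objective`, `trace`
#'   (objective per iteration of the winning replicate), `sizes`.
#' @export
kmeans_l1 <- function(X, k, max_iter = 150, n_replicates = 20, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k != round(k)) stop_config("k must be a positive integer")
  if (k > n) stop_config("k = ", k, " exceeds the number of rows (", n, ")")
  best <- NULL
  for (r in seq_len(n_replicates)) {
    C0 <- with_seed(derive_seed(seed, "kmeanspp", r), kmeanspp_l1(X, k))
    fit <- .kmedians_lloyd(X, C0, as.integer(max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  # canonical state order: descending pooled dwell (occupancy), ties by
  # original index
  sizes <- tabulate(best$labels, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  structure(list(k = k,
                 centroids = best$centroids[ord, , drop = FALSE],
                 labels = remap[best$labels],
                 objective = best$objective,
                 trace = best$trace,
                 sizes = sizes[ord],
                 dimnames_edges = colnames(X)),
            class = "dfnc_kmeans")
}

# k-means++-style seeding under the L1 metric: first centroid uniform,
# subsequent centroids sampled with probability proportional to the L1
# distance to the nearest centroid chosen so far (compiled scan).
kmeanspp_l1 <- function(X, k) {
  n <- nrow(X)
  first <- sample.int(n, 1)
  u <- if (k > 1) runif(k - 1) else numeric(0)
  idx <- .kmeanspp_l1_idx(X, as.integer(k), as.integer(first), u)
  X[idx, , drop = FALSE]
}

#' @export
print.dfnc_kmeans <- function(x, ...) {
  cat("L1 k-means:", x$k, "states,", length(x$labels), "windows, objective",
      format(x$objective, digits = 6), "\n")
  cat("state sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster validity curve over a range of k
#'
#' For each k, fits [kmeans_l1()] and records the ratio of the mean
#' within-cluster L1 distance (windows to own centroid) to the mean
#' pairwise L1 distance among centroids. The curve typically drops steeply
#' until k reaches the number of genuine states and flattens after.
#'
#' @param X windows x edges matrix.
#' @param k_range candidate k values (consecutive integers).
#' @param max_iter,n_replicates,seed passed to [kmeans_l1()].
#' @return named numeric vector of ratios, names = k.
#' @export
validity_curve <- function(X, k_range = 2:10, max_iter = 150,
                           n_replicates = 20, seed = 1) {
  X <- as.matrix(X)
  if (max(k_range) > nrow(X)) stop_config("max k exceeds number of rows")
  out <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmeans_l1(X, k, max_iter = max_iter, n_replicates = n_replicates,
                     seed = derive_seed(seed, "validity", k))
    within <- fit$objective / nrow(X)
    if (k == 1) {
      out[i] <- NA_real_
      next
    }
    D <- as.matrix(stats::dist(fit$centroids, method = "manhattan"))
    between <- mean(D[upper.tri(D)])
    out[i] <- within / between
  }
  out
}

#' Elbow selection of the number of states
#'
#' Picks the interior k maximizing the discrete second difference of the
#' validity curve, `ratio(k-1) - 2 ratio(k) + ratio(k+1)`, i.e. the
#' sharpest bend; ties break toward smaller k. A flat curve (max second
#' difference below `1e-9`) returns the smallest k with a warning.
#'
#' @param curve named numeric vector from [validity_curve()] on >= 3
#'   consecutive k.
#' @return selected k (integer).
#' @export
select_k_elbow <- function(curve) {
  ks <- as.integer(names(curve))
  if (length(curve) < 3 || any(diff(ks) != 1)) {
    stop_config("validity curve must cover >= 3 consecutive k")
  }
  v <- as.numeric(curve)
  d2 <- v[seq_len(length(v) - 2)] - 2 * v[seq(2, length(v) - 1)] +
    v[seq(3, length(v))]
  if (max(d2) < 1e-9) {
    warning("validity curve is flat; returning smallest k")
    return(ks[1])
  }
  ks[which.max(d2) + 1L]
}

#' Per-run state transition count and fractional dwell time
#'
#' A transition is a change of assigned state between consecutive windows;
#' fractional dwell time of state s is the proportion of windows labeled s.
#'
#' @param labels integer state labels (values in 1..k) for one
#'   subject/task run, in temporal order.
#' @param k number of states.
#' @return list with `n_transitions` (integer) and `fractional_dwell`
#'   (length-k numeric summing to 1).
#' @export
state_metrics <- function(labels, k) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("empty label sequence", call. = FALSE)
  if (any(labels < 1 | labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  n_trans <- sum(labels[-1] != labels[-length(labels)])
  dwell <- tabulate(labels, nbins = k) / length(labels)
  list(n_transitions = as.integer(n_trans), fractional_dwell = dwell)
}

#' Fit the full state model: validity curve, elbow k, final clustering
#'
#' Convenience wrapper that pools windows across runs, computes the
#' validity curve over `k_range`, selects k by the elbow rule, refits at
#' the chosen k, and splits the labels back per run.
#'
#' @param window_list named list of windows x edges matrices (one per
#'   subject/task run), all with identical edge count.
#' @param k_range candidate k values.
#' @param k optional fixed k (skips the elbow).
#' @param max_iter,n_replicates,seed passed to [kmeans_l1()].
#' @return object of class `dfnc_state_model`: `k`, `centroids`, `fit`
#'   (the pooled [kmeans_l1()] object), `validity` (or NULL), `labels`
#'   (named list per run), `metrics` (data.frame: run, n_transitions,
#'   dwell_1..k).
#' @export
fit_state_model <- function(window_list, k_range = 2:10, k = NULL,
                            max_iter = 150, n_replicates = 20, seed = 1) {
  stopifnot(is.list(window_list), length(window_list) >= 1)
  mats <- lapply(window_list, function(x) {
    if (inherits(x, "dfnc_windows")) x$fnc else as.matrix(x)
  })
  counts <- vapply(mats, nrow, integer(1))
  X <- do.call(rbind, mats)
  validity <- NULL
  if (is.null(k)) {
    validity <- validity_curve(X, k_range, max_iter = max_iter,
                               n_replicates = n_replicates, seed = seed)
    k <- select_k_elbow(validity)
  }
  fit <- kmeans_l1(X, k, max_iter = max_iter, n_replicates = n_replicates,
                   seed = derive_seed(seed, "final"))
  splits <- split(fit$labels, rep(seq_along(mats), counts))
  names(splits) <- names(mats) %||% paste0("run_", seq_along(mats))
  met <- lapply(splits, state_metrics, k = k)
  metrics <- data.frame(
    run = names(splits),
    n_transitions = vapply(met, `[[`, integer(1), "n_transitions"),
    stringsAsFactors = FALSE, row.names = NULL)
  dw <- t(vapply(met, `[[`, numeric(k), "fractional_dwell"))
  colnames(dw) <- paste0("dwell_", seq_len(k))
  structure(list(k = k, centroids = fit$centroids, fit = fit,
                 validity = validity, labels = splits,
                 metrics = cbind(metrics, as.data.frame(dw))),
            class = "dfnc_state_model")
}

#' @export
print.dfnc_state_model <- function(x, ...) {
  cat("State model: k =", x$k, "states over", length(x$labels), "runs\n")
  if (!is.null(x$validity)) {
    cat("validity ratios:",
        paste(sprintf("k=%s:%.3f", names(x$validity), x$validity),
              collapse = " "), "\n")
  }
  invisible(x)
}
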