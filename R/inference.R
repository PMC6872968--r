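#' Permutation test on a difference of group means
#'
#' Observed statistic is `mean(a) - mean(b)`. Group membership is randomly
#' reassigned `B` times; the p-value uses the add-one convention
#' `p = (1 + #extreme) / (B + 1)`. Two-sided compares `|stat|`; the
#' one-sided variants compare the signed statistic.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @param sidedness "two", "greater" (a > b) or "less".
#' @return object of class `dfnc_test`: list with `statistic`, `p_value`,
#'   `n_permutations`, `sidedness`.
#' @export
permutation_mean_diff <- function(a, b, B = 10000, seed = 1,
                                  sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (B < 100) stop_config("B must be >= 100")
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  })
  extreme <- switch(sidedness,
                    two = sum(abs(perm) >= abs(obs)),
                    greater = sum(perm >= obs),
                    less = sum(perm <= obs))
  structure(list(statistic = obs,
                 p_value = (1 + extreme) / (B + 1),
                 n_permutations = B,
                 sidedness = sidedness),
            class = "dfnc_test")
}

#' @export
print.dfnc_test <- function(x, ...) {
  cat("statistic:", format(x$statistic, digits = 4),
      " p:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Subject-level state-specific mean connectivity
#'
#' The "spatial strength" of a state for one run: the mean of the windowed
#' FNC rows assigned to that state. Runs with no window in the state give
#' `NA` rows.
#'
#' @param fnc windows x edges matrix for one run.
#' @param labels state labels for the same windows.
#' @param state state index.
#' @return edge-length numeric vector (NA if the state is unvisited).
#' @export
state_mean_fnc <- function(fnc, labels, state) {
  fnc <- as.matrix(fnc)
  sel <- labels == state
  if (!any(sel)) return(rep(NA_real_, ncol(fnc)))
  colMeans(fnc[sel, , drop = FALSE])
}

#' Edgewise paired t-tests on state connectivity, BH-FDR corrected
#'
#' Compares the subject-level state-specific mean FNC between two paired
#' conditions edge by edge (paired t-test), applying Benjamini-Hochberg
#' FDR control across edges within the state. Subjects with no window in
#' the state under either condition are excluded pairwise (with a
#' message).
#'
#' @param mat_a,mat_b subjects x edges matrices of state mean FNC (rows
#'   paired by subject; NA rows mark unvisited states).
#' @param alpha FDR level.
#' @return data.frame: edge, mean_diff, t, df, p, q, significant; the
#'   number of complete pairs is in attribute `n_pairs`. Returns NULL with
#'   a warning when fewer than 3 complete pairs exist.
#' @export
state_edge_paired_t <- function(mat_a, mat_b, alpha = 0.05) {
  mat_a <- as.matrix(mat_a); mat_b <- as.matrix(mat_b)
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  complete <- stats::complete.cases(mat_a) & stats::complete.cases(mat_b)
  if (any(!complete)) {
    message(sum(!complete), " subject(s) excluded pairwise ",
            "(state unvisited in one condition)")
  }
  if (sum(complete) < 3) {
    warning("fewer than 3 complete pairs; test skipped")
    return(NULL)
  }
  d <- mat_a[complete, , drop = FALSE] - mat_b[complete, , drop = FALSE]
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)),
                  ifelse(m == 0, 0, sign(m) * Inf))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(edge = colnames(mat_a) %||% seq_along(m),
                    mean_diff = m, t = tstat, df = n - 1, p = p, q = q,
                    significant = q <= alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- n
  out
}

#' Signal-detection sensitivity (d-prime) with log-linear correction
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)` under the
#' equal-variance Gaussian model. The log-linear correction (add 0.5 to
#' each count and 1 to each denominator) is always applied, so perfect or
#' zero rates stay finite.
#'
#' @param hits,n_signal hit count and number of signal trials.
#' @param false_alarms,n_noise false-alarm count and number of noise
#'   trials.
#' @return d-prime (numeric, vectorized over inputs).
#' @export
dprime <- function(hits, n_signal, false_alarms, n_noise) {
  if (any(n_signal <= 0) || any(n_noise <= 0)) {
    stop("trial counts must be positive", call. = FALSE)
  }
  if (any(hits < 0 | hits > n_signal) ||
      any(false_alarms < 0 | false_alarms > n_noise)) {
    stop("counts outside [0, n]", call. = FALSE)
  }
  hr <- (hits + 0.5) / (n_signal + 1)
  fr <- (false_alarms + 0.5) / (n_noise + 1)
  qnorm(hr) - qnorm(fr)
}

#' FD-adjusted partial correlation of a state metric with behavior
#'
#' First-order partial Pearson correlation between `x` and `y` controlling
#' for a single covariate (typically mean framewise displacement), tested
#' with `t = r sqrt(n - 3) / sqrt(1 - r^2)` on `n - 3` degrees of freedom
#' (two-sided).
#'
#' @param x,y numeric vectors (the state metric and the behavioral score).
#' @param covariate numeric vector, same length.
#' @return object of class `dfnc_test` with `r` (partial correlation),
#'   `statistic` (t), `df`, `p_value`.
#' @export
partial_corr_behavior <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (anyNA(c(x, y, covariate))) stop("missing values not allowed", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input", call. = FALSE)
  Z <- cbind(1, covariate)
  rx <- qr.resid(qr(Z), cbind(x, y))
  r <- cor(rx[, 1], rx[, 2])
  tstat <- r * sqrt(n - 3) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 3)
  structure(list(r = r, statistic = tstat, df = n - 3,
                 p_value = min(1, p), sidedness = "two"),
            class = "dfnc_test")
}

#' Kolmogorov-Smirnov normality diagnostic
#'
#' One-sample KS test of `x` against a normal with the sample mean and
#' standard deviation. Reported as a diagnostic (to motivate permutation
#' inference for non-normal metrics), not as a gate.
#'
#' @param x numeric vector.
#' @return list with `statistic` and `p_value`.
#' @export
normality_screen <- function(x) {
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}
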