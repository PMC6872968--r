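#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma density peaking at 6 s minus a
#' gamma undershoot peaking at 16 s scaled by 1/6 (both with unit scale),
#' sampled on the TR grid and normalized to unit peak.
#'
#' @param TR sample spacing in seconds (> 0).
#' @param duration kernel support in seconds.
#' @return object of class `dfnc_hrf`: list with `t` (seconds), `values`
#'   (unit peak), `TR`.
#' @export
canonical_hrf <- function(TR, duration = 32) {
  if (!is.numeric(TR) || length(TR) != 1 || !is.finite(TR) || TR <= 0) {
    stop_config("TR must be a single positive number")
  }
  tt <- seq(0, duration, by = TR)
  h <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  h <- h / max(h)
  structure(list(t = tt, values = h, TR = TR), class = "dfnc_hrf")
}

#' Convolve a regressor with an HRF kernel
#' @param x numeric vector on the same TR grid as `hrf`.
#' @param hrf a [canonical_hrf()] kernel.
#' @return vector of `length(x)`: causal convolution truncated to the input
#'   length.
#' @export
hrf_convolve <- function(x, hrf) {
  stopifnot(inherits(hrf, "dfnc_hrf"))
  full <- convolve(x, rev(hrf$values), type = "open")
  full[seq_along(x)]
}

#' Build the nuisance regression model
#'
#' Columns: HRF-convolved task paradigm, the six realignment parameters,
#' their backward-difference derivatives (first row zero), and an
#' intercept. All-zero columns (e.g. zero motion) are flagged and dropped.
#'
#' @param paradigm a [make_paradigm()] object (or NULL for no task
#'   regressor).
#' @param motion n_volumes x 6 motion-parameter matrix (or NULL).
#' @param TR repetition time in seconds.
#' @param n_volumes number of time points the model must match.
#' @return object of class `dfnc_nuisance`: list with `X` (n_volumes x p),
#'   `labels`, `dropped` (labels of removed all-zero columns).
#' @export
build_nuisance <- function(paradigm, motion, TR, n_volumes) {
  cols <- list()
  if (!is.null(paradigm)) {
    box <- paradigm_boxcar(paradigm, n_volumes)
    cols[["task"]] <- hrf_convolve(box, canonical_hrf(TR))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) stop("motion must have 6 columns", call. = FALSE)
    if (nrow(motion) != n_volumes) {
      stop("motion has ", nrow(motion), " rows but n_volumes = ", n_volumes,
           call. = FALSE)
    }
    mlab <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    for (j in 1:6) cols[[mlab[j]]] <- motion[, j]
    d <- rbind(0, diff(motion))
    for (j in 1:6) cols[[paste0("d_", mlab[j])]] <- d[, j]
  }
  cols[["intercept"]] <- rep(1, n_volumes)
  X <- do.call(cbind, cols)
  labels <- names(cols)
  zero <- apply(X, 2, function(v) all(abs(v) < .Machine$double.eps)) &
    labels != "intercept"
  dropped <- labels[zero]
  if (any(zero)) {
    X <- X[, !zero, drop = FALSE]
    labels <- labels[!zero]
  }
  structure(list(X = X, labels = labels, dropped = dropped),
            class = "dfnc_nuisance")
}

#' Regress nuisance signals out of component time series
#'
#' Ordinary least squares per component; returns the residuals. Collinear
#' model columns are dropped with a warning (QR pivoting).
#'
#' @param ts numeric time x components matrix.
#' @param model a [build_nuisance()] model with matching row count.
#' @return residual matrix, same dimensions and dimnames as `ts`.
#' @export
regress_out <- function(ts, model) {
  ts <- as.matrix(ts)
  stopifnot(inherits(model, "dfnc_nuisance"))
  X <- model$X
  if (nrow(X) != nrow(ts)) {
    stop("model rows (", nrow(X), ") do not match time series rows (",
         nrow(ts), ")", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear nuisance column(s): ",
            paste(model$labels[-keep], collapse = ", "))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  res <- qr.resid(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

# Analog Butterworth low-pass of order n discretized by the bilinear
# transform (fs = 2, frequencies normalized to Nyquist = 1). Returns
# transfer-function coefficients (b, a).
butter_lowpass <- function(n, Wn) {
  stopifnot(n >= 1, Wn > 0, Wn < 1)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle prototype poles
  fs <- 2
  warped <- 2 * fs * tan(pi * Wn / fs)
  p <- p * warped
  gain <- warped^n
  # bilinear transform
  pz <- (2 * fs + p) / (2 * fs - p)
  gain_z <- gain * Re(prod(1 / (2 * fs - p)))
  zz <- rep(-1 + 0i, n)
  b <- Re(gain_z * poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

# Direct-form transposed-II IIR filter with zero initial conditions.
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  na <- length(a)
  y <- numeric(n)
  z <- numeric(max(na, nb) - 1)
  b <- c(b, rep(0, max(na, nb) - nb))
  a <- c(a, rep(0, max(na, nb) - na))
  for (t in seq_len(n)) {
    y[t] <- b[1] * x[t] + z[1]
    for (j in seq_along(z)) {
      zn <- if (j < length(z)) z[j + 1] else 0
      z[j] <- b[j + 1] * x[t] + zn - a[j + 1] * y[t]
    }
  }
  y
}

# Zero-phase filtering: forward and reverse passes with odd-reflection
# padding at both ends to suppress edge transients.
filtfilt0 <- function(b, a, x) {
  npad <- 3 * (max(length(a), length(b)) - 1)
  npad <- min(npad * 2 + 9, length(x) - 1)
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  ext <- c(pre, x, post)
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(npad + 1, npad + length(x))]
}

#' Linear detrend plus zero-phase low-pass filtering
#'
#' Removes a per-column linear trend, then applies a zero-phase (forward +
#' reverse) 5th-order Butterworth low-pass at `cutoff` Hz. Standard
#' temporal conditioning of component time courses ahead of sliding-window
#' connectivity.
#'
#' @param ts time x components numeric matrix (or vector).
#' @param TR repetition time in seconds.
#' @param cutoff low-pass cutoff in Hz; must be below Nyquist `1/(2 TR)`.
#' @param order filter order.
#' @return filtered matrix, same shape as `ts`.
#' @export
detrend_lowpass <- function(ts, TR, cutoff = 0.1, order = 5) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 30) stop_config("need at least 30 samples to filter")
  nyq <- 1 / (2 * TR)
  if (cutoff >= nyq) {
    stop_config("cutoff ", cutoff, " Hz is at or above Nyquist ", nyq, " Hz")
  }
  n <- nrow(ts)
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  ts_d <- qr.resid(qr(X), ts)
  coefs <- butter_lowpass(order, cutoff / nyq)
  out <- apply(ts_d, 2, function(col) filtfilt0(coefs$b, coefs$a, col))
  dimnames(out) <- dimnames(ts)
  out
}

#' Framewise displacement from realignment parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus `radius` times the absolute differences of the
#' three rotations (radians). The first frame is 0 by convention.
#'
#' @param motion n x 6 matrix: translations (mm) in columns 1-3, rotations
#'   (radians) in columns 4-6.
#' @param radius assumed head radius in mm used to convert rotations to arc
#'   displacement.
#' @return FD vector of length n (mm).
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("motion must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  }
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}
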