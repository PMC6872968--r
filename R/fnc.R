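#' Tapered sliding-window weights
#'
#' Builds the taper by convolving a rectangle of length `w` (in TRs) with a
#' discrete Gaussian of standard deviation `sigma` TRs (support +/- 3
#' sigma), keeping the central `w` samples and normalizing to sum 1. As
#' `sigma` grows the taper tends to the uniform window; small `sigma`
#' concentrates weight at the window center.
#'
#' @param w window length in TRs (>= 3).
#' @param sigma Gaussian standard deviation in TRs (> 0).
#' @return object of class `dfnc_taper`: list with `weights` (length `w`,
#'   positive, sums to 1), `w`, `sigma`.
#' @export
make_taper <- function(w = 20, sigma = 3) {
  if (!is.numeric(w) || w < 3 || w != round(w)) {
    stop_config("window length w must be an integer >= 3")
  }
  if (!is.numeric(sigma) || sigma <= 0) stop_config("sigma must be > 0")
  w <- as.integer(w)
  half <- max(1L, ceiling(3 * min(sigma, w)))
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  g <- g / sum(g)
  rect <- rep(1, w)
  full <- convolve(c(rect, rep(0, length(g) - 1)), rev(g), type = "open")
  # central w samples of the length (w + 2*half) convolution
  start <- half + 1L
  weights <- full[start:(start + w - 1L)]
  weights <- (weights + rev(weights)) / 2  # enforce exact symmetry
  weights <- weights / sum(weights)
  structure(list(weights = weights, w = w, sigma = sigma),
            class = "dfnc_taper")
}

#' Sliding-window tapered correlation of component time series
#'
#' For each window position, computes the weighted Pearson correlation
#' matrix of all component pairs using the taper weights (weighted means
#' and covariances), and stores its vectorized upper triangle. With `T`
#' time points, window length `w` and step 1 this yields `T - w + 1`
#' windows (197 volumes and w = 20 give 178).
#'
#' @param ts time x components numeric matrix (>= 2 components).
#' @param taper a [make_taper()] object.
#' @param step window step in samples.
#' @return object of class `dfnc_windows`: list with `fnc` (windows x
#'   edges matrix), `starts` (window start indices), `w`, `sigma`, `step`,
#'   `edge_names`, `n_components`.
#' @export
sliding_window_fnc <- function(ts, taper, step = 1) {
  ts <- as.matrix(ts)
  stopifnot(inherits(taper, "dfnc_taper"))
  n <- nrow(ts)
  p <- ncol(ts)
  w <- taper$w
  if (p < 2) stop("need at least 2 components", call. = FALSE)
  if (n < w) stop("series length ", n, " shorter than window ", w,
                  call. = FALSE)
  starts <- seq(1L, n - w + 1L, by = step)
  wt <- taper$weights
  n_edges <- choose(p, 2)
  up <- upper.tri(matrix(0, p, p))
  out <- matrix(NA_real_, length(starts), n_edges)
  degenerate <- FALSE
  for (i in seq_along(starts)) {
    X <- ts[starts[i]:(starts[i] + w - 1L), , drop = FALSE]
    m <- colSums(X * wt)
    Xc <- sweep(X, 2, m)
    C <- crossprod(Xc * wt, Xc)
    v <- diag(C)
    bad <- v <= 0
    if (any(bad)) {
      degenerate <- TRUE
      v[bad] <- 1
    }
    R <- C / sqrt(outer(v, v))
    if (any(bad)) {
      R[bad, ] <- 0
      R[, bad] <- 0
    }
    out[i, ] <- t(R)[lower.tri(R)][seq_len(n_edges)]
  }
  if (degenerate) {
    warning("zero weighted variance in at least one window; ",
            "affected correlations set to 0")
  }
  cn <- colnames(ts) %||% paste0("comp_", seq_len(p))
  structure(list(fnc = out, starts = starts, w = w, sigma = taper$sigma,
                 step = step, edge_names = edge_labels(cn),
                 n_components = p),
            class = "dfnc_windows")
}

#' @export
print.dfnc_windows <- function(x, ...) {
  cat("Windowed FNC:", nrow(x$fnc), "windows x", ncol(x$fnc), "edges",
      sprintf("(w = %d, sigma = %g, step = %d)\n", x$w, x$sigma, x$step))
  invisible(x)
}

#' Write windowed FNC as TSV plus a JSON sidecar
#' @param wf a [sliding_window_fnc()] object.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param meta extra metadata fields for the sidecar (subject, task, TR...).
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(wf, path, meta = list()) {
  stopifnot(inherits(wf, "dfnc_windows"))
  df <- as.data.frame(wf$fnc)
  names(df) <- wf$edge_names
  write.table(cbind(window = seq_len(nrow(df)), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  side <- c(list(w = wf$w, sigma = wf$sigma, step = wf$step), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
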