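#' @useDynLib dfncstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef convolve cor dgamma lm.fit mad median pnorm
#'   pt qnorm quantile rbinom rnorm runif sd setNames t.test var p.adjust
#'   fft ks.test
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1L)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Edges are taken row-major from the strict upper triangle, i.e. in the
#' order (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p).
#'
#' @param mat symmetric p x p matrix.
#' @return numeric vector of length `choose(p, 2)`.
#' @seealso [unvectorize_fnc()]
#' @export
vectorize_fnc <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop("`mat` must be a square matrix", call. = FALSE)
  }
  t(mat)[lower.tri(mat)]
}

#' Rebuild a symmetric unit-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_fnc()]: the vector must have triangular length
#' `choose(p, 2)` and is placed into the upper triangle row-major; the
#' diagonal is set to 1.
#'
#' @param edges numeric vector of length `choose(p, 2)`.
#' @return symmetric p x p matrix with unit diagonal.
#' @export
unvectorize_fnc <- function(edges) {
  m <- length(edges)
  p <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(p - round(p)) > 1e-9) {
    stop("edge vector length ", m, " is not a triangular number", call. = FALSE)
  }
  p <- as.integer(round(p))
  out <- diag(1, p)
  out[lower.tri(out)] <- edges
  out <- t(out)
  out[lower.tri(out)] <- edges
  t(out)
}

#' Edge labels for a vectorized connectivity matrix
#' @param comp_names component names (length p).
#' @return character vector "name_i-name_j" in vectorization order.
#' @export
edge_labels <- function(comp_names) {
  p <- length(comp_names)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0(comp_names[idx[, 1]], "-", comp_names[idx[, 2]])
}

#' Adjusted Rand index between two label vectors
#'
#' Standard Hubert-Arabie chance-corrected agreement; 1 means identical
#' partitions up to relabeling, 0 is chance level.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sij - expected) / (maxi - expected)
}

stop_config <- function(...) {
  stop(structure(class = c("dfnc_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
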