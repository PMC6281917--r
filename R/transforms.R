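# The eight DCT and eight DST orthonormal transform families, indexed
# [sample n][frequency k] (both 0-based in the formulas, 1-based in storage).
# Forward analysis contracts over the sample index n, so that for the cosine
# type-2 family X[k] = sqrt(2/N) * sigma_k * sum_n x[n] cos(pi k (2n+1) / 2N).

# normalization factors: 1/sqrt(2) at the stated index, 1 elsewhere
.sig <- function(i) ifelse(i == 0, 1 / sqrt(2), 1)           # sigma: index 0
.eps <- function(i, N) ifelse(i == N - 1, 1 / sqrt(2), 1)    # epsilon: index N-1
.gam <- function(i, N) ifelse(i == 0 | i == N - 1, 1 / sqrt(2), 1)

# Kernel table shared by the standard transforms and their quadrature
# companions: for family "cosine" type i, the companion sine matrix uses the
# same angle and amplitude with sin() in place of cos(), and vice versa.
# Returns list(angle, amp, n_idx, k_idx) with angle/amp matrices [n, k].
.kernel <- function(family, type, N) {
  if (N < 2) stop("transform order must be at least 2")
  if (!type %in% 1:8) stop("type index must be in 1..8")
  a <- sqrt(2 / (N - 1)); b <- sqrt(2 / N)
  cc <- 2 / sqrt(2 * N - 1); d <- 2 / sqrt(2 * N + 1)
  full <- list(n = 0:(N - 1), k = 0:(N - 1))
  if (family == "cosine") {
    switch(type,
      `1` = list(ang = outer(full$n, full$k, function(n, k) n * k * pi / (N - 1)),
                 amp = outer(.gam(full$n, N), .gam(full$k, N)) * a,
                 n_idx = full$n, k_idx = full$k),
      `2` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * k * pi / N),
                 amp = outer(rep(1, N), .sig(full$k)) * b,
                 n_idx = full$n, k_idx = full$k),
      `3` = list(ang = outer(full$n, full$k, function(n, k) (k + 0.5) * n * pi / N),
                 amp = outer(.sig(full$n), rep(1, N)) * b,
                 n_idx = full$n, k_idx = full$k),
      `4` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 0.5) * pi / N),
                 amp = matrix(b, N, N), n_idx = full$n, k_idx = full$k),
      `5` = list(ang = outer(full$n, full$k, function(n, k) n * k * 2 * pi / (2 * N - 1)),
                 amp = outer(.sig(full$n), .sig(full$k)) * cc,
                 n_idx = full$n, k_idx = full$k),
      `6` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * k * 2 * pi / (2 * N - 1)),
                 amp = outer(.eps(full$n, N), .sig(full$k)) * cc,
                 n_idx = full$n, k_idx = full$k),
      `7` = list(ang = outer(full$n, full$k, function(n, k) (k + 0.5) * n * 2 * pi / (2 * N - 1)),
                 amp = outer(.sig(full$n), .eps(full$k, N)) * cc,
                 n_idx = full$n, k_idx = full$k),
      `8` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 0.5) * 2 * pi / (2 * N + 1)),
                 amp = matrix(d, N, N), n_idx = full$n, k_idx = full$k))
  } else {
    red <- list(n = 1:(N - 1), k = 1:(N - 1))  # DST-1 and DST-5 are (N-1)th order
    switch(type,
      `1` = list(ang = outer(red$n, red$k, function(n, k) n * k * pi / N),
                 amp = matrix(b, N - 1, N - 1), n_idx = red$n, k_idx = red$k),
      `2` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 1) * pi / N),
                 amp = outer(rep(1, N), .eps(full$k, N)) * b,
                 n_idx = full$n, k_idx = full$k),
      `3` = list(ang = outer(full$n, full$k, function(n, k) (k + 0.5) * (n + 1) * pi / N),
                 amp = outer(.eps(full$n, N), rep(1, N)) * b,
                 n_idx = full$n, k_idx = full$k),
      `4` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 0.5) * pi / N),
                 amp = matrix(b, N, N), n_idx = full$n, k_idx = full$k),
      `5` = list(ang = outer(red$n, red$k, function(n, k) n * k * 2 * pi / (2 * N - 1)),
                 amp = matrix(cc, N - 1, N - 1), n_idx = red$n, k_idx = red$k),
      `6` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 1) * 2 * pi / (2 * N + 1)),
                 amp = matrix(d, N, N), n_idx = full$n, k_idx = full$k),
      `7` = list(ang = outer(full$n, full$k, function(n, k) (n + 1) * (k + 0.5) * 2 * pi / (2 * N + 1)),
                 amp = matrix(d, N, N), n_idx = full$n, k_idx = full$k),
      `8` = list(ang = outer(full$n, full$k, function(n, k) (n + 0.5) * (k + 0.5) * 2 * pi / (2 * N - 1)),
                 amp = outer(.eps(full$n, N), .eps(full$k, N)) * cc,
                 n_idx = full$n, k_idx = full$k))
  }
}

#' Build a DCT/DST orthonormal transform matrix
#'
#' Constructs one of the sixteen orthonormal trigonometric transform matrices
#' (cosine types 1-8 are the DCT family, sine types 1-8 the DST family).
#' Entries are indexed `[sample n, frequency k]`; the forward analysis of a
#' signal is the contraction over the sample index, `t(entries) %*% x`, and
#' because the matrices are orthonormal the inverse is `entries %*% X`.
#'
#' DST-1 and DST-5 are naturally of order `N - 1` (their index ranges are
#' `1 <= n, k <= N - 1`); for those two, the returned matrix is
#' `(N-1) x (N-1)` and [transform_forward()] expects signals of length
#' `N - 1`. All other types are full `N x N`.
#'
#' @param family `"cosine"` or `"sine"`.
#' @param type integer type index, 1 to 8.
#' @param N nominal transform order (at least 2).
#' @return An object of class `fq_transform_matrix`: a list with `entries`
#'   (the matrix), `family`, `type`, `order` (`N`) and `effective_order`
#'   (`N` or `N - 1`).
#' @examples
#' A <- transform_matrix("cosine", 2, 8)
#' max(abs(crossprod(A$entries) - diag(8)))  # orthonormal
#' @export
transform_matrix <- function(family = c("cosine", "sine"), type, N) {
  family <- match.arg(family)
  k <- .kernel(family, type, N)
  entries <- k$amp * (if (family == "cosine") cos(k$ang) else sin(k$ang))
  structure(list(entries = entries, family = family, type = as.integer(type),
                 order = as.integer(N), effective_order = ncol(entries)),
            class = "fq_transform_matrix")
}

#' @export
print.fq_transform_matrix <- function(x, ...) {
  cat(sprintf("<fq_transform_matrix> %s type %d, order %d (effective %d)\n",
              x$family, x$type, x$order, x$effective_order))
  invisible(x)
}

# -- fast orthonormal DCT-2 / IDCT-2 via a single FFT (Makhoul reordering) ---

.counter_env <- new.env(parent = emptyenv())
.counter_env$analysis <- 0L
.counter_env$synthesis <- 0L

.count_reset <- function() {
  .counter_env$analysis <- 0L
  .counter_env$synthesis <- 0L
}
.count_get <- function() list(analysis = .counter_env$analysis,
                              synthesis = .counter_env$synthesis)

#' Orthonormal DCT-2 of a numeric vector (fast path)
#'
#' Computes `X[k] = sqrt(2/N) * sigma_k * sum_n x[n] cos(pi k (2n+1) / 2N)`
#' with `sigma_0 = 1/sqrt(2)`, via one length-N FFT. Identical (to 1e-10) to
#' the explicit-matrix path `transform_forward(x, "cosine", 2)`.
#'
#' @param x numeric vector.
#' @return numeric vector of coefficients, same length.
#' @export
dct2 <- function(x) {
  x <- .samples(x)
  N <- length(x)
  .counter_env$analysis <- .counter_env$analysis + 1L
  v <- c(x[seq.int(1, N, 2)], rev(x[seq.int(2, N, 2)]))
  k <- 0:(N - 1)
  Xu <- Re(stats::fft(v) * exp(-1i * pi * k / (2 * N)))
  sqrt(2 / N) * .sig(k) * Xu
}

# One-sided complex synthesis on the DCT-2 half-sample grid:
#   z[n] = sum_k W[k] exp(j pi k (2n+1) / (2N)),  n = 0..N-1,
# evaluated with a single length-2N FFT. This primitive backs the inverse
# DCT-2, the type-2 quadrature transform, the quadrature analytic signal and
# every band synthesis of the filter bank.
.dct2_csynth <- function(W) {
  N <- length(W)
  .counter_env$synthesis <- .counter_env$synthesis + 1L
  Wp <- c(W * exp(1i * pi * (0:(N - 1)) / (2 * N)), rep(0, N))
  stats::fft(Wp, inverse = TRUE)[seq_len(N)]
}

# analysis companion: A[k] = sum_n y[n] exp(+j pi k (2n+1) / (2N))
.dct2_canalysis <- function(y) {
  N <- length(y)
  .counter_env$analysis <- .counter_env$analysis + 1L
  F <- stats::fft(c(y, rep(0, N)), inverse = TRUE)[seq_len(N)]
  exp(1i * pi * (0:(N - 1)) / (2 * N)) * F
}

#' Orthonormal inverse DCT-2 (fast path)
#'
#' @param X numeric coefficient vector as produced by [dct2()].
#' @return numeric vector of samples.
#' @export
idct2 <- function(X) {
  N <- length(X)
  Re(sqrt(2 / N) * .dct2_csynth(.sig(0:(N - 1)) * X))
}

#' Forward trigonometric transform
#'
#' Analysis of a real signal with any of the sixteen orthonormal transforms:
#' `coeffs[k] = sum_n entries[n, k] * x[n]`. The cosine type-2 family uses an
#' FFT fast path; all others use the explicit matrix.
#'
#' @param x numeric vector or [fq_signal]. For sine types 1 and 5 of nominal
#'   order `N`, the expected signal length is `N - 1` (see
#'   [transform_matrix()]).
#' @param family `"cosine"` or `"sine"`.
#' @param type type index 1..8.
#' @param fs optional sampling rate carried through to the result.
#' @return An `fq_spectrum`: list with `coeffs`, `family`, `type`, `order`,
#'   `fs`.
#' @export
transform_forward <- function(x, family = c("cosine", "sine"), type = 2, fs = NULL) {
  family <- match.arg(family)
  if (is.null(fs) && inherits(x, "fq_signal")) fs <- x$fs
  x <- .samples(x)
  L <- length(x)
  N <- if (family == "sine" && type %in% c(1, 5)) L + 1L else L
  if (family == "cosine" && type == 2) {
    coeffs <- dct2(x)
  } else {
    A <- transform_matrix(family, type, N)
    if (nrow(A$entries) != L)
      stop("signal length ", L, " incompatible with ", family, " type ", type,
           " of order ", N)
    coeffs <- drop(crossprod(A$entries, x))
  }
  structure(list(coeffs = coeffs, family = family, type = as.integer(type),
                 order = as.integer(N), fs = fs), class = "fq_spectrum")
}

#' Inverse trigonometric transform
#'
#' Synthesis from an `fq_spectrum`; exact round trip with
#' [transform_forward()] (orthonormal bases).
#'
#' @param X an `fq_spectrum` from [transform_forward()].
#' @return numeric vector of samples (an [fq_signal] when `X$fs` is set).
#' @export
transform_inverse <- function(X) {
  stopifnot(inherits(X, "fq_spectrum"))
  x <- if (X$family == "cosine" && X$type == 2) {
    idct2(X$coeffs)
  } else {
    A <- transform_matrix(X$family, X$type, X$order)
    if (ncol(A$entries) != length(X$coeffs))
      stop("coefficient length does not match transform order")
    drop(A$entries %*% X$coeffs)
  }
  if (!is.null(X$fs)) fq_signal(x, X$fs) else x
}

#' @export
print.fq_spectrum <- function(x, ...) {
  cat(sprintf("<fq_spectrum> %s type %d, %d coefficients\n",
              x$family, x$type, length(x$coeffs)))
  invisible(x)
}
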