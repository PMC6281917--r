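# Quadrature companions of the sixteen trigonometric transforms: the sine
# companion of DCT type i shares the DCT-i kernel angles and amplitudes with
# sin() in place of cos(); the cosine companion of DST type i likewise takes
# cos() on the DST-i kernel. Re-synthesizing analysis coefficients on the
# companion basis yields the Fourier quadrature transform of the signal,
# the discrete analogue of the Hilbert transform.

#' Build a quadrature companion matrix
#'
#' `family = "sine"` returns the sine companion of the cosine (DCT) transform
#' of the given type; `family = "cosine"` returns the cosine companion of the
#' sine (DST) transform. Companion matrices share the kernel angle and
#' normalization of their parent transform, so their dimensions match the
#' parent analysis matrix (in particular the cosine companions of DST-1 and
#' DST-5 are `(N-1) x (N-1)`).
#'
#' Several sine companions contain structurally zero columns or rows (for
#' example column `k = 0` of the type-2 sine companion is identically zero,
#' since `sin(0) = 0`), which is why the quadrature transform annihilates the
#' constant component of a signal; their nonzero columns remain orthonormal.
#'
#' @param family `"sine"` (companion of the DCT family) or `"cosine"`
#'   (companion of the DST family).
#' @param type type index 1..8 of the parent transform.
#' @param N nominal order.
#' @return An object of class `fq_quadrature_matrix`: list with `entries`,
#'   `family`, `type`, `order`, `effective_order`.
#' @examples
#' Q <- quadrature_matrix("sine", 2, 4)
#' Q$entries[1, 2]  # sqrt(2/4) * sin(pi/8) = 0.2706
#' @export
quadrature_matrix <- function(family = c("sine", "cosine"), type, N) {
  family <- match.arg(family)
  parent <- if (family == "sine") "cosine" else "sine"
  k <- .kernel(parent, type, N)
  entries <- k$amp * (if (family == "sine") sin(k$ang) else cos(k$ang))
  structure(list(entries = entries, family = family, type = as.integer(type),
                 order = as.integer(N), effective_order = ncol(entries)),
            class = "fq_quadrature_matrix")
}

#' @export
print.fq_quadrature_matrix <- function(x, ...) {
  cat(sprintf("<fq_quadrature_matrix> %s companion, type %d, order %d\n",
              x$family, x$type, x$order))
  invisible(x)
}

#' Fourier cosine quadrature transform (FCQT)
#'
#' DCT analysis followed by synthesis on the companion sine basis:
#' the quadrature (Hilbert-like) companion of `x`. For type 2,
#' `xq[n] = sqrt(2/N) * sum_k X[k] sin(pi k (2n+1) / 2N)` with `X` the
#' orthonormal DCT-2 coefficients; this path is computed by FFT. Like the
#' Hilbert transform, the FCQT of a constant signal is identically zero, so
#' the transform is invertible only on zero-mean signals (see
#' [invert_fcqt()]).
#'
#' @param x numeric vector or [fq_signal].
#' @param type DCT type index 1..8 (default 2).
#' @return numeric vector, the quadrature signal (same length as `x`).
#' @examples
#' N <- 16; n <- 0:(N - 1)
#' x <- cos(pi * 3 * (2 * n + 1) / (2 * N))
#' max(abs(fcqt(x) - sin(pi * 3 * (2 * n + 1) / (2 * N))))  # ~1e-15
#' @export
fcqt <- function(x, type = 2) {
  x <- .samples(x)
  if (type == 2) {
    N <- length(x)
    X <- dct2(x)
    return(Im(sqrt(2 / N) * .dct2_csynth(.sig(0:(N - 1)) * X)))
  }
  N <- length(x)
  A <- transform_matrix("cosine", type, N)
  Q <- quadrature_matrix("sine", type, N)
  drop(Q$entries %*% crossprod(A$entries, x))
}

#' Fourier sine quadrature transform (FSQT)
#'
#' DST analysis followed by synthesis on the companion cosine basis; the
#' mirror image of [fcqt()]. For DST types 1 and 5 the natural transform
#' order is one more than the signal length (see [transform_matrix()]).
#'
#' @param x numeric vector or [fq_signal].
#' @param type DST type index 1..8 (default 2).
#' @return numeric vector, same length as `x`.
#' @export
fsqt <- function(x, type = 2) {
  x <- .samples(x)
  L <- length(x)
  N <- if (type %in% c(1, 5)) L + 1L else L
  A <- transform_matrix("sine", type, N)
  Q <- quadrature_matrix("cosine", type, N)
  drop(Q$entries %*% crossprod(A$entries, x))
}

#' Fourier quadrature analytic signal (FSAS)
#'
#' The quadrature analytic-signal representation built from a trigonometric
#' transform pair. For the cosine family the real part is the original signal
#' and the imaginary part its FCQT (`z = x + i * fcqt(x)`); for the sine
#' family the imaginary part is the original signal and the real part its
#' FSQT (`z = fsqt(x) + i * x`). Like the classical analytic signal the
#' spectrum is one-sided, but real and imaginary parts are in general not
#' orthogonal.
#'
#' @param x numeric vector or [fq_signal].
#' @param family `"cosine"` (default) or `"sine"`.
#' @param type type index 1..8 (default 2, the workhorse variant).
#' @param fs optional sampling rate (taken from `x` when it is an
#'   [fq_signal]).
#' @return An [fq_analytic] object.
#' @examples
#' N <- 32; n <- 0:(N - 1)
#' z <- fsas(cos(pi * 4 * (2 * n + 1) / (2 * N)))
#' range(Mod(z$values))  # unit modulus: the analytic form of the tone
#' @export
fsas <- function(x, family = c("cosine", "sine"), type = 2, fs = NULL) {
  family <- match.arg(family)
  if (is.null(fs) && inherits(x, "fq_signal")) fs <- x$fs
  x <- .samples(x)
  if (family == "cosine") {
    values <- complex(real = x, imaginary = fcqt(x, type))
    kind <- sprintf("fsas_cosine_%d", type)
    original_part <- "real"
  } else {
    values <- complex(real = fsqt(x, type), imaginary = x)
    kind <- sprintf("fsas_sine_%d", type)
    original_part <- "imaginary"
  }
  fq_analytic(values, fs = fs, kind = kind, original_part = original_part)
}

#' Invert the type-2 FCQT on the zero-mean subspace
#'
#' Recovers the zero-mean part of a signal from its type-2 FCQT: the sine
#' basis spans only the `k >= 1` coefficients, so the mean (DC) component is
#' annihilated by construction and cannot be recovered;
#' `invert_fcqt(fcqt(x)) == x - mean-component of x`.
#'
#' @param xq numeric vector produced by `fcqt(x, type = 2)`.
#' @return numeric vector, the zero-mean part of the original signal.
#' @export
invert_fcqt <- function(xq) {
  xq <- .samples(xq)
  N <- length(xq)
  Xq <- sqrt(2 / N) * Im(.dct2_canalysis(xq))  # sine analysis of the quadrature
  Xq[1] <- 0
  idct2(Xq)
}

#' Closed-form cosine-sine basis cross inner product
#'
#' Evaluates `sum_n cos(pi k (2n+1)/2N) * sin(pi m (2n+1)/2N)` for
#' `0 <= k, m <= N-1` in closed form: 0 when `k = m` or when `m + k` is even
#' (`m + k` and `m - k` always share parity), and otherwise
#' `(1/2) / sin(pi (m+k) / 2N) + (1/2) / sin(pi (m-k) / 2N)`. Being nonzero
#' for odd `m + k` is what makes the quadrature analytic signal's real and
#' imaginary parts non-orthogonal, unlike the classical analytic signal.
#'
#' @param k,m frequency indices in `0..N-1`.
#' @param N transform order.
#' @return scalar value of the inner product.
#' @examples
#' cos_sin_inner(1, 2, 4)  # 1.8478
#' @export
cos_sin_inner <- function(k, m, N) {
  if (k < 0 || m < 0 || k > N - 1 || m > N - 1)
    stop("indices must satisfy 0 <= k, m <= N-1")
  if (k == m) return(0)
  if ((m + k) %% 2 == 0) return(0)
  0.5 / sin(pi * (m + k) / (2 * N)) + 0.5 / sin(pi * (m - k) / (2 * N))
}
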