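# Fourier decomposition method: a zero-phase filter bank over the DCT-2 (or
# one-sided DFT) coefficients. A band plan partitions the frequency bins
# k = 1..Kmax into contiguous bands; each band is synthesized back to the
# time domain as a Fourier intrinsic band function (FIBF) together with its
# analytic companion. Bin k of the DCT-2 basis corresponds to
# f_k = k * fs / (2N) Hz; bin k of the DFT basis to k * fs / N.

.k_max <- function(N, basis) if (basis == "dct2") N - 1L else N %/% 2L

# Hz -> bin index under the basis bin convention; ties round toward the
# lower bin.
.hz_to_bin <- function(f_hz, N, fs, basis) {
  v <- if (basis == "dct2") f_hz * 2 * N / fs else f_hz * N / fs
  k <- ceiling(v - 0.5)
  pmin(pmax(as.integer(round(k)), 0L), .k_max(N, basis))
}

.bin_to_hz <- function(k, N, fs, basis) {
  if (basis == "dct2") k * fs / (2 * N) else k * fs / N
}

#' Plan frequency bands for the zero-phase filter bank
#'
#' Partitions the non-DC frequency bins `k = 1..Kmax` (`Kmax = N - 1` for the
#' DCT-2 basis, `floor(N/2)` for the DFT basis) into `M` ordered, contiguous,
#' non-overlapping bands:
#'
#' * `"equal"`: near-equal numbers of bins per band;
#' * `"dyadic"`: octave bands; the top band is `[fs/4, fs/2)`, each next band
#'   halves downward, and the lowest band absorbs the residual down to (but
#'   excluding) DC, so its upper edge is `fs / 2^M`;
#' * `"equal_energy"`: boundaries at the cumulative-energy quantiles of the
#'   signal's squared coefficient spectrum (a bin joins the earlier band when
#'   the running sum first reaches `i * total / M`);
#' * `"custom"`: explicit edges in Hz via `edges_hz` (length `M + 1`,
#'   ascending, starting at 0).
#'
#' @param N transform length (signal length).
#' @param fs sampling rate in Hz.
#' @param M number of bands, `1 <= M <= Kmax` (implied by `edges_hz` for
#'   `"custom"`).
#' @param strategy `"equal"`, `"dyadic"`, `"equal_energy"` or `"custom"`.
#' @param basis `"dct2"` (default) or `"dft"`.
#' @param x the signal (numeric or [fq_signal]); required for
#'   `"equal_energy"`.
#' @param edges_hz numeric vector of band edges in Hz for `"custom"`.
#' @return An object of class `fq_band_plan`: list with `bands` (an `M x 2`
#'   integer matrix of inclusive bin ranges), `edges_hz` (nominal edges,
#'   length `M + 1`), `strategy`, `N`, `fs`, `basis`.
#' @examples
#' p <- select_bands(N = 1000, fs = 50, M = 8, strategy = "dyadic")
#' p$edges_hz  # 0, 0.1953, 0.3906, 0.78125, 1.5625, 3.125, 6.25, 12.5, 25
#' @export
select_bands <- function(N, fs, M = NULL,
                         strategy = c("equal", "dyadic", "equal_energy", "custom"),
                         basis = c("dct2", "dft"), x = NULL, edges_hz = NULL) {
  strategy <- match.arg(strategy)
  basis <- match.arg(basis)
  kmax <- .k_max(N, basis)
  if (strategy == "custom") {
    if (is.null(edges_hz)) stop("strategy 'custom' requires edges_hz")
    if (is.unsorted(edges_hz, strictly = TRUE) || edges_hz[1] != 0)
      stop("edges_hz must be strictly increasing and start at 0")
    M <- length(edges_hz) - 1L
    k_hi <- .hz_to_bin(edges_hz[-1], N, fs, basis)
    k_hi[M] <- kmax
  } else {
    if (is.null(M)) stop("number of bands M is required")
    if (M < 1 || M > kmax) stop("M must be between 1 and ", kmax)
    if (strategy == "equal") {
      k_hi <- floor(seq_len(M) * kmax / M)
      edges_hz <- c(0, .bin_to_hz(k_hi, N, fs, basis))
    } else if (strategy == "dyadic") {
      edges_hz <- c(0, fs / 2^(M:1))
      k_hi <- .hz_to_bin(edges_hz[-1], N, fs, basis)
      k_hi[M] <- kmax
    } else {  # equal_energy
      if (is.null(x)) stop("strategy 'equal_energy' requires the signal x")
      xs <- .samples(x)
      if (length(xs) != N) stop("length(x) must equal N")
      E <- if (basis == "dct2") dct2(xs)[-1]^2 else
        Mod(stats::fft(xs))[2:(kmax + 1)]^2
      E <- E[seq_len(kmax)]
      cum <- cumsum(E)
      tot <- cum[kmax]
      if (tot <= 0) stop("equal_energy: signal has no non-DC energy")
      k_hi <- integer(M)
      prev <- 0L
      for (i in seq_len(M - 1)) {
        # small relative slack so exact quantile ties are not lost to rounding
        ki <- which(cum >= i * tot / M - 1e-9 * tot)[1]
        k_hi[i] <- max(ki, prev + 1L)           # keep bands nonempty
        prev <- k_hi[i]
      }
      k_hi[M] <- kmax
      if (any(diff(k_hi) < 1)) stop("M too large for the energy distribution")
      edges_hz <- c(0, .bin_to_hz(k_hi, N, fs, basis))
    }
  }
  k_lo <- c(1L, utils::head(k_hi, -1) + 1L)
  if (any(k_hi < k_lo))
    stop("band plan has an empty band: increase N or decrease M")
  structure(list(bands = cbind(k_lo = as.integer(k_lo), k_hi = as.integer(k_hi)),
                 edges_hz = edges_hz, strategy = strategy,
                 N = as.integer(N), fs = fs, basis = basis),
            class = "fq_band_plan")
}

#' @export
print.fq_band_plan <- function(x, ...) {
  cat(sprintf("<fq_band_plan> %d %s bands, basis %s, N = %d, fs = %g Hz\n",
              nrow(x$bands), x$strategy, x$basis, x$N, x$fs))
  lo <- .bin_to_hz(x$bands[, 1] - 1L, x$N, x$fs, x$basis)
  hi <- .bin_to_hz(x$bands[, 2], x$N, x$fs, x$basis)
  for (i in seq_len(nrow(x$bands)))
    cat(sprintf("  band %d: bins %d..%d  (%.4g - %.4g Hz)\n",
                i, x$bands[i, 1], x$bands[i, 2], lo[i], hi[i]))
  invisible(x)
}

#' Zero-phase frequency-domain mask for one band
#'
#' Real non-negative gain over the coefficient index `k = 0..N-1`: 1 inside
#' the inclusive bin range and 0 outside (`shape = "binary"`), or a Gaussian
#' bump centred on the band (`shape = "gaussian"`, `sigma` in bins defaulting
#' to a quarter of the band width). Real masks introduce no group delay, so
#' extrema of the filtered waveform stay where they are in the input.
#'
#' @param band length-2 integer vector `(k_lo, k_hi)`, inclusive.
#' @param N transform length.
#' @param shape `"binary"` or `"gaussian"`.
#' @param sigma Gaussian width in bins.
#' @return numeric vector of length `N`, all entries `>= 0`.
#' @examples
#' zero_phase_mask(c(3, 5), 8)  # 0 0 0 1 1 1 0 0
#' @export
zero_phase_mask <- function(band, N, shape = c("binary", "gaussian"),
                            sigma = NULL) {
  shape <- match.arg(shape)
  k_lo <- band[1]; k_hi <- band[2]
  if (k_lo > k_hi || k_lo < 0 || k_hi > N - 1)
    stop("band must satisfy 0 <= k_lo <= k_hi <= N-1")
  k <- 0:(N - 1)
  if (shape == "binary")
    return(as.numeric(k >= k_lo & k <= k_hi))
  if (is.null(sigma)) sigma <- max((k_hi - k_lo + 1) / 4, 0.5)
  centre <- (k_lo + k_hi) / 2
  exp(-0.5 * ((k - centre) / sigma)^2)
}

#' Decompose a signal into Fourier intrinsic band functions
#'
#' Runs the zero-phase filter bank: one forward transform, then one synthesis
#' per band of the masked coefficients. With the DCT-2 basis and
#' `analytic = "fsas"`, band i is synthesized directly in analytic form,
#' `z_i[n] = sqrt(2/N) * sum_{k in band i} X[k] exp(i pi k (2n+1) / 2N)`,
#' whose real part is the FIBF and whose imaginary part is its quadrature;
#' with `analytic = "gas"` the real FIBF is synthesized and its classical
#' analytic signal taken instead. With the DFT basis each band is synthesized
#' by the one-sided spectrum construction (both `analytic` choices coincide).
#' The DC bin never belongs to a band; it is carried separately as the mean
#' term `a0`. The FIBFs are complete (`a0 + sum_i Re z_i = x`) and mutually
#' orthogonal by construction.
#'
#' @param x numeric vector or [fq_signal] of length `plan$N`.
#' @param plan an `fq_band_plan` from [select_bands()].
#' @param analytic `"fsas"` (default) or `"gas"`: how the analytic companion
#'   of each band is built.
#' @param masks optional list of custom mask vectors (one per band, length
#'   `N`), e.g. Gaussian masks from [zero_phase_mask()]; defaults to binary
#'   masks from the plan.
#' @return An object of class `fq_fibf_set`: list with `a0` (mean term),
#'   `components` (list of complex vectors), `plan`, `analytic_kind`, `fs`.
#' @examples
#' x <- synthetic_ecg(fs = 200, duration = 4, seed = 1)
#' plan <- select_bands(length(x$samples), x$fs, M = 6, strategy = "dyadic")
#' f <- fdm_decompose(x, plan)
#' max(abs(fdm_reconstruct(f) - x$samples))  # completeness
#' @export
fdm_decompose <- function(x, plan, analytic = c("fsas", "gas"), masks = NULL) {
  analytic <- match.arg(analytic)
  stopifnot(inherits(plan, "fq_band_plan"))
  fs <- if (inherits(x, "fq_signal")) x$fs else plan$fs
  x <- .samples(x)
  N <- length(x)
  if (N != plan$N) stop("plan$N (", plan$N, ") does not match signal length (", N, ")")
  M <- nrow(plan$bands)
  if (!is.null(masks)) {
    if (length(masks) != M) stop("need one mask per band")
    if (any(vapply(masks, length, 1L) != N)) stop("each mask must have length N")
  }
  components <- vector("list", M)
  if (plan$basis == "dct2") {
    X <- dct2(x)
    a0 <- X[1] / sqrt(N)                       # DC synthesis = signal mean
    for (i in seq_len(M)) {
      m <- if (is.null(masks)) zero_phase_mask(plan$bands[i, ], N) else masks[[i]]
      m[1] <- 0
      Xi <- m * X
      if (analytic == "fsas") {
        components[[i]] <- sqrt(2 / N) * .dct2_csynth(.sig(0:(N - 1)) * Xi)
      } else {
        xi <- idct2(Xi)
        components[[i]] <- gas(xi)$values
      }
    }
  } else {
    X <- stats::fft(x) / N
    a0 <- Re(X[1])
    kmax <- .k_max(N, "dft")
    n <- 0:(N - 1)
    w <- rep(2, N)                              # one-sided weights
    if (N %% 2 == 0) w[kmax + 1] <- 1
    for (i in seq_len(M)) {
      m <- if (is.null(masks)) zero_phase_mask(plan$bands[i, ], N) else masks[[i]]
      m[1] <- 0
      Xi <- X * m * w
      Xi[(kmax + 2):N] <- 0                     # keep the spectrum one-sided
      components[[i]] <- stats::fft(Xi, inverse = TRUE)
    }
  }
  structure(list(a0 = a0, components = components, plan = plan,
                 analytic_kind = analytic, fs = fs),
            class = "fq_fibf_set")
}

#' @export
print.fq_fibf_set <- function(x, ...) {
  cat(sprintf("<fq_fibf_set> %d %s components + mean term a0 = %.4g (basis %s)\n",
              length(x$components), x$analytic_kind, x$a0, x$plan$basis))
  invisible(x)
}

#' Reconstruct a signal from (a subset of) its FIBFs
#'
#' Sums the real signal parts of the selected band components, optionally
#' plus the mean term. With all bands and the mean this is the original
#' signal; dropping bands performs zero-phase band-stop filtering.
#'
#' @param fset an `fq_fibf_set` from [fdm_decompose()].
#' @param include integer indices of bands to keep (default all). An empty
#'   selection is allowed.
#' @param with_mean include the mean term `a0`? Default `TRUE`.
#' @return numeric vector of samples.
#' @export
fdm_reconstruct <- function(fset, include = NULL, with_mean = TRUE) {
  stopifnot(inherits(fset, "fq_fibf_set"))
  if (is.null(include)) include <- seq_along(fset$components)
  N <- fset$plan$N
  out <- rep(if (with_mean) fset$a0 else 0, N)
  for (i in include) out <- out + Re(fset$components[[i]])
  out
}

#' Remove frequency bands from a signal (zero-phase band-stop)
#'
#' Builds a band plan whose boundaries align to the requested stop-band
#' cut-offs (nearest bin), zeroes the stop bands, and returns the cleaned
#' signal together with each removed component separately. The typical use is
#' ECG denoising: a `(0, 0.5)` Hz stop band removes baseline wander and a
#' `(49, 51)` Hz band removes 50 Hz power-line interference. The mean term is
#' kept in the cleaned signal unless a stop band starts at 0 Hz (baseline
#' removal implies detrending to the mean; `a0` itself is retained).
#'
#' @param x numeric vector or [fq_signal].
#' @param stop_hz list of length-2 numeric vectors `(f_lo, f_hi)` in Hz.
#'   Overlapping bands are merged with a warning.
#' @param fs sampling rate (required when `x` is a bare vector).
#' @param basis `"dct2"` (default) or `"dft"`.
#' @return list with `clean` (numeric), `removed` (list of numeric vectors,
#'   one per merged stop band), and `stop_bins` (matrix of bin ranges).
#'   `clean + sum(removed)` equals the input exactly.
#' @export
remove_bands <- function(x, stop_hz, fs = NULL, basis = c("dct2", "dft")) {
  basis <- match.arg(basis)
  fs <- .fs(x, fs)
  xs <- .samples(x)
  N <- length(xs)
  kmax <- .k_max(N, basis)
  if (length(stop_hz) == 0)
    return(list(clean = xs, removed = list(),
                stop_bins = matrix(integer(0), 0, 2)))
  spec <- lapply(stop_hz, function(b) {
    if (b[1] < 0 || b[2] <= b[1] || b[2] > fs / 2)
      stop("stop band must satisfy 0 <= f_lo < f_hi <= fs/2")
    k_lo <- max(1L, .hz_to_bin(b[1], N, fs, basis) + as.integer(b[1] > 0))
    k_hi <- .hz_to_bin(b[2], N, fs, basis)
    c(k_lo, max(k_lo, k_hi))
  })
  spec <- spec[order(vapply(spec, `[`, 1L, 1))]
  merged <- list(spec[[1]])
  for (b in spec[-1]) {
    last <- merged[[length(merged)]]
    if (b[1] <= last[2] + 1L) {
      if (b[1] <= last[2]) warning("overlapping stop bands merged")
      merged[[length(merged)]] <- c(last[1], max(last[2], b[2]))
    } else merged <- c(merged, list(b))
  }
  removed <- vector("list", length(merged))
  if (basis == "dct2") {
    X <- dct2(xs)
    for (i in seq_along(merged)) {
      m <- zero_phase_mask(merged[[i]], N)
      m[1] <- 0
      removed[[i]] <- idct2(m * X)
    }
  } else {
    X <- stats::fft(xs) / N
    w <- rep(2, N); w[1] <- 0
    if (N %% 2 == 0) w[kmax + 1] <- 1
    for (i in seq_along(merged)) {
      m <- zero_phase_mask(merged[[i]], N)
      Xi <- X * m * w
      Xi[(kmax + 2):N] <- 0
      removed[[i]] <- Re(stats::fft(Xi, inverse = TRUE))
    }
  }
  clean <- xs - Reduce(`+`, removed)
  list(clean = clean, removed = removed,
       stop_bins = do.call(rbind, merged))
}

#' Extract trend and variability at a chosen timescale
#'
#' The trend is the zero-phase reconstruction of all coefficients whose
#' frequency is at most `1 / timescale` (variations of `timescale` or longer),
#' including the mean; the variability is the exact remainder
#' `x - trend`. Bin `k` of the DCT-2 basis maps to `k * fs / (2N)` Hz.
#'
#' @param x numeric vector or [fq_signal].
#' @param timescale period `T` in the time unit of `1/fs` (e.g. years for
#'   annual data with `fs = 1`); must exceed `2/fs` (the Nyquist period).
#'   A timescale longer than the record yields the mean as trend.
#' @param fs sampling rate (required when `x` is a bare vector).
#' @return list with numeric vectors `trend` and `variability` and the
#'   cut-off bin `k_cut`.
#' @export
extract_trend <- function(x, timescale, fs = NULL) {
  fs <- .fs(x, fs)
  xs <- .samples(x)
  N <- length(xs)
  if (timescale <= 2 / fs)
    stop("timescale must exceed the Nyquist period 2/fs")
  f_cut <- 1 / timescale
  k_cut <- min(floor(f_cut * 2 * N / fs + 1e-9), N - 1)
  X <- dct2(xs)
  keep <- as.numeric(0:(N - 1) <= k_cut)
  trend <- idct2(keep * X)
  list(trend = trend, variability = xs - trend, k_cut = as.integer(k_cut))
}

#' Windowed band reconstruction
#'
#' Reconstructs `sum_i w_i[n] * Re z_i[n]` with one time-domain weight vector
#' per selected band (e.g. Gaussian windows localizing each band's
#' contribution in time). All-ones windows reduce to [fdm_reconstruct()]
#' without the mean term.
#'
#' @param fset an `fq_fibf_set`.
#' @param windows list of numeric weight vectors of length `N`, one per
#'   selected band.
#' @param include indices of the bands the windows apply to (default
#'   `seq_along(windows)`).
#' @param with_mean include `a0`? Default `FALSE`.
#' @return numeric vector of samples.
#' @export
window_reconstruct <- function(fset, windows, include = NULL, with_mean = FALSE) {
  stopifnot(inherits(fset, "fq_fibf_set"))
  if (is.null(include)) include <- seq_along(windows)
  if (length(windows) != length(include))
    stop("need exactly one window per selected band")
  N <- fset$plan$N
  out <- rep(if (with_mean) fset$a0 else 0, N)
  for (j in seq_along(include)) {
    w <- windows[[j]]
    if (length(w) != N) stop("each window must have length N")
    out <- out + w * Re(fset$components[[include[j]]])
  }
  out
}
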