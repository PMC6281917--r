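# Classical (Gabor) analytic signal via the one-sided DFT spectrum, and
# instantaneous amplitude / phase / frequency estimation from any analytic
# signal by finite differences of the wrapped phase.

#' Analytic signal container
#'
#' Complex-valued signal with a one-sided spectrum, tagged with the
#' construction that produced it (`"gas"` for the classical one-sided-DFT
#' analytic signal, `"fsas_cosine_t"` / `"fsas_sine_t"` for the quadrature
#' variants) and with which part carries the original signal.
#'
#' @param values complex vector.
#' @param fs sampling rate in Hz, or `NULL`.
#' @param kind construction tag.
#' @param original_part `"real"` or `"imaginary"`.
#' @return An object of class `fq_analytic`.
#' @export
fq_analytic <- function(values, fs = NULL, kind = "gas",
                        original_part = c("real", "imaginary")) {
  original_part <- match.arg(original_part)
  structure(list(values = as.complex(values), fs = fs, kind = kind,
                 original_part = original_part),
            class = "fq_analytic")
}

#' @export
print.fq_analytic <- function(x, ...) {
  cat(sprintf("<fq_analytic> %s, %d samples%s, original signal in %s part\n",
              x$kind, length(x$values),
              if (is.null(x$fs)) "" else sprintf(" @ %g Hz", x$fs),
              x$original_part))
  invisible(x)
}

.analytic_values <- function(z) {
  if (inherits(z, "fq_analytic")) z$values else as.complex(z)
}

#' Gabor analytic signal (one-sided DFT spectrum)
#'
#' The classical analytic signal of a real signal: the DFT is computed, all
#' strictly negative-frequency bins are zeroed, interior positive bins are
#' doubled, and DC (and Nyquist, for even length) are kept unscaled; the
#' inverse DFT yields the complex signal. Its real part is the original
#' signal, its imaginary part the (periodic) Hilbert transform, and the two
#' parts are orthogonal.
#'
#' @param x numeric vector or [fq_signal].
#' @param fs optional sampling rate.
#' @return An [fq_analytic] with `kind = "gas"`.
#' @examples
#' N <- 64; n <- 0:(N - 1)
#' z <- gas(cos(2 * pi * 5 * n / N))
#' max(Mod(z$values - exp(2i * pi * 5 * n / N)))  # harmonic correspondence
#' @export
gas <- function(x, fs = NULL) {
  if (is.null(fs) && inherits(x, "fq_signal")) fs <- x$fs
  x <- .samples(x)
  N <- length(x)
  X <- stats::fft(x) / N
  w <- rep(0, N)
  w[1] <- 1
  if (N %% 2 == 0) {
    if (N / 2 >= 2) w[2:(N / 2)] <- 2
    w[N / 2 + 1] <- 1
  } else if (N >= 3) {
    w[2:((N + 1) / 2)] <- 2
  }
  z <- stats::fft(X * w, inverse = TRUE)
  fq_analytic(z, fs = fs, kind = "gas", original_part = "real")
}

#' Instantaneous amplitude and phase of an analytic signal
#'
#' Polar form: amplitude is the complex modulus; phase is the two-argument
#' arctangent `atan2(Im z, Re z)` with range `(-pi, pi]` (`atan2(0, 0) = 0`,
#' so samples of exactly zero amplitude get phase 0).
#'
#' @param z an [fq_analytic] or complex vector.
#' @return list with numeric vectors `ia` (amplitude, `>= 0`) and `ip`
#'   (phase in `(-pi, pi]`).
#' @examples
#' analytic_polar(complex(real = 1, imaginary = 1))  # ia = sqrt(2), ip = pi/4
#' @export
analytic_polar <- function(z) {
  v <- .analytic_values(z)
  list(ia = Mod(v), ip = atan2(Im(v), Re(v)))
}

# wrap into [-pi, pi]; both endpoints map to themselves (round half-to-even
# keeps +pi and -pi fixed), so a one-sided difference of exactly -pi is
# corrected to 0 by the positivity rule while +pi stays at the Nyquist rate
.wrap_pi <- function(d) d - 2 * pi * round(d / (2 * pi))

# positivity correction: a negative phase increment reflects the multivalued
# arctangent, so pi is added to land in [0, pi]
.if_correct <- function(d) ifelse(d >= 0, d, d + pi)

#' Instantaneous frequency from a wrapped phase sequence
#'
#' Differentiates the wrapped instantaneous phase by forward (`"ffd"`),
#' backward (`"bfd"`) or central (`"cfd"`, default) finite differences, wraps
#' each raw one-sample difference into `[-pi, pi]`, and applies the
#' positivity correction (add `pi` to negative increments) so that the
#' angular frequency lies in `[0, pi]` rad/sample for mono- and multicomponent
#' signals alike.
#'
#' The central estimate is computed as the mean of the two corrected
#' one-sided differences. Wherever both one-sided differences fall in the
#' same branch of the positivity rule (every smooth phase law) this is
#' exactly the corrected central difference `(ip[n+1] - ip[n-1]) / 2`; on
#' phase staircases of sparse signals (for example a delta sequence, whose
#' quadrature phase is quantized to multiples of `pi/2`) it is the variant
#' that recovers the flat mid-Nyquist frequency ridge. Endpoints always use
#' the available one-sided difference.
#'
#' @param ip numeric vector of wrapped phases in `(-pi, pi]`.
#' @param method `"cfd"`, `"ffd"` or `"bfd"`.
#' @param fs sampling rate in Hz; when given, frequencies in Hz are returned
#'   alongside rad/sample.
#' @return list with `omega` (rad/sample, in `[0, pi]`) and `f_hz`
#'   (`omega * fs / (2 pi)`, or `NULL` when `fs` is missing).
#' @export
inst_frequency <- function(ip, method = c("cfd", "ffd", "bfd"), fs = NULL) {
  method <- match.arg(method)
  N <- length(ip)
  if (N < 2) stop("need at least 2 phase samples")
  if (method == "cfd" && N < 3) stop("central differences need at least 3 samples")
  d <- diff(ip)
  fwd <- .if_correct(.wrap_pi(c(d, NA)))   # fwd[n] uses ip[n+1] - ip[n]
  bwd <- .if_correct(.wrap_pi(c(NA, d)))   # bwd[n] uses ip[n]   - ip[n-1]
  omega <- switch(method,
    ffd = { o <- fwd; o[N] <- bwd[N]; o },
    bfd = { o <- bwd; o[1] <- fwd[1]; o },
    cfd = { o <- (fwd + bwd) / 2; o[1] <- fwd[1]; o[N] <- bwd[N]; o })
  list(omega = omega, f_hz = if (is.null(fs)) NULL else omega * fs / (2 * pi))
}

#' Instantaneous descriptors of an analytic signal
#'
#' Convenience wrapper combining [analytic_polar()] and [inst_frequency()].
#' At samples of exactly zero amplitude the frequency estimate is replaced by
#' linear interpolation from the neighbouring nonzero-amplitude samples (the
#' phase is undefined there).
#'
#' @param z an [fq_analytic] or complex vector.
#' @param method finite-difference method, see [inst_frequency()].
#' @param fs sampling rate in Hz (taken from `z` when available).
#' @return data frame with columns `n` (0-based sample index), `t` (seconds,
#'   when `fs` known), `ia`, `ip`, `omega`, and `f_hz` (when `fs` known).
#' @export
inst_descriptors <- function(z, method = c("cfd", "ffd", "bfd"), fs = NULL) {
  method <- match.arg(method)
  if (is.null(fs) && inherits(z, "fq_analytic")) fs <- z$fs
  p <- analytic_polar(z)
  est <- inst_frequency(p$ip, method = method, fs = fs)
  omega <- est$omega
  zero <- p$ia == 0
  if (any(zero) && !all(zero)) {
    idx <- seq_along(omega)
    omega[zero] <- stats::approx(idx[!zero], omega[!zero], xout = idx[zero],
                                 rule = 2)$y
  }
  n <- seq_along(omega) - 1L
  out <- data.frame(n = n, ia = p$ia, ip = p$ip, omega = omega)
  if (!is.null(fs)) {
    out$t <- n / fs
    out$f_hz <- omega * fs / (2 * pi)
    out <- out[, c("n", "t", "ia", "ip", "omega", "f_hz")]
  }
  out
}
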