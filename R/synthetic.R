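# Synthetic fixture generators: every worked example and application in the
# package can be exercised without external recordings. All generators are
# deterministic given their seed.

#' Unit sample (delta) sequence
#'
#' `x[n] = 1` at `n = n0` (0-based) and 0 elsewhere. The classic
#' impulse-analysis fixture: its analytic representation concentrates energy
#' at `t = n0 / fs` and instantaneous frequency at half Nyquist (`fs / 4`).
#'
#' @param N length.
#' @param n0 0-based index of the unit sample, `0 <= n0 < N`.
#' @param fs sampling rate in Hz.
#' @return An [fq_signal].
#' @export
unit_sample <- function(N, n0, fs = 1) {
  if (n0 < 0 || n0 >= N) stop("n0 must satisfy 0 <= n0 < N")
  x <- numeric(N)
  x[n0 + 1] <- 1
  fq_signal(x, fs)
}

#' Linear chirp
#'
#' `x(t) = cos(2 pi (f0 t + (f1 - f0) t^2 / (2 T)))` over `t in [0, T)`, so
#' the instantaneous frequency sweeps linearly from `f0` to `f1`. The true IF
#' law is stored in attribute `if_hz`.
#'
#' @param fs sampling rate in Hz.
#' @param duration T in seconds.
#' @param f0,f1 start and end frequencies, `0 <= f0 < f1 <= fs/2`.
#' @return An [fq_signal] with attribute `if_hz` (numeric vector of the true
#'   instantaneous frequency at each sample).
#' @export
linear_chirp <- function(fs, duration, f0, f1) {
  if (f0 < 0 || f1 <= f0 || f1 > fs / 2)
    stop("need 0 <= f0 < f1 <= fs/2")
  N <- round(fs * duration)
  t <- (0:(N - 1)) / fs
  x <- cos(2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2))
  out <- fq_signal(x, fs)
  attr(out, "if_hz") <- f0 + (f1 - f0) * t / duration
  out
}

#' Single-bin DCT-2 tone
#'
#' `amplitude * cos(pi k0 (2n+1) / 2N)`: the k0-th DCT-2 basis sequence, an
#' exactly on-grid tone whose forward DCT-2 has a single nonzero bin.
#'
#' @param N length.
#' @param k0 bin index `0..N-1` (`k0 = 0` gives a constant).
#' @param amplitude peak amplitude.
#' @param fs sampling rate in Hz.
#' @return An [fq_signal].
#' @export
dct_tone <- function(N, k0, amplitude = 1, fs = 1) {
  if (k0 < 0 || k0 > N - 1) stop("k0 must be in 0..N-1")
  n <- 0:(N - 1)
  fq_signal(amplitude * cos(pi * k0 * (2 * n + 1) / (2 * N)), fs)
}

#' Multicomponent AM-FM mixture with ground truth
#'
#' Sums components `a_i(t) cos(phi_i(t))` with linear IF laws
#' `f_i(t) = f_lo_i + (f_hi_i - f_lo_i) t / T` (constant when
#' `f_hi = f_lo`) and constant or slowly varying amplitudes. The per-component
#' instantaneous amplitude and frequency laws are stored as ground truth for
#' recovery tests. Components whose frequency ranges overlap are flagged.
#'
#' @param components list of lists with fields `amp` (scalar, or function of
#'   time returning the amplitude envelope), `f_lo`, `f_hi` (Hz; equal for a
#'   pure tone), and optional `phase0` (radians).
#' @param fs sampling rate in Hz.
#' @param N length.
#' @return An [fq_signal] with attributes `ia` and `if_hz` (matrices
#'   `N x n_components`) and `bands_hz` (per-component frequency ranges).
#' @export
multicomponent_amfm <- function(components, fs, N) {
  t <- (0:(N - 1)) / fs
  dur <- N / fs
  n_c <- length(components)
  x <- numeric(N)
  ia <- matrix(0, N, max(n_c, 1))
  iff <- matrix(0, N, max(n_c, 1))
  bands <- matrix(0, max(n_c, 1), 2)
  for (i in seq_len(n_c)) {
    cmp <- components[[i]]
    a <- if (is.function(cmp$amp)) cmp$amp(t) else rep(cmp$amp, N)
    f <- cmp$f_lo + (cmp$f_hi - cmp$f_lo) * t / dur
    if (max(f) > fs / 2) stop("component ", i, " exceeds Nyquist")
    ph <- (if (is.null(cmp$phase0)) 0 else cmp$phase0) +
      2 * pi * cumsum(c(0, (f[-N] + f[-1]) / 2)) / fs
    x <- x + a * cos(ph)
    ia[, i] <- a
    iff[, i] <- f
    bands[i, ] <- range(f)
  }
  if (n_c > 1) {
    o <- order(bands[, 1])
    if (any(bands[o, 1][-1] < bands[o, 2][-n_c]))
      warning("component frequency bands overlap; band-separated recovery not guaranteed")
  }
  out <- fq_signal(x, fs)
  attr(out, "ia") <- ia
  attr(out, "if_hz") <- iff
  attr(out, "bands_hz") <- bands
  out
}

# Gaussian-bump PQRST beat template: offsets (s) relative to the R peak,
# amplitudes (mV) and widths (s). Fixed documented constants.
.ecg_template <- data.frame(
  wave   = c("P", "Q", "R", "S", "T"),
  offset = c(-0.20, -0.04, 0.00, 0.04, 0.32),
  amp    = c(0.12, -0.10, 1.20, -0.25, 0.35),
  width  = c(0.045, 0.012, 0.018, 0.016, 0.070))

#' Synthetic ECG signal
#'
#' A periodic heartbeat built from five Gaussian bumps (P, Q, R, S, T waves)
#' at fixed offsets, amplitudes and widths around each R peak, with seeded
#' log-normal-free RR-interval jitter (2% coefficient of variation). A
#' deterministic, downloads-free stand-in for a clean ECG recording: its
#' spectral energy lies well above the baseline-wander band and away from
#' power-line frequencies, so band-stop denoising of a corrupted copy is
#' near-lossless.
#'
#' @param fs sampling rate in Hz (at least 100).
#' @param duration length in seconds.
#' @param heart_rate_bpm mean heart rate, beats per minute.
#' @param rr_jitter coefficient of variation of the RR intervals.
#' @param seed integer seed (RR jitter only).
#' @return An [fq_signal] with attribute `r_peaks_s` (R-peak times, s).
#' @export
synthetic_ecg <- function(fs = 360, duration = 10, heart_rate_bpm = 72,
                          rr_jitter = 0.02, seed = 1) {
  if (fs < 100) stop("fs must be at least 100 Hz for an ECG")
  rr_mean <- 60 / heart_rate_bpm
  n_beats <- ceiling(duration / rr_mean) + 2L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rr <- rr_mean * (1 + rr_jitter * stats::rnorm(n_beats))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  r_times <- cumsum(c(rr_mean / 2, rr[-n_beats]))
  r_times <- r_times[r_times < duration + 0.5]
  N <- round(fs * duration)
  t <- (0:(N - 1)) / fs
  x <- numeric(N)
  for (rt in r_times) {
    for (j in seq_len(nrow(.ecg_template))) {
      mu <- rt + .ecg_template$offset[j]
      w <- .ecg_template$width[j]
      lo <- max(1L, floor((mu - 5 * w) * fs) + 1L)
      hi <- min(N, ceiling((mu + 5 * w) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + .ecg_template$amp[j] * exp(-0.5 * ((t[idx] - mu) / w)^2)
    }
  }
  out <- fq_signal(x, fs)
  attr(out, "r_peaks_s") <- r_times[r_times <= duration]
  out
}

#' Corrupt a signal with baseline wander and power-line interference
#'
#' Adds `w[n] = BLW + PLI`, a slow sinusoidal baseline drift (default
#' 0.3 Hz) plus a power-line sinusoid (default 50 Hz), with equal energy in
#' the two parts. When `target_snr_db` is given, `w` is scaled so that the
#' input signal-to-noise ratio `10 log10(sum x^2 / sum w^2)` equals it
#' exactly; otherwise the supplied amplitudes are used as-is.
#'
#' @param x numeric vector or [fq_signal], the clean signal.
#' @param blw_hz baseline-wander frequency in Hz (below 0.5 Hz).
#' @param pli_hz power-line frequency in Hz (50 or 60 typically).
#' @param blw_amp,pli_amp amplitudes used when `target_snr_db` is `NULL`.
#' @param target_snr_db desired input SNR in dB, or `NULL`.
#' @param fs sampling rate (required for a bare vector).
#' @param seed integer seed for the sinusoid phases; `NULL` for zero phases.
#' @return list with `noisy` (numeric), `w` (the added noise, so
#'   `noisy - x == w` exactly), `blw`, `pli`, and `snr_in_db`.
#' @export
add_blw_pli <- function(x, blw_hz = 0.3, pli_hz = 50, blw_amp = 1, pli_amp = 1,
                        target_snr_db = NULL, fs = NULL, seed = NULL) {
  fs <- .fs(x, fs)
  xs <- .samples(x)
  if (blw_hz >= 0.5) warning("baseline wander is conventionally below 0.5 Hz")
  if (pli_hz >= fs / 2) stop("pli_hz must be below Nyquist")
  N <- length(xs)
  t <- (0:(N - 1)) / fs
  ph <- c(0, 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    ph <- stats::runif(2, 0, 2 * pi)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  blw <- sin(2 * pi * blw_hz * t + ph[1])
  pli <- sin(2 * pi * pli_hz * t + ph[2])
  if (is.null(target_snr_db)) {
    blw <- blw_amp * blw
    pli <- pli_amp * pli
  } else {
    ex <- sum(xs^2)
    if (ex == 0) stop("target SNR unreachable: signal has zero energy")
    e_target <- ex / 10^(target_snr_db / 10)
    # equal energy in the two noise classes
    blw <- blw / sqrt(sum(blw^2)) * sqrt(e_target / 2)
    pli <- pli / sqrt(sum(pli^2)) * sqrt(e_target / 2)
    w0 <- blw + pli
    sc <- sqrt(e_target / sum(w0^2))  # exact: the parts are not quite orthogonal
    blw <- sc * blw
    pli <- sc * pli
  }
  w <- blw + pli
  list(noisy = xs + w, w = w, blw = blw, pli = pli,
       snr_in_db = snr_input(xs, w))
}

#' Input and output signal-to-noise ratios (dB)
#'
#' `snr_input` compares the clean signal energy with the energy of the added
#' noise `w`; `snr_output` compares it with the residual energy of an
#' estimate, `10 log10(sum x^2 / sum (x - x_est)^2)`. A zero denominator
#' yields `Inf` (perfect estimate / no noise), not an error.
#'
#' @param x clean signal (numeric or [fq_signal]).
#' @param w added noise component.
#' @param x_est estimate of `x` after denoising.
#' @return scalar dB value.
#' @export
snr_input <- function(x, w) {
  x <- .samples(x); w <- .samples(w)
  ew <- sum(w^2)
  if (ew == 0) return(Inf)
  10 * log10(sum(x^2) / ew)
}

#' @rdname snr_input
#' @export
snr_output <- function(x, x_est) {
  x <- .samples(x); x_est <- .samples(x_est)
  er <- sum((x - x_est)^2)
  if (er == 0) return(Inf)
  10 * log10(sum(x^2) / er)
}
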