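---
title: "Fourier quadrature analytic signals and zero-phase decomposition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier quadrature analytic signals and zero-phase decomposition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqsig)
```

## The model

fqsig treats a sampled real signal `x[n]`, `n = 0..N-1`, at rate `fs` as a
superposition of a mean term and a small number of amplitude- and
frequency-modulated band components,

    x[n] = a0 + sum_i a_i[n] cos(phi_i[n]),

and provides the two operations this model needs: a complex (analytic)
extension from which `a_i`, `phi_i` and the instantaneous frequency
`omega_i = dphi_i/dn` can be read off, and a zero-phase band split that
isolates the components. Both are built on the discrete trigonometric
transform families rather than on the discrete Fourier transform alone.

## The sixteen trigonometric transforms

`transform_matrix()` constructs the eight orthonormal DCT and eight
orthonormal DST matrices, indexed `[sample n, frequency k]`. Forward
analysis contracts over the sample index, so for the cosine type-2 family

    X[k] = sqrt(2/N) * sigma_k * sum_n x[n] cos(pi k (2n+1) / 2N),

with `sigma_0 = 1/sqrt(2)`. The normalization constants are those that make
every family exactly orthonormal: `sqrt(2/(N-1))` for cosine type 1,
`sqrt(2/N)` for the even types, and `2/sqrt(2N-1)` or `2/sqrt(2N+1)` for the
"odd" types 5–8 (whose kernels have denominators `2N-1` or `2N+1`). Several
published tabulations of the odd types circulate with inconsistent scalings
and, for the sine types 6 and 7, with kernels that collide with type 8; the
package follows the standard orthonormal definitions (sine type 6
`~ sin(2 pi (n+1/2)(k+1) / (2N+1))`, sine type 7 its transpose) and the test
suite asserts the Gram identity `A'A = I` to `1e-10` for every family and
type at orders 4, 7 and 16. Unitarity is non-negotiable here: Parseval,
exact round trips and the filter-bank completeness below all rest on it.

Sine types 1 and 5 are naturally of order `N - 1` (their kernels vanish
identically at the index borders); the package represents them as
`(N-1) x (N-1)` matrices and expects signals of length `N - 1`, rather than
embedding them in an `N x N` matrix with zero border rows whose round trip
would silently drop a sample.

The cosine type-2 pair has a fast path: the forward transform by one
length-`N` FFT (even/odd reordering), and every synthesis — inverse
transform, quadrature, analytic form, band components — by one length-`2N`
FFT evaluating `sum_k W[k] exp(i pi k (2n+1) / 2N)`. Types other than
cosine-2 use explicit matrices; at desk scales (`N <= 4096`) this is cheap,
and the fast path is verified against the matrix path to `1e-10` in the
tests.

## Quadrature transforms and analytic signals

Each transform family has a *companion* obtained by swapping cosine for sine
in its kernel while keeping the normalization. Analysing `x` with a DCT and
re-synthesizing the coefficients on the companion sine basis yields the
Fourier cosine quadrature transform (`fcqt()`); DST analysis onto the cosine
companion gives `fsqt()`. For the type-2 pair,

    xq[n] = sqrt(2/N) * sum_{k>=1} X[k] sin(pi k (2n+1) / 2N).

The sine basis annihilates the `k = 0` coefficient, so — exactly like the
Hilbert transform — the quadrature of a constant is zero and the transform
is invertible only on the zero-mean subspace, where it is an isometry
(`invert_fcqt()` recovers `x - mean(x)`). `fcqt()`/`fsas()` deliberately do
*not* remove the mean themselves: the annihilation is a property of the
operator, and silently detrending would change what "reconstruction"
means. Callers who need invertibility subtract the mean first.

Pairing signal and quadrature gives the quadrature analytic signal
`fsas()`: `z = x + i*xq` for the cosine family (real part is the original,
bit-exact by construction) or `z = xq_s + i*x` for the sine family. On the
type-2 half-sample grid the paired bases combine into
`exp(i pi k (2n+1) / 2N)`, so on-grid tones map to unit-modulus complex
exponentials with exactly linear phase — the harmonic-correspondence
property that anchors instantaneous-frequency estimation. The spectrum is
one-sided, but unlike the classical analytic signal the real and imaginary
parts are *not* orthogonal: the cosine–sine cross inner product
(`cos_sin_inner()`) is nonzero whenever `m + k` is odd, with closed form
`(1/2)/sin(pi(m+k)/2N) + (1/2)/sin(pi(m-k)/2N)` (the second term defined as
0 at `m = k`, where the sine factor it came from vanishes identically before
any division). The closed form is checked against the brute-force sum for
all index pairs at several orders.

The classical construction is kept alongside: `gas()` zeroes the strictly
negative DFT bins, doubles the interior positive ones and keeps DC (and
Nyquist, for even `N`) unscaled. The DFT convention is the standard sum over
all `N` samples with `1/N` forward scaling, so that the DC coefficient is
the signal mean. Its textbook properties (orthogonal parts, one-sided
spectrum, quadrature-squared = negation on the DC- and Nyquist-free
subspace) are property-tested.

## Instantaneous frequency

`analytic_polar()` uses `atan2`, range `(-pi, pi]`, with `atan2(0,0) = 0` at
samples of exactly zero amplitude. `inst_frequency()` differentiates the
wrapped phase by forward, backward or central differences; each raw
one-sample difference is wrapped into `[-pi, pi]` and the positivity
correction applied (add `pi` to a negative increment), confining `omega` to
`[0, pi]` rad/sample — `[0, fs/2]` in Hz — for mono- and multicomponent
signals alike.

Two conventions here deserve justification:

* **Wrapping keeps `-pi` at `-pi`** (implemented as
  `d - 2*pi*round(d/(2*pi))`; round-half-to-even leaves both endpoints
  fixed). A one-sided difference of exactly `-pi` then corrects to 0 while
  `+pi` stays at the Nyquist rate. Mapping `-pi` to `+pi` instead would
  read *every* sign-ambiguous Nyquist-rate increment as `+pi` and bias
  staircase phases upward.
* **The central estimate is the mean of the two corrected one-sided
  differences**, not the corrected two-sample difference. For smooth phase
  laws the two coincide to machine precision (both one-sided increments fall
  in the same branch of the positivity rule). They differ exactly on the
  quantized phase staircases of sparse signals: the quadrature analytic
  signal of a unit sample has phase alternating between `-pi/2` and `+pi/2`,
  so the two-sample difference is identically zero and would report 0 Hz
  everywhere, whereas the one-sided increments are `-pi` and `+pi`,
  correcting to 0 and `pi` — mean `pi/2`, i.e. the flat mid-Nyquist ridge
  the impulse actually has. The test suite pins this: the 1000-sample delta
  at `fs = 100` yields `omega = pi/2` at 996 of 1000 samples (endpoints and
  the two samples flanking the impulse use one-sided/mixed branches), median
  exactly 25 Hz.

Endpoints always use the available one-sided difference. Samples of exactly
zero amplitude have undefined phase; `inst_descriptors()` interpolates
`omega` there linearly from the neighbouring nonzero-amplitude samples.

On a 1 s, 5–100 Hz linear chirp at 1 kHz the quadrature analytic signal
tracks the true frequency law within 1 Hz RMSE over the central 80% of the
record, and its end-of-record error is strictly smaller than the classical
analytic signal's — the practical motivation for the quadrature variant.

## The zero-phase filter bank

`select_bands()` partitions the non-DC coefficient bins `k = 1..Kmax` into
`M` contiguous bands. Conventions:

* **Bin mapping.** DCT-2 bin `k` corresponds to `f_k = k*fs/(2N)` Hz (the
  kernel advances by `pi k / N` per sample); DFT bin `k` to `k*fs/N`,
  `Kmax = floor(N/2)`. Hz-to-bin conversion rounds to the nearest bin with
  ties toward the lower bin.
* **DC handling.** Bin 0 is never inside a band; it is carried as the mean
  term `a0` and returned with the decomposition.
* **Dyadic plans** place the top band at `[fs/4, fs/2)` and halve downward;
  the lowest band absorbs everything from bin 1 up to `fs/2^M`. At
  `fs = 50`, `M = 8` the nominal edges are 0.1953125, 0.390625, 0.78125,
  1.5625, 3.125, 6.25, 12.5, 25 Hz.
* **Equal-energy plans** walk the cumulative squared-coefficient spectrum
  and close band `i` at the first bin where the running sum reaches
  `i/M` of the total (with a `1e-9` relative slack so that exact quantile
  ties — a flat spectrum splitting into equal widths — are not lost to
  round-off), always advancing at least one bin so every band is nonempty.

`fdm_decompose()` is one forward transform plus one synthesis per band
(asserted structurally in the tests by call counting). Each band's
coefficients are masked with a real non-negative gain (`zero_phase_mask()`,
binary by default, optionally Gaussian) and synthesized in analytic form:
with the quadrature construction the band component is

    z_i[n] = sqrt(2/N) * sum_{k in band i} X[k] exp(i pi k (2n+1) / 2N),

whose real part is the FIBF and imaginary part its quadrature; with the
classical construction the real FIBF is synthesized and `gas()` applied per
band. Real masks add no phase, so a signal symmetric about its midpoint
yields symmetric components (no group delay) — property-tested. Binary
masks over a partition give completeness (`a0 + sum_i Re z_i = x`) and
cross-band orthogonality to `1e-9`, and decomposition is idempotent per
band.

The application operators are thin wrappers over the same machinery:
`remove_bands()` (stop bands aligned to nearest bins; cleaned signal and
removed components partition the input exactly), `extract_trend()` (trend =
all bins with `f_k <= 1/T` plus the mean; variability the exact remainder),
`window_reconstruct()` (per-band time-domain weights), and `tfe_ridges()` /
`tfe_grid()` (per-band `{t, f, a^2}` ridges; rasterization conserves energy
exactly).

## Synthetic data: what it emulates, what it does not

The generators state the worlds the tests run in:

* `unit_sample(1000, 499, fs = 100)` — the impulse-analysis fixture.
* `linear_chirp(1000, 1, 5, 100)` — the non-stationary sweep, with the
  exact IF law attached as ground truth.
* `dct_tone()` — exactly on-grid single-bin tones (the discrete world's
  pure frequencies; note an equal-frequency tone of *different phase* is
  not a single bin).
* `multicomponent_amfm()` — band-separated AM–FM mixtures with stored
  envelopes and IF laws; recovery through the filter bank is exact to
  `1e-3` relative only when components are band-separated *and* their
  envelopes taper at the record edges (an abrupt onset leaks across bands).
* `synthetic_ecg()` — five Gaussian bumps (P, Q, R, S, T) per beat at fixed
  offsets/amplitudes/widths (constants in the source), 2% seeded RR jitter.
  It reproduces the spectral layout that matters for denoising — energy
  above 0.5 Hz and away from 50 Hz — but none of the physiological
  variability of real ECG (no respiration modulation, ectopy, or
  morphology changes), so a green denoising test establishes the operator,
  not clinical performance.
* `add_blw_pli()` — sinusoidal baseline wander (0.3 Hz default) plus mains
  interference (50 Hz default) with a 1:1 energy split, scaled exactly to a
  requested input SNR; `-18.4` dB is the heavy-corruption default.
  `snr_input()`/`snr_output()` are the plain log-energy ratios.

All generators are deterministic given their seed; the ECG and corruption
generators save and restore the caller's RNG state.

## Numerical choices

* Orthogonality, round-trip and completeness tolerances: `1e-10` (`1e-9`
  where a chain of FFTs is involved); double precision at `N <= 4096`.
* Hz-to-bin ties round toward the lower bin, everywhere, so CLI and library
  agree.
* The WAV reader/writer is a minimal RIFF implementation (PCM 8/16/32-bit
  and IEEE float, first channel) because no WAV package is available in the
  dependency set; CSV carries an explicit time column or an `fs` flag, with
  a warning above 1% timing jitter.
* The repeatable `--stop` flag of the CLI is collected by a manual pre-scan
  (the option parser used retains only the last occurrence of a repeated
  flag).

## Limitations

* Only type 2 has a fast transform path; types 5–8 are `O(N^2)` by design
  (no standard fast algorithm at these scalings) and intended for desk-size
  `N`.
* The quadrature analytic signal's real and imaginary parts are not
  orthogonal, so energy read from `|z|^2` is not additive across the two
  parts in the way classical analytic-signal energy is; TFE plots use
  `|z|^2` as-is.
* The one-sided-spectrum claim for the quadrature representations is exact
  on the on-grid harmonic pairs; off-grid tones show leakage, which is
  documented rather than asserted in tests.
* Band-stop denoising removes everything in the stop band, including any
  genuine signal energy there; stop bands should be as narrow as the
  interference allows.
* 2-D extensions, modified (lapped) DCTs and FIR-filter-bank variants of
  the decomposition are out of scope.
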