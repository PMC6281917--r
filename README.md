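# fqsig

Time–frequency–energy analysis and denoising of non-stationary 1-D signals
(ECG, speech-like, seismic, climate series) built on trigonometric transforms
and zero-phase filter banks.

## What it does

Many physiological and geophysical signals are well modelled as a
superposition of amplitude- and frequency-modulated components,
`x[n] = a0 + Σ_i a_i[n] cos(φ_i[n])`. Analysing them needs two ingredients:

1. **An analytic (complex) extension** of the real signal, from which
   instantaneous amplitude `a[n] = |z[n]|`, phase
   `φ[n] = atan2(Im z, Re z)` and frequency `ω[n] = φ'[n]` are read off.
   Besides the classical one-sided-spectrum (Gabor) analytic signal
   (`gas()`), the package implements *Fourier quadrature transforms*: the
   signal is analysed with one of the eight orthonormal DCTs (or DSTs) and
   re-synthesized on the companion sine (cosine) basis, giving a
   Hilbert-like quadrature (`fcqt()`, `fsqt()`) and sixteen quadrature
   analytic-signal representations (`fsas()`). Like the Gabor construction
   these have one-sided spectra; unlike it, the real and imaginary parts are
   not orthogonal — and the quadrature variant is markedly less prone to
   end-of-record artifacts in instantaneous-frequency estimation.
2. **A decomposition into band components.** The Fourier decomposition
   method (`fdm_decompose()`) masks the DCT-2 (or DFT) coefficients with
   real, non-negative, zero-phase gains `H_i[k]` over contiguous bin bands
   (`select_bands()`: equal, dyadic, equal-energy or custom bands) and
   synthesizes each band back to the time domain as a Fourier intrinsic band
   function (FIBF) with its analytic companion. The components are complete
   (`a0 + Σ_i x_i = x`), mutually orthogonal, and free of group delay, which
   makes band-stop denoising (`remove_bands()`), trend extraction at an
   exact timescale (`extract_trend()`), windowed reconstruction
   (`window_reconstruct()`) and time-frequency-energy ridges
   (`tfe_ridges()`) one-liners.

Synthetic generators (`unit_sample()`, `linear_chirp()`, `dct_tone()`,
`multicomponent_amfm()`, `synthetic_ecg()`, `add_blw_pli()`) provide
deterministic fixtures with known ground truth, so the whole pipeline is
testable without external recordings. A CLI (`inst/exec/fqsig`, or
`run_cli()` from R) wraps the main operations for shell use.

## Worked example: ECG denoising

A synthetic ECG is corrupted with 0.3 Hz baseline wander plus 50 Hz mains
interference down to −18.4 dB, then cleaned with two zero-phase stop bands:

```r
library(fqsig)

ecg  <- synthetic_ecg(fs = 500, duration = 10, heart_rate_bpm = 72, seed = 1)
corr <- add_blw_pli(ecg, blw_hz = 0.3, pli_hz = 50,
                    target_snr_db = -18.4, seed = 1)
res  <- remove_bands(fq_signal(corr$noisy, 500), list(c(0, 0.5), c(49, 51)))

sprintf("input SNR: %.2f dB", corr$snr_in_db)        # "input SNR: -18.40 dB"
sprintf("output SNR: %.2f dB", snr_output(ecg, res$clean))  # "output SNR: 8.57 dB"
```

The cleaned trace recovers the PQRST morphology (27 dB of improvement), and
`res$removed` holds the separated baseline and mains components.

Impulse analysis — the quadrature analytic signal pins both the time and the
frequency of a unit sample:

```r
s <- unit_sample(N = 1000, n0 = 499, fs = 100)
d <- inst_descriptors(fsas(s), method = "cfd")
median(d$f_hz)          # 25  (half the Nyquist frequency, fs/4)
d$t[which.max(d$ia)]    # 4.99 s (the impulse position)
```

Dyadic band planning at `fs = 50` Hz:

```r
select_bands(N = 1000, fs = 50, M = 8, strategy = "dyadic")$edges_hz
# 0 0.1953125 0.390625 0.78125 1.5625 3.125 6.25 12.5 25
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's desk-scale reference
computations from scratch — the orthogonality of the one-sided-spectrum
analytic signal's real and imaginary parts on a seeded zero-mean signal, and
the lowest-band cutoff of the 8-band dyadic plan at 50 Hz — and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

```sh
fqsig synth delta --N 1000 --n0 499 --fs 100 --out delta.csv
fqsig analytic --input delta.csv --kind fsas2 --if cfd --out out/
fqsig decompose --input signal.csv --M 8 --bands dyadic --out out/
fqsig denoise --input noisy.csv --stop 0-0.5 --stop 49-51 --truth clean.csv --out out/
fqsig trend --input gsta.csv --timescale 64 --out out/
fqsig tfe --input signal.csv --M 6 --grid 64 --out out/
```

See the methods vignette (`vignettes/fourier-quadrature-decomposition.Rmd`)
for the model, parameter conventions, numerical choices and limitations.
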