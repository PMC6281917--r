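Package: fqsig
Title: Fourier Quadrature Transforms and Zero-Phase Fourier Decomposition of
    Non-Stationary Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-frequency-energy analysis and denoising of non-stationary
    one-dimensional signals (ECG, speech-like, seismic, climate series).
    Implements the eight discrete cosine and eight discrete sine orthonormal
    transforms, their sixteen Fourier quadrature transforms and quadrature
    analytic-signal representations, the classical one-sided-spectrum (Gabor)
    analytic signal, instantaneous amplitude/phase/frequency estimation by
    finite phase differences, and the Fourier decomposition method: a
    zero-phase DCT/DFT filter bank that splits a signal into Fourier intrinsic
    band functions with equal, dyadic, equal-energy or custom frequency bands.
    Includes application operators for baseline-wander and
    power-line-interference removal from ECG, trend/variability extraction at
    a chosen timescale, windowed band reconstruction, synthetic fixture
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
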