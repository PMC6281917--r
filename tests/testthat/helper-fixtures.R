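# Brute-force oracles built independently of the package internals.

# direct evaluation of the DCT-2 analysis formula
brute_dct2 <- function(x) {
  N <- length(x)
  sapply(0:(N - 1), function(k) {
    s <- if (k == 0) 1 / sqrt(2) else 1
    sqrt(2 / N) * s * sum(x * cos(pi * k * (2 * (0:(N - 1)) + 1) / (2 * N)))
  })
}

# direct evaluation of the type-2 cosine quadrature synthesis
brute_fcqt2 <- function(x) {
  N <- length(x)
  X <- brute_dct2(x)
  sapply(0:(N - 1), function(n) {
    sqrt(2 / N) * sum(X * sin(pi * (0:(N - 1)) * (2 * n + 1) / (2 * N)))
  })
}

all_families <- expand.grid(family = c("cosine", "sine"), type = 1:8,
                            stringsAsFactors = FALSE)
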