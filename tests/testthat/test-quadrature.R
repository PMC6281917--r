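test_that("quadrature matrix entries match direct evaluation", {
  Q <- quadrature_matrix("sine", 2, 4)
  expect_equal(Q$entries[1, 2], sqrt(2 / 4) * sin(pi / 8), tolerance = 1e-12)
  expect_equal(round(Q$entries[1, 2], 4), 0.2706)
  # column k = 0 of the type-2 sine companion is identically zero
  for (N in c(4, 9, 16))
    expect_true(all(quadrature_matrix("sine", 2, N)$entries[, 1] == 0))
  # its columns 1..N-1 are orthonormal (sine-basis Gram = diag(0, N/2, ...))
  Q8 <- quadrature_matrix("sine", 2, 8)$entries
  G <- crossprod(Q8[, -1])
  expect_lt(max(abs(G - diag(7))), 1e-10)
  n <- 0:7
  raw <- sapply(0:7, function(k) sin(pi * k * (2 * n + 1) / 16))
  G_raw <- crossprod(raw)
  want <- diag(c(0, rep(4, 7)))
  expect_lt(max(abs(G_raw - want)), 1e-12)
})

test_that("FCQT annihilates constants and maps cosine bases to sine bases", {
  N <- 16; n <- 0:(N - 1)
  expect_lt(max(abs(fcqt(rep(3.7, N)))), 1e-12)
  for (k0 in 1:(N - 1)) {
    got <- fcqt(cos(pi * k0 * (2 * n + 1) / (2 * N)))
    expect_lt(max(abs(got - sin(pi * k0 * (2 * n + 1) / (2 * N)))), 1e-10,
              label = sprintf("harmonic correspondence k0=%d", k0))
  }
})

test_that("FCQT of a shifted delta matches the frozen worked value", {
  got <- fcqt(c(0, 1, 0, 0))
  expect_equal(round(got, 4), c(-0.6036, 0.1036, 0.6036, -0.1036))
  expect_equal(got, brute_fcqt2(c(0, 1, 0, 0)), tolerance = 1e-12)
  # fast path == matrix composition for every cosine type
  set.seed(5)
  x <- rnorm(10)
  for (tp in 1:8) {
    A <- transform_matrix("cosine", tp, 10)
    Q <- quadrature_matrix("sine", tp, 10)
    expect_equal(fcqt(x, tp), drop(Q$entries %*% crossprod(A$entries, x)),
                 tolerance = 1e-12, label = sprintf("fcqt type %d", tp))
  }
})

test_that("FCQT is linear and an isometry on zero-mean signals", {
  set.seed(42)
  for (i in 1:10) {
    N <- sample(8:64, 1)
    x <- rnorm(N); y <- rnorm(N)
    al <- rnorm(1); be <- rnorm(1)
    expect_lt(max(abs(fcqt(al * x + be * y) - al * fcqt(x) - be * fcqt(y))),
              1e-10)
    x0 <- x - mean(x)
    expect_equal(sqrt(sum(fcqt(x0)^2)), sqrt(sum(x0^2)), tolerance = 1e-10)
  }
})

test_that("FSQT mirrors FCQT: DST analysis onto the cosine companion basis", {
  # a DST-2 basis vector maps to the corresponding cosine companion column
  N <- 12
  S <- transform_matrix("sine", 2, N)
  Ct <- quadrature_matrix("cosine", 2, N)
  for (k0 in c(1, 5, 11)) {
    expect_equal(fsqt(S$entries[, k0]), Ct$entries[, k0], tolerance = 1e-10,
                 label = sprintf("fsqt basis k0=%d", k0))
  }
  expect_equal(fsqt(numeric(12) + 0), numeric(12))
  # reduced-order types accept length N-1 input
  expect_length(fsqt(rnorm(7), type = 1), 7)
  expect_length(fsqt(rnorm(7), type = 5), 7)
})

test_that("FSAS carries the original signal exactly and is analytic on tones", {
  N <- 32; n <- 0:(N - 1)
  set.seed(9); x <- rnorm(N)
  zc <- fsas(x)
  expect_identical(Re(zc$values), x)          # bit-exact real part
  expect_identical(zc$original_part, "real")
  zs <- fsas(x, family = "sine")
  expect_identical(Im(zs$values), x)
  expect_identical(zs$original_part, "imaginary")
  # harmonic correspondence: cosine basis k0 -> complex exponential
  for (k0 in c(1, 4, 13)) {
    z <- fsas(cos(pi * k0 * (2 * n + 1) / (2 * N)))
    expect_lt(max(abs(z$values - exp(1i * pi * k0 * (2 * n + 1) / (2 * N)))),
              1e-10)
    expect_lt(max(abs(Mod(z$values) - 1)), 1e-10)
    # linear phase of slope pi * k0 / N per sample
    ph <- atan2(Im(z$values), Re(z$values))
    d <- diff(ph); d <- d - 2 * pi * round(d / (2 * pi))
    expect_lt(max(abs(d - pi * k0 / N)), 1e-9)
  }
  # real and imaginary parts are NOT orthogonal (unlike the classical GAS)
  mix <- dct_tone(N, 1)$samples + dct_tone(N, 2)$samples
  zmix <- fsas(mix)
  expect_gt(abs(sum(Re(zmix$values) * Im(zmix$values))), 1)
})

test_that("the type-2 FCQT inverts exactly on the zero-mean subspace", {
  set.seed(17)
  x <- rnorm(40)
  x0 <- x - mean(x)
  expect_lt(max(abs(invert_fcqt(fcqt(x0)) - x0)), 1e-10)
  # non-zero-mean input: the mean is unrecoverable, remainder is exact
  expect_lt(max(abs(invert_fcqt(fcqt(x)) - x0)), 1e-10)
  # constant input maps to zero and back to zero
  expect_lt(max(abs(invert_fcqt(fcqt(rep(4, 16))))), 1e-12)
})

test_that("closed-form cosine-sine cross inner product matches brute force", {
  expect_equal(cos_sin_inner(2, 2, 8), 0)
  expect_equal(cos_sin_inner(1, 3, 8), 0)       # m+k and m-k both even
  expect_equal(round(cos_sin_inner(1, 2, 4), 4), 1.8478)
  for (N in c(4, 8, 11)) {
    n <- 0:(N - 1)
    for (k in 0:(N - 1)) for (m in 0:(N - 1)) {
      brute <- sum(cos(pi * k * (2 * n + 1) / (2 * N)) *
                   sin(pi * m * (2 * n + 1) / (2 * N)))
      expect_equal(cos_sin_inner(k, m, N), brute, tolerance = 1e-9,
                   label = sprintf("cross inner product k=%d m=%d N=%d", k, m, N))
    }
  }
  expect_error(cos_sin_inner(0, 9, 8), "indices")
})
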