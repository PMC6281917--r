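test_that("dyadic band planning reproduces the canonical fs = 50, M = 8 edge list", {
  p <- select_bands(N = 1000, fs = 50, M = 8, strategy = "dyadic")
  expect_equal(p$edges_hz,
               c(0, 0.1953125, 0.390625, 0.78125, 1.5625, 3.125, 6.25, 12.5, 25))
  expect_equal(round(p$edges_hz[2], 4), 0.1953)
  # bands are contiguous, non-overlapping and cover k = 1 .. N-1
  expect_equal(unname(p$bands[1, "k_lo"]), 1L)
  expect_equal(unname(p$bands[8, "k_hi"]), 999L)
  expect_true(all(p$bands[-1, "k_lo"] == utils::head(p$bands[, "k_hi"], -1) + 1L))
})

test_that("equal and equal-energy planning split the bin range as specified", {
  p <- select_bands(N = 9, fs = 1, M = 2, strategy = "equal")
  expect_equal(unname(p$bands), rbind(c(1L, 4L), c(5L, 8L)))
  # flat-spectrum input: equal-energy boundaries coincide with equal widths
  N <- 17
  X <- c(0, rep(1, N - 1))
  x_flat <- idct2(X)
  pe <- select_bands(N, 1, M = 4, strategy = "equal_energy", x = x_flat)
  expect_equal(unname(pe$bands[, 2] - pe$bands[, 1] + 1L), rep(4L, 4))
  expect_error(select_bands(N, 1, M = 4, strategy = "equal_energy"), "requires")
  expect_error(select_bands(8, 1, M = 20, strategy = "equal"), "between")
})

test_that("zero-phase masks are binary partitions (or non-negative Gaussians)", {
  expect_equal(zero_phase_mask(c(3, 5), 8), c(0, 0, 0, 1, 1, 1, 0, 0))
  # the masks of a plan tile k = 1..Kmax exactly once and exclude DC
  p <- select_bands(64, 10, M = 5, strategy = "equal")
  msum <- Reduce(`+`, lapply(seq_len(5), function(i)
    zero_phase_mask(p$bands[i, ], 64)))
  expect_equal(msum, c(0, rep(1, 63)))
  g <- zero_phase_mask(c(10, 20), 64, shape = "gaussian")
  expect_true(all(g >= 0))
  expect_error(zero_phase_mask(c(5, 3), 8), "band")
})

test_that("decomposition is complete, orthogonal across bands, and separates tones", {
  set.seed(14)
  for (basis in c("dct2", "dft")) {
    for (analytic in c("fsas", "gas")) {
      x <- rnorm(200)
      p <- select_bands(200, 100, M = 6, strategy = "equal", basis = basis)
      f <- fdm_decompose(x, p, analytic = analytic)
      # completeness: a0 + sum of real parts = x
      expect_lt(max(abs(fdm_reconstruct(f) - x)), 1e-9 * max(abs(x)),
                label = paste("completeness", basis, analytic))
      # cross-band orthogonality
      xi <- sapply(f$components, Re)
      for (i in 1:5) for (j in (i + 1):6) {
        expect_lt(abs(sum(xi[, i] * xi[, j])),
                  1e-9 * sqrt(sum(xi[, i]^2) * sum(xi[, j]^2)),
                  label = sprintf("orthogonality %s/%s bands %d,%d",
                                  basis, analytic, i, j))
      }
    }
  }
  # exact two-tone separation with a split at k = 7
  N <- 64; n <- 0:(N - 1)
  t1 <- cos(pi * 3 * (2 * n + 1) / (2 * N))
  t2 <- cos(pi * 11 * (2 * n + 1) / (2 * N))
  p2 <- select_bands(N, 1, strategy = "custom",
                     edges_hz = c(0, 7 / (2 * N), 0.5))
  expect_equal(unname(p2$bands), rbind(c(1L, 7L), c(8L, 63L)))
  f2 <- fdm_decompose(t1 + t2, p2)
  expect_lt(max(abs(Re(f2$components[[1]]) - t1)), 1e-10)
  expect_lt(max(abs(Re(f2$components[[2]]) - t2)), 1e-10)
  # single full band returns the zero-mean signal
  set.seed(15); y <- rnorm(50) + 3
  f1 <- fdm_decompose(y, select_bands(50, 1, M = 1, strategy = "equal"))
  expect_lt(max(abs(Re(f1$components[[1]]) - (y - mean(y)))), 1e-9)
  expect_equal(f1$a0, mean(y), tolerance = 1e-12)
})

test_that("reconstruction subsets behave linearly", {
  set.seed(25)
  x <- rnorm(128)
  f <- fdm_decompose(x, select_bands(128, 1, M = 4, strategy = "equal"))
  expect_lt(max(abs(fdm_reconstruct(f) - x)), 1e-9)
  expect_equal(fdm_reconstruct(f, include = integer(0)), rep(f$a0, 128))
  expect_equal(fdm_reconstruct(f, include = integer(0), with_mean = FALSE),
               rep(0, 128))
  # complement identity: x - band 2 = reconstruction without band 2
  expect_lt(max(abs(fdm_reconstruct(f, include = c(1, 3, 4)) -
                    (x - Re(f$components[[2]])))), 1e-9)
})

test_that("zero-phase filtering preserves midpoint symmetry and is idempotent per band", {
  # symmetric input -> every binary-mask FIBF symmetric about the midpoint
  set.seed(33)
  half <- rnorm(32)
  x <- c(half, rev(half))
  f <- fdm_decompose(x, select_bands(64, 1, M = 4, strategy = "equal"))
  for (i in 1:4) {
    xi <- Re(f$components[[i]])
    expect_lt(max(abs(xi - rev(xi))), 1e-9, label = paste("symmetry band", i))
  }
  # decomposing a FIBF again returns it in its own band and ~0 elsewhere
  plan <- select_bands(64, 1, M = 4, strategy = "equal")
  fi <- Re(f$components[[2]])
  f_again <- fdm_decompose(fi, plan)
  expect_lt(max(abs(Re(f_again$components[[2]]) - fi)), 1e-9)
  for (i in c(1, 3, 4))
    expect_lt(max(abs(Re(f_again$components[[i]]))), 1e-9)
})

test_that("decomposition costs one analysis plus one synthesis per band", {
  x <- rnorm(256)
  p <- select_bands(256, 1, M = 7, strategy = "equal")
  fqsig:::.count_reset()
  fdm_decompose(x, p, analytic = "fsas")
  counts <- fqsig:::.count_get()
  expect_equal(counts$analysis, 1L)
  expect_equal(counts$synthesis, 7L)
})

test_that("band-stop removal cleans a corrupted ECG and partitions exactly", {
  ecg <- synthetic_ecg(fs = 500, duration = 10, heart_rate_bpm = 72, seed = 2)
  cor <- add_blw_pli(ecg, blw_hz = 0.3, pli_hz = 50, target_snr_db = -18.4,
                     seed = 2)
  noisy <- fq_signal(cor$noisy, ecg$fs)
  res <- remove_bands(noisy, list(c(0, 0.5), c(49, 51)))
  # the denoised output is strictly better than the corrupted input
  expect_gt(snr_output(ecg, res$clean), cor$snr_in_db)
  # clean + removed components reassemble the input exactly
  total <- res$clean + Reduce(`+`, res$removed)
  expect_lt(max(abs(total - cor$noisy)), 1e-9)
  # empty stop list is the identity
  res0 <- remove_bands(noisy, list())
  expect_identical(res0$clean, cor$noisy)
  expect_warning(remove_bands(noisy, list(c(0, 0.5), c(0.3, 1))), "overlap")
})

test_that("trend extraction keeps slow oscillations and drops fast ones", {
  fs <- 1                                     # annual sampling
  N <- 200
  # on-grid tones: bin k0 has period 2N/k0 samples, so k0 = 4 -> 100 periods
  slow <- 0.4 * dct_tone(N, 4)$samples        # 100-period tone
  fast <- 0.7 * dct_tone(N, 100)$samples      # 4-period tone
  r1 <- extract_trend(2 + slow, timescale = 64, fs = fs)
  expect_lt(max(abs(r1$trend - (2 + slow))), 1e-9)
  expect_lt(max(abs(r1$variability)), 1e-9)
  r2 <- extract_trend(2 + fast, timescale = 64, fs = fs)
  expect_lt(max(abs(r2$trend - 2)), 1e-9)     # trend reduces to the mean
  # exact additive split
  x <- slow + fast
  r3 <- extract_trend(x, timescale = 10, fs = fs)
  expect_equal(r3$trend + r3$variability, x, tolerance = 1e-12)
  expect_error(extract_trend(x, timescale = 1, fs = fs), "Nyquist")
})

test_that("windowed reconstruction reduces to plain reconstruction and localizes energy", {
  set.seed(77)
  x <- rnorm(128)
  f <- fdm_decompose(x, select_bands(128, 64, M = 4, strategy = "equal"))
  ones <- replicate(4, rep(1, 128), simplify = FALSE)
  expect_equal(window_reconstruct(f, ones),
               fdm_reconstruct(f, with_mean = FALSE), tolerance = 1e-12)
  zeros <- replicate(4, rep(0, 128), simplify = FALSE)
  expect_equal(window_reconstruct(f, zeros), rep(0, 128))
  # a Gaussian window concentrates the component energy near its centre
  n <- 0:127; w <- exp(-0.5 * ((n - 64) / 10)^2)
  y <- window_reconstruct(f, list(w), include = 2)
  inside <- sum(y[55:75]^2); outside <- sum(y[-(55:75)]^2)
  base_in <- sum(Re(f$components[[2]])[55:75]^2)
  base_out <- sum(Re(f$components[[2]])[-(55:75)]^2)
  expect_gt(inside / max(outside, 1e-300), base_in / base_out)
  expect_error(window_reconstruct(f, list(w[-1]), include = 2), "length N")
})
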