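test_that("Fourier features reproduce closed-form spectra", {
  # constant signal: all energy in the DC bin, which is bin Nf under the
  # 1-based index convention
  d <- dft_features(c(3, 3, 3, 3))
  expect_equal(Mod(d[4]), 12, tolerance = 1e-12)
  expect_equal(Mod(d[1:3]), rep(0, 3), tolerance = 1e-12)
  # unit impulse: flat magnitude spectrum
  expect_equal(Mod(dft_features(c(1, 0, 0, 0))), rep(1, 4), tolerance = 1e-12)
})

test_that("transforms match independent brute-force oracles", {
  set.seed(11)
  for (n in c(8L, 17L, 32L, 64L)) {
    x <- stats::rnorm(n)
    expect_equal(dft_features(x), oracle_dft(x), tolerance = 1e-10)
    expect_equal(dct_features(x, "standard_dct2"), oracle_dct2(x), tolerance = 1e-10)
    expect_equal(dct_features(x, "paper_literal"), oracle_dct_literal(x), tolerance = 1e-12)
    for (m in c(2L, 3L, 5L, 8L)) {
      for (pad in c("zero", "reflect")) {
        expect_equal(
          conv_features(x, m = m, la = 0.01, padding = pad),
          oracle_conv(x, m, 0.01, pad),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("the literal cosine transform matches its hand-derived form on ones", {
  n <- 8L
  i <- seq_len(n)
  expect_equal(
    dct_features(rep(1, n), "paper_literal"),
    cos((2 * i + 1) * pi / (2 * n)) / 2,
    tolerance = 1e-12
  )
  expect_equal(dct_features(numeric(6), "paper_literal"), numeric(6))
  expect_equal(dct_features(numeric(6), "standard_dct2"), numeric(6))
})

test_that("lrelu follows its two branches and boundary", {
  expect_identical(lrelu(5, 0.01), 5)
  expect_identical(lrelu(-1, 0.01), -0.01)
  expect_identical(lrelu(0, 0.5), 0)
  expect_equal(lrelu(c(-2, 0, 2), 0.1), c(-0.2, 0, 2))
})

test_that("the windowed convolution applies the printed ramp kernel", {
  # m = 2 on all-ones: interior taps are 0, 1, 2 -> value 3
  expect_equal(conv_features(c(1, 1, 1), m = 2, padding = "zero"), c(1, 3, 3))
  expect_equal(conv_features(numeric(10) , m = 4), numeric(10))
  expect_error(conv_features(c(1, 2), m = 5), "exceeds")
})

test_that("Fourier, convolution and wavelet transforms are homogeneous", {
  set.seed(4)
  x <- stats::rnorm(32)
  a <- -2.5
  expect_equal(dft_features(a * x), a * dft_features(x), tolerance = 1e-12)
  expect_equal(conv_features(a * x, m = 3), a * conv_features(x, m = 3), tolerance = 1e-12)
  wx <- wavelet_features(x, 2)
  wax <- wavelet_features(a * x, 2)
  expect_equal(wax$wa, a * wx$wa, tolerance = 1e-12)
  expect_equal(wax$wd, a * wx$wd, tolerance = 1e-12)
})

test_that("Gabor responses obey linearity, the envelope-free limit and rotation symmetry", {
  set.seed(5)
  x <- stats::rnorm(48)
  g0 <- gabor_config()
  expect_equal(unname(gabor_response(numeric(48), g0, fs = 8)), rep(0, 4))

  # sigma -> Inf with delta = 0, phi = 0 degenerates to a plain cosine
  # correlation with the embedding, computed here by direct summation
  glim <- gabor_config(sigma = 1e9, delta = 0, phi = 0, c = 40, n_lags = 8)
  resp <- gabor_response(x, glim, fs = 8)
  L <- 8L
  nc <- length(x) - L + 1L
  E <- sapply(seq_len(nc), function(t) x[t:(t + L - 1L)])
  lambda <- 40 / 8
  cx <- (seq_len(nc) - (nc + 1) / 2)
  direct <- 0
  for (r in seq_len(L)) for (cc in seq_len(nc)) {
    direct <- direct + cos(2 * pi * cx[cc] / lambda) * E[r, cc]
  }
  expect_equal(unname(resp), direct, tolerance = 1e-8)

  # responses at delta and delta + pi agree for the centred embedding
  for (d in c(0.3, 1.1)) {
    ga <- gabor_config(delta = d, phi = 0, n_lags = 8)
    gb <- gabor_config(delta = d + pi, phi = 0, n_lags = 8)
    expect_equal(
      abs(unname(gabor_response(x, ga, fs = 8))),
      abs(unname(gabor_response(x, gb, fs = 8))),
      tolerance = 1e-10
    )
  }
  expect_error(gabor_response(stats::rnorm(4), gabor_config(n_lags = 16), fs = 8), "too short")
})

test_that("the spectrogram embedding is accepted", {
  set.seed(6)
  x <- stats::rnorm(64)
  g <- gabor_config(embedding = "spectrogram")
  expect_length(gabor_features(x, g, fs = 8), 4L)
})

test_that("wavelet analysis halves, reconstructs and annihilates constants", {
  w <- wavelet_features(c(1, 3), levels = 1)
  expect_equal(w$wa, 2)
  expect_equal(w$wd, -1)

  set.seed(7)
  x <- stats::rnorm(16)
  w1 <- wavelet_features(x, levels = 1)
  odd <- x[seq(1, 15, 2)]
  even <- x[seq(2, 16, 2)]
  expect_equal(w1$wa + w1$wd, odd)
  expect_equal(w1$wa - w1$wd, even)

  wc <- wavelet_features(rep(4.2, 16), levels = 3)
  expect_equal(wc$wd, rep(0, 14))
  expect_warning(wavelet_features(c(1, 2, 3), levels = 1), "odd length")
  expect_error(wavelet_features(numeric(0)), "empty")
})

test_that("the BFV is a deterministic, fully attributed concatenation", {
  ds <- generate_dataset(tiny_synth(n_subjects = 2), seed = 9)
  b1 <- build_bfv(ds[[1]])
  b2 <- build_bfv(ds[[1]])
  expect_identical(b1$values, b2$values)
  expect_identical(nrow(b1$provenance), length(b1$values))
  expect_true(all(is.finite(b1$values)))
  # categories appear alphabetically and transforms in the fixed order
  expect_identical(unique(b1$provenance$category), sort(names(ds[[1]]$series)))
  expect_identical(
    unique(b1$provenance$transform[b1$provenance$category == "activity"]),
    c("DFT", "DCT", "CONV", "GABOR", "WA", "WD")
  )

  # dropping one category removes exactly that category's block
  rec <- ds[[1]]$series
  b_full <- build_bfv(rec)
  b_less <- build_bfv(rec[names(rec) != "motion"])
  motion_count <- sum(b_full$provenance$category == "motion")
  expect_identical(length(b_full$values) - length(b_less$values), motion_count)
  expect_error(build_bfv(list()), "named")
})
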