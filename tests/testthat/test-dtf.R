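freqs_grid <- seq(1, 30, 0.5)

test_that("the spectral transfer matrix obeys its closed forms", {
  # zero coefficients: H(f) is the identity at every frequency
  H0 <- transferFunction(mvarModel(list(matrix(0, 3, 3))), freqs_grid, 250)
  for (fi in c(1, 20, 59))
    expect_equal(H0@H[, , fi], diag(3) + 0i, ignore_attr = TRUE)

  # triangular coefficients: no path 2 -> 1, so H_12 = 0 everywhere
  A1 <- matrix(c(0.5, 0.4, 0, 0.3), 2)    # A1[2,1] = 0.4: channel 1 -> 2
  Ht <- transferFunction(mvarModel(list(A1)), freqs_grid, 250)
  expect_lt(max(Mod(Ht@H[1, 2, ])), 1e-12)
  expect_gt(max(Mod(Ht@H[2, 1, ])), 0)

  # univariate AR(1): |H|^2 = 1 / |1 - a exp(-i 2 pi f / fs)|^2
  a <- 0.5; fs <- 250
  H1 <- transferFunction(mvarModel(list(matrix(a, 1, 1))), freqs_grid, fs)
  expected <- 1 / Mod(1 - a * exp(-2i * pi * freqs_grid / fs))^2
  expect_equal(as.vector(Mod(H1@H[1, 1, ])^2), expected, tolerance = 1e-12)
})

test_that("gamma^2 is row-normalized and recovers structural direction", {
  Ht <- transferFunction(mvarModel(list(matrix(c(0.5, 0.4, 0, 0.3), 2))),
                         freqs_grid, 250)
  d <- dtf(Ht)
  expect_true(all(d@gamma2[1, 2, ] == 0))
  expect_true(all(d@gamma2[2, 1, ] > 0))
  rowsums <- apply(d@gamma2, c(1, 3), sum)
  expect_lt(max(abs(rowsums - 1)), 1e-10)

  dI <- dtf(transferFunction(mvarModel(list(matrix(0, 3, 3))), freqs_grid, 250))
  for (fi in c(1, 30)) expect_equal(dI@gamma2[, , fi], diag(3), ignore_attr = TRUE)
})

test_that("row normalization holds for random stable models", {
  set.seed(51)
  worst <- max(replicate(25, {
    A <- random_stable_mvar(4, 2)
    d <- dtf(transferFunction(mvarModel(A), freqs_grid, 250))
    max(abs(apply(d@gamma2, c(1, 3), sum) - 1))
  }))
  expect_lt(worst, 1e-10)
})

test_that("dtfMean averages in-band bins, then epochs", {
  k <- 2
  mk <- function(val) {
    g <- array(0, dim = c(k, k, length(freqs_grid)))
    g[1, 1, ] <- 1 - val; g[1, 2, ] <- val; g[2, 2, ] <- 1
    new("DTFResult", freqs = freqs_grid, gamma2 = g, k = 2L)
  }
  expect_equal(dtfMean(mk(0.2), "delta")[1, 2], 0.2)
  expect_equal(dtfMean(list(mk(0.2), mk(0.4)), "delta")[1, 2], 0.3)

  # a band covering a single bin returns that bin
  one <- mk(0.3)
  one@gamma2[1, 2, ] <- seq_along(freqs_grid) / 100
  one@gamma2[1, 1, ] <- 1 - one@gamma2[1, 2, ]
  expect_equal(dtfMean(one, c(10, 10.5))[1, 2],
               one@gamma2[1, 2, which(freqs_grid == 10)])
  expect_error(dtfMean(one, c(40, 45)), "no grid frequencies")
})

test_that("the C++ band DTF matches the R reference path", {
  set.seed(61)
  A <- random_stable_mvar(4, 2)
  x <- simulateMVAR(A, 1250)
  bf <- all_band_freqs()
  cppOut <- eegdtf:::cpp_epoch_band_dtf(list(x), 2L, 250, bf)
  fit <- fitMVAR(x, 2)
  d <- dtf(transferFunction(fit, freqs_grid, 250))
  bands <- eegBands()
  for (b in seq_len(3)) {
    rOut <- dtfMean(d, c(bands$lo[b], bands$hi[b]))
    expect_equal(cppOut[, , b], rOut, tolerance = 1e-10, ignore_attr = TRUE)
  }

  # min-norm fallback agrees on rank-deficient (average-referenced) data too
  xr <- sweep(x, 2, colMeans(x))
  cppR <- eegdtf:::cpp_epoch_band_dtf(list(xr), 2L, 250, bf)
  fitR <- fitMVAR(xr, 2, onDeficient = "minnorm")
  dR <- dtf(transferFunction(fitR, freqs_grid, 250))
  expect_equal(cppR[, , 1], dtfMean(dR, "delta"), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("estimated DTF converges to the analytic DTF of the generating model", {
  A1 <- matrix(c(0.5, 0.4, 0, 0.3), 2)
  set.seed(71)
  x <- simulateMVAR(list(A1), 5000)
  est <- dtf(transferFunction(fitMVAR(x, 1), freqs_grid, 250))
  truth <- dtf(transferFunction(mvarModel(list(A1)), freqs_grid, 250))
  expect_lt(max(abs(est@gamma2 - truth@gamma2)), 0.05)
  expect_lt(max(est@gamma2[1, 2, ]), 0.02)   # structurally zero reverse edge
})
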