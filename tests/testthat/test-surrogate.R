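test_that("phase randomization preserves amplitude spectra exactly", {
  set.seed(81)
  x <- matrix(rnorm(3 * 1000), 3)
  s <- phaseRandomize(x)
  expect_equal(dim(s), dim(x))
  for (ch in 1:3) {
    a0 <- Mod(fft(x[ch, ])); a1 <- Mod(fft(s[ch, ]))
    expect_lt(max(abs(a1 - a0)) / max(a0), 1e-8)
  }
  # odd length and vector input
  v <- rnorm(999)
  sv <- phaseRandomize(v)
  expect_length(sv, 999)
  expect_lt(max(abs(Mod(fft(sv)) - Mod(fft(v)))) / max(Mod(fft(v))), 1e-8)

  const <- matrix(5, 1, 64)
  expect_equal(phaseRandomize(const), const)

  x[1, 3] <- Inf
  expect_error(phaseRandomize(x), "non-finite")

  # the C++ synthesis path preserves amplitudes too
  set.seed(82)
  y <- matrix(rnorm(2 * 1250), 2)
  sy <- eegdtf:::cpp_phase_randomize(y)
  expect_lt(max(abs(Mod(fft(sy[1, ])) - Mod(fft(y[1, ])))) /
            max(Mod(fft(y[1, ]))), 1e-8)
})

test_that("phase randomization destroys cross-channel coupling", {
  # mixture channels (oscillator + broadband noise), 20 s: enough
  # independent cycles that surrogate correlations concentrate near zero
  set.seed(91)
  n <- 5000
  src <- makeOscillator(c(4, 7), 250, n) + 0.5 * rnorm(n)
  tgt <- c(rep(0, 3), src[1:(n - 3)]) + 0.5 * rnorm(n)
  x <- rbind(src, tgt)
  r0 <- cor(x[1, 1:(n - 3)], x[2, 4:n])
  expect_gt(abs(r0), 0.5)
  rs <- replicate(100, {
    s <- phaseRandomize(x)
    cor(s[1, 1:(n - 3)], s[2, 4:n])
  })
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("surrogate thresholds sit at the right rank and are sorted", {
  set.seed(101)
  ep <- matrix_epochs(matrix(rnorm(3 * 2500), 3), epochLengthS = 5)
  null1000 <- surrogateThreshold(ep, p = 2, nSurrogates = 1000, alpha = 0.05)
  expect_equal(null1000@rankIndex, 950L)
  null100 <- surrogateThreshold(ep, p = 2, nSurrogates = 100, alpha = 0.05)
  expect_equal(null100@rankIndex, 95L)

  # values sorted along the surrogate dimension; threshold = value at rank
  v <- null100@values
  expect_true(all(apply(v, c(1, 2, 3), function(z) !is.unsorted(z))))
  expect_equal(null100@thresholds[["delta"]][1, 2], v[1, 2, 1, 95])
  expect_true(all(vapply(null100@thresholds, function(m)
    all(m >= 0 & m <= 1), logical(1))))

  expect_error(surrogateThreshold(ep, nSurrogates = 10), "at least 20")
})

test_that("thresholding keeps only strictly supra-threshold edges", {
  thr <- matrix(0.25, 3, 3)
  null <- new("SurrogateNull",
              values = array(0, c(3, 3, 1, 20)),
              thresholds = list(delta = thr), bands = "delta",
              nSurrogates = 20L, alpha = 0.05, rankIndex = 19L)
  m <- matrix(c(0.9, 0.30, 0.20,
                0.25, 0.9, 0.26,
                0.10, 0.40, 0.9), 3, byrow = TRUE)
  out <- thresholdNetwork(m, null, "delta")
  expect_equal(out[1, 2], 0.30)   # above
  expect_equal(out[1, 3], 0)      # below
  expect_equal(out[2, 1], 0)      # exact tie -> non-significant
  expect_equal(diag(out), rep(0, 3))
  expect_error(thresholdNetwork(matrix(0, 2, 2), null, "delta"), "shape")
  expect_error(thresholdNetwork(m, null, "beta"), "band")
})

test_that("subject connectivity bundles DTF_Mean, null and thresholded nets", {
  spec <- small_cohort_spec(seed = 14, n = 1, seconds = 10)
  rec <- generateCohorts(spec)$recordings[[1]]
  ep <- preprocessRecording(rec)
  cr <- subjectConnectivity(ep, nSurrogates = 50)
  expect_s4_class(cr, "ConnectivityResult")
  m <- dtfMeanMatrix(cr, "delta")
  expect_equal(dim(m), c(32, 32))
  expect_true(all(m >= 0 & m <= 1))
  tm <- dtfMeanMatrix(cr, "delta", thresholded = TRUE)
  expect_true(all(tm[tm > 0] == m[tm > 0]))
  expect_true(all(diag(tm) == 0))
  expect_error(dtfMeanMatrix(cr, "beta"), "unknown band")

  # no-surrogate mode skips thresholding
  cr0 <- subjectConnectivity(ep, nSurrogates = 0)
  expect_length(cr0@thresholded, 0)
  expect_null(cr0@null)
})
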