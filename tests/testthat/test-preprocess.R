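test_that("average reference zeroes the per-sample channel mean and is idempotent", {
  rec <- white_recording(k = 6, seconds = 2)
  ref <- averageReference(rec)
  expect_lt(max(abs(colMeans(eegData(ref)))), 1e-10)
  expect_equal(dim(eegData(ref)), dim(eegData(rec)))
  expect_equal(eegData(averageReference(ref)), eegData(ref))

  # all channels identical -> all zero
  const <- make_recording(matrix(rep(sin(1:500), 3), 3, byrow = TRUE))
  expect_equal(max(abs(eegData(averageReference(const)))), 0)

  # two channels: closed form (a-b)/2, (b-a)/2
  ab <- make_recording(rbind(a = 1:10, b = rep(2, 10)))
  got <- eegData(averageReference(ab))
  expect_equal(got[1, ], (1:10 - 2) / 2, ignore_attr = TRUE)
  expect_equal(got[2, ], (2 - 1:10) / 2, ignore_attr = TRUE)

  expect_error(averageReference(make_recording(matrix(rnorm(100), 1))),
               "2 channels")
})

test_that("the band-pass is selective and strictly zero-phase", {
  fs <- 250
  t <- seq(1 / fs, 10, by = 1 / fs)
  tone <- function(f) make_recording(matrix(sin(2 * pi * f * t), 1), fs = fs)
  rms <- function(x) sqrt(mean(x^2))

  out50 <- eegData(bandpassFilter(tone(50), 1, 30))
  expect_lt(rms(out50) / rms(sin(2 * pi * 50 * t)), 0.05)

  out10 <- eegData(bandpassFilter(tone(10), 1, 30))
  expect_gte(rms(out10) / rms(sin(2 * pi * 10 * t)), 0.90)

  dc <- make_recording(matrix(rep(7, 2500), 1), fs = fs)
  expect_lt(rms(eegData(bandpassFilter(dc, 1, 30))), 0.05)

  # impulse keeps its peak position (zero group delay)
  imp <- matrix(0, 1, 2500); imp[1, 1250] <- 1
  fi <- eegData(bandpassFilter(make_recording(imp, fs = fs), 1, 30))
  expect_lte(abs(which.max(abs(fi[1, ])) - 1250), 1)

  # narrowband input: cross-correlation peak with the output at lag 0
  set.seed(2)
  nb <- makeOscillator(c(8, 13), fs, 2500)
  fo <- eegData(bandpassFilter(make_recording(matrix(nb, 1), fs = fs), 1, 30))
  cc <- ccf(nb, fo[1, ], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpassFilter(tone(10), 1, 200), "Nyquist")
})

test_that("epoching follows the floor rule and reconstructs the recording", {
  rec <- white_recording(k = 3, seconds = 300)
  ep <- epochRecording(rec, 5)
  expect_equal(nEpochs(ep), 60)
  expect_equal(dim(ep@epochs)[3], 1250)

  rec301 <- white_recording(k = 2, seconds = 301, seed = 8)
  expect_equal(nEpochs(epochRecording(rec301, 5)), 60)

  short <- white_recording(k = 2, seconds = 4, seed = 9)
  expect_warning(ep0 <- epochRecording(short, 5), "0 epochs")
  expect_equal(nEpochs(ep0), 0)

  expect_error(epochRecording(rec, 0), "positive")

  # concatenating the epochs reproduces the (truncated) input exactly
  recat <- do.call(cbind, lapply(seq_len(nEpochs(ep)), function(i)
    epochMatrix(ep, i)))
  expect_equal(unname(recat), unname(eegData(rec)[, 1:75000]))
})

test_that("baseline correction removes per-epoch channel means and the chain composes", {
  rec <- white_recording(k = 4, seconds = 15, seed = 4)
  ep <- preprocessRecording(rec, lo = 1, hi = 30, epochLengthS = 5)
  expect_equal(nEpochs(ep), 3)
  mus <- apply(ep@epochs, c(1, 2), mean)
  expect_lt(max(abs(mus)), 1e-10)

  # the artifact hook runs and must return a recording
  marker <- new.env(); marker$hit <- FALSE
  ep2 <- preprocessRecording(rec, cleaner = function(r) { marker$hit <- TRUE; r })
  expect_true(marker$hit)
  expect_equal(nEpochs(ep2), 3)
  expect_error(preprocessRecording(rec, cleaner = function(r) NULL),
               "EEGRecording")
})
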