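test_that("band oscillators concentrate power in their band and are reproducible", {
  set.seed(11)
  x <- makeOscillator(c(8, 13), 250, 75000)
  expect_equal(mean(x), 0, tolerance = 1e-8)
  expect_equal(sd(x), 1, tolerance = 1e-8)
  psd <- welchPsd(x, sampleRate = 250)
  inband <- function(lo, hi) sum(psd@power[1, psd@freqs >= lo & psd@freqs < hi])
  expect_gte(inband(8, 13) / inband(1, 30), 0.7)

  set.seed(5); a <- makeOscillator(c(1, 4), 250, 1000)
  set.seed(5); b <- makeOscillator(c(1, 4), 250, 1000)
  expect_identical(a, b)

  expect_length(makeOscillator(c(1, 4), 250, 0), 0)
  expect_error(makeOscillator(c(100, 130), 250, 100), "Nyquist")
  expect_error(makeOscillator(c(0, 4), 250, 100), "Nyquist")
})

test_that("injected band effects raise in-band power monotonically at the target electrode", {
  pow <- vapply(c(1, 1.5, 2.5), function(m) {
    spec <- cohortSpec(nSubjectsPerGroup = 1, durationS = 10, seed = 7,
                       bandEffects = data.frame(group = "MCI", band = "delta",
                                                electrode = "Fz", multiplier = m))
    rec <- generateCohorts(spec)$recordings[[2]]   # the MCI subject
    psd <- welchPsd(eegData(rec)["Fz", , drop = FALSE], sampleRate = 250)
    unname(bandPower(psd, "delta"))
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
})

test_that("a delta boost separates cohort mean delta power at the boosted electrode", {
  spec <- cohortSpec(nSubjectsPerGroup = 15, durationS = 15, seed = 21,
                     bandEffects = data.frame(group = "MCI", band = "delta",
                                              electrode = "Fz", multiplier = 1.5))
  recs <- generateCohorts(spec)$recordings
  dp <- vapply(recs, function(r) {
    unname(bandPower(welchPsd(eegData(r)["Fz", , drop = FALSE],
                              sampleRate = 250), "delta"))
  }, numeric(1))
  grp <- vapply(recs, groupLabel, character(1))
  expect_gt(mean(dp[grp == "MCI"]), mean(dp[grp == "NC"]))
})

test_that("with no injected effects the two groups are draws from one distribution", {
  spec <- cohortSpec(nSubjectsPerGroup = 25, durationS = 10, seed = 31)
  recs <- generateCohorts(spec)$recordings
  grp <- vapply(recs, groupLabel, character(1))
  v <- lapply(recs, function(r) apply(eegData(r), 1, var))
  vn <- unlist(v[grp == "NC"]); vm <- unlist(v[grp == "MCI"])
  expect_gt(suppressWarnings(stats::ks.test(vn, vm)$p.value), 0.01)
})

test_that("a directed coupling shows up as asymmetric lagged cross-correlation", {
  spec <- cohortSpec(nSubjectsPerGroup = 1, durationS = 20, seed = 13,
                     couplingCv = 0,
                     couplings = data.frame(group = "MCI", source = "PO3",
                                            target = "CP5", band = "delta",
                                            strength = 0.4, lag = 2))
  rec <- generateCohorts(spec)$recordings[[2]]
  x <- eegData(rec)
  cc <- ccf(x["PO3", ], x["CP5", ], lag.max = 25, plot = FALSE)
  fwd <- max(abs(cc$acf[cc$lag < 0]))   # PO3 leading CP5
  rev <- max(abs(cc$acf[cc$lag > 0]))
  expect_gt(fwd, rev)
})

test_that("without couplings, lagged cross-correlations are centered on zero", {
  spec <- cohortSpec(nSubjectsPerGroup = 15, durationS = 10, seed = 17)
  recs <- generateCohorts(spec)$recordings
  r2 <- vapply(recs, function(r) {
    x <- eegData(r)
    n <- ncol(x)
    cor(x["PO3", 1:(n - 2)], x["CP5", 3:n])
  }, numeric(1))
  expect_lt(abs(mean(r2)), 3 * sd(r2) / sqrt(length(r2)))
})

test_that("cohort generation is deterministic, counted and manifest-complete", {
  spec <- small_cohort_spec(seed = 9, n = 3)
  out <- withr::with_tempdir({
    a <- generateCohorts(spec, outDir = "cohort")
    list(res = a, manifest = readLines(file.path("cohort", "manifest.csv")))
  })
  expect_length(out$res$recordings, 6)
  expect_equal(nrow(out$res$manifest), 6)
  expect_equal(sum(out$res$manifest$group == "MCI"), 3)

  b <- generateCohorts(spec)
  expect_identical(out$res$manifest, b$manifest)
  expect_identical(eegData(out$res$recordings[[4]]), eegData(b$recordings[[4]]))

  full <- cohortSpec(nSubjectsPerGroup = 1, durationS = 300, seed = 2)
  rec <- generateCohorts(full)$recordings[[1]]
  expect_equal(ncol(eegData(rec)), 75000)
  expect_true(all(vapply(out$res$recordings, function(r)
    mocaScore(r) >= 0 && mocaScore(r) <= 30, logical(1))))
})

test_that("unknown electrodes in a spec are rejected", {
  spec <- cohortSpec(nSubjectsPerGroup = 1, durationS = 5,
                     couplings = data.frame(group = "MCI", source = "QQ1",
                                            target = "CP5", band = "delta",
                                            strength = 0.2, lag = 1))
  expect_error(generateSubject(spec, group = "MCI"), "unknown electrode")
  expect_error(cohortSpec(couplings = data.frame(group = "MCI", source = "PO3",
                                                 target = "CP5", band = "delta",
                                                 strength = 1.2, lag = 1)),
               "strength")
  expect_error(cohortSpec(bandEffects = data.frame(group = "MCI", band = "delta",
                                                   electrode = "Fz",
                                                   multiplier = -1)),
               "multiplier")
})

test_that("simulateMVAR reproduces a stable process with the right shape", {
  A <- list(matrix(c(0.5, 0.3, 0, 0.4), 2))
  set.seed(3)
  x <- simulateMVAR(A, 800)
  expect_equal(dim(x), c(2, 800))
  expect_true(all(is.finite(x)))
})
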