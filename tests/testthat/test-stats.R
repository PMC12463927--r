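test_that("the test router follows the normality and variance gates", {
  # under ideal conditions the three 5%-level gates pass jointly with
  # probability ~0.95^3 ~ 0.86, so the t route dominates but not at 90%
  set.seed(111)
  gauss <- replicate(100, routeTest(rnorm(20), rnorm(20)))
  expect_gte(mean(gauss == "student_t"), 0.8)

  set.seed(113)
  skewed <- replicate(100, routeTest(rexp(20), rnorm(20)))
  expect_gte(mean(skewed == "mann_whitney"), 0.9)

  expect_warning(r <- routeTest(c(1, 2), rnorm(20)), "Mann-Whitney")
  expect_identical(r, "mann_whitney")
  expect_warning(rc <- routeTest(rep(1, 10), rnorm(10)), "Mann-Whitney")
  expect_identical(rc, "mann_whitney")

  # unequal variances push Gaussian samples to the rank test
  set.seed(117)
  hetero <- replicate(100, routeTest(rnorm(20, sd = 1), rnorm(20, sd = 6)))
  expect_gte(mean(hetero == "mann_whitney"), 0.9)
})

test_that("the pooled t from summaries matches its closed form and raw-sample t", {
  expect_equal(tFromSummary(26.70, 1.38, 20, 19.91, 2.98, 21), 9.284,
               tolerance = 1e-3)
  expect_equal(tFromSummary(5, 2, 10, 5, 2, 10), 0)
  expect_equal(tFromSummary(1, 1, 10, 0, 1, 10), sqrt(5), tolerance = 1e-12)
  expect_equal(tFromSummary(3, 0, 5, 3, 0, 5), 0)
  expect_error(tFromSummary(3, 0, 5, 4, 0, 5), "undefined")
  expect_error(tFromSummary(1, 1, 1, 2, 1, 10), "n >= 2")

  set.seed(121)
  x <- rnorm(15, 1); y <- rnorm(12)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tFromSummary(mean(x), sd(x), 15, mean(y), sd(y), 12),
               unname(tt$statistic), tolerance = 1e-12)
})

test_that("Cohen's d uses the pooled SD with MCI-minus-NC sign", {
  # printed-summary check: (26.70 - 19.91) / pooled SD of 1.38/2.98
  sp <- sqrt((19 * 1.38^2 + 20 * 2.98^2) / 39)
  expect_equal(tFromSummary(26.70, 1.38, 20, 19.91, 2.98, 21) *
                 sqrt(1 / 20 + 1 / 21), (26.70 - 19.91) / sp,
               tolerance = 1e-12)
  expect_equal((26.70 - 19.91) / sp, 2.90, tolerance = 0.01)

  x <- c(1, 2, 3, 4)
  expect_equal(cohensD(x, x), 0)
  set.seed(123)
  a <- rnorm(1000); b <- rnorm(1000) + 1
  expect_equal(cohensD(b, a), 1, tolerance = 0.1)
  expect_error(cohensD(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("Cliff's delta equals the exhaustive pairwise count", {
  expect_equal(cliffsDelta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffsDelta(c(1, 3), 2), 0)
  expect_error(cliffsDelta(numeric(0), 1), "non-empty")

  brute <- function(x, y) {
    s <- 0
    for (i in seq_along(x)) for (j in seq_along(y))
      s <- s + sign(x[i] - y[j])
    s / (length(x) * length(y))
  }
  set.seed(131)
  for (rep in 1:50) {
    nx <- sample(2:50, 1); ny <- sample(2:50, 1)
    x <- sample(1:10, nx, replace = TRUE)   # ties included
    y <- rnorm(ny)
    expect_identical(cliffsDelta(x, y), brute(x, y))
  }
})

test_that("the 2x2 chi-square is Pearson's without continuity correction", {
  expect_equal(chiSquare2x2(matrix(c(12, 15, 8, 6), 2)), 0.595,
               tolerance = 1e-3)
  expect_equal(chiSquare2x2(matrix(c(10, 20, 5, 10), 2)), 0)
  expect_equal(chiSquare2x2(matrix(c(10, 0, 0, 10), 2)), 20)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chiSquare2x2(matrix(1, 3, 3)), "2x2")
})

test_that("BH q-values match the hand-computed step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(c(0.005, 0.1, 0.2, 0.9)),
               c(0.02, 0.2, 0.2 * 4 / 3, 0.9))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(0.37), 0.37)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # monotone transform of ranks, q >= p, order-preserving
  set.seed(141)
  p <- runif(200)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("Pearson correlation handles exact and simulated cases", {
  x <- 1:10
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(1:2, 1:2), "at least 3")
  expect_error(pearsonR(rep(1, 5), 1:5), "zero variance")

  # built-in negative MoCA link: sign recovered in nearly all seeds
  set.seed(151)
  hits <- replicate(100, {
    z <- rnorm(41)
    edge <- 0.05 + 0.01 * z + 0.01 * rnorm(41)
    moca <- 23 - 0.5 * 2.2 * z + 2.2 * rnorm(41)
    pearsonR(edge, moca)$r < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("routed group comparison recovers injected electrode effects", {
  set.seed(161)
  electrodes <- paste0("E", 1:20)
  mk <- function(id, group, shift) {
    pw <- rnorm(20, 10, 1)
    pw[1:2] <- pw[1:2] + shift          # E1, E2 carry the effect
    data.frame(subject_id = id, group = group, band = "delta",
               electrode = electrodes, power = pw)
  }
  tbl <- rbind(
    do.call(rbind, lapply(1:15, function(i) mk(paste0("N", i), "NC", 0))),
    do.call(rbind, lapply(1:15, function(i) mk(paste0("M", i), "MCI", 3))))
  cmp <- compareGroups(tbl, value = "power")
  sig <- cmp$electrode[cmp$significant]
  expect_setequal(sig, c("E1", "E2"))
  expect_true(all(cmp$direction[cmp$significant] == "MCI>NC"))
  expect_true(all(cmp$q >= cmp$p))
  expect_true(all(cmp$effect_type[cmp$test == "student_t"] == "cohens_d"))
  expect_true(all(cmp$effect_type[cmp$test == "mann_whitney"] == "cliffs_delta"))
})

test_that("group comparison is calibrated under the null after FDR", {
  set.seed(171)
  electrodes <- paste0("E", 1:32)
  frac <- replicate(60, {
    tbl <- do.call(rbind, lapply(1:20, function(i)
      data.frame(subject_id = paste0("S", i),
                 group = if (i <= 10) "NC" else "MCI", band = "delta",
                 electrode = electrodes, power = rnorm(32))))
    mean(compareGroups(tbl, value = "power")$significant)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("the routed test keeps its nominal type-I error", {
  set.seed(181)
  rejections <- replicate(2000, {
    x <- rnorm(20); y <- rnorm(20)
    if (suppressWarnings(routeTest(x, y)) == "student_t")
      t.test(x, y, var.equal = TRUE)$p.value < 0.05
    else
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value) < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("insufficient data is rejected up front", {
  tbl <- data.frame(subject_id = c("a", "b"), group = c("NC", "MCI"),
                    band = "delta", electrode = "E1", power = 1:2)
  expect_error(compareGroups(tbl, value = "power"), "2 subjects")
  expect_error(compareGroups(tbl[tbl$group == "NC", ], value = "power"),
               "both groups")
})

test_that("MoCA correlations are computed per edge over pooled subjects", {
  set.seed(191)
  n <- 30
  z <- rnorm(n)
  tbl <- data.frame(subject_id = paste0("S", 1:n),
                    group = rep(c("NC", "MCI"), each = n / 2),
                    moca = 24 - 2 * z + rnorm(n),
                    band = "delta", source = "PO3", target = "CP5",
                    value = 0.04 + 0.01 * z)
  ct <- correlateWithMoca(tbl)
  expect_equal(nrow(ct), 1)
  expect_lt(ct$r, 0)
  expect_equal(ct$n, n)
  expect_lte(abs(ct$r), 1)
})
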