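test_that("a pure 20-Hz sinusoid peaks in the 20-Hz bin", {
  t <- seq_len(1000) / 1000
  v <- array(rep(sin(2 * pi * 20 * t), 2), c(1, 1000, 2))
  rec <- laminarRecording(v, 1000, 100)
  pm <- computePowerMap(rec)
  expect_equal(freqs(pm)[which.max(powerValues(pm)[1, ])], 20)
})

test_that("white-noise spectra match a direct periodogram oracle", {
  set.seed(1)
  fs <- 1000; n <- 1000; ntr <- 60
  v <- array(rnorm(n * ntr, sd = 2), c(1, n, ntr))
  rec <- laminarRecording(v, fs, 100)
  pm <- computePowerMap(rec)
  # oracle: trial-averaged one-sided periodogram, computed directly
  per <- rowMeans(vapply(seq_len(ntr), function(j) {
    x <- v[1, , j] - mean(v[1, , j])
    (2 * Mod(fft(x))^2 / (n * fs))[2:151]
  }, numeric(150)))
  mt <- powerValues(pm)[1, ]
  expect_equal(mean(mt), mean(per), tolerance = 0.05)
  expect_equal(mean(mt), 2 * 4 / fs, tolerance = 0.1)  # 2*sigma^2/fs
  # flat within sampling error: no frequency trend
  expect_lt(abs(cor(freqs(pm), mt)), 0.25)
})

test_that("zero signal yields all-zero power", {
  rec <- laminarRecording(array(0, c(2, 1000, 1)), 1000, 100)
  expect_true(all(powerValues(computePowerMap(rec)) == 0))
  # a window too short for the lowest requested bin is a resolution error
  short <- laminarRecording(array(0, c(2, 400, 1)), 1000, 100)
  expect_error(computePowerMap(short), "too short")
})

test_that("relative power normalizes each column to a max of exactly 1", {
  pm <- powerMap(matrix(c(2, 4, 8), 3, 1), freqs = 10)
  expect_equal(relPower(relativePower(pm))[, 1], c(0.25, 0.5, 1.0))
  single <- powerMap(matrix(c(3, 5, 7), 1, 3), freqs = 1:3)
  expect_true(all(relPower(relativePower(single)) == 1))
  set.seed(2)
  rnd <- powerMap(matrix(rexp(24 * 50) + 0.01, 24, 50), 1:50)
  rel <- relativePower(rnd)
  expect_equal(unname(apply(relPower(rel), 2, max)), rep(1, 50))
  expect_equal(apply(relPower(rel), 2, which.max),
               apply(powerValues(rnd), 2, which.max))
})

test_that("relative power is idempotent and rejects all-zero columns", {
  set.seed(3)
  pm <- powerMap(matrix(runif(10 * 5), 10, 5), 1:5)
  once <- relativePower(pm)
  expect_equal(relPower(relativePower(once)), relPower(once))
  bad <- powerMap(cbind(c(1, 2), c(0, 0)), 1:2)
  expect_error(relativePower(bad), "2 Hz")
})

test_that("band profiles average the configured bins", {
  m <- matrix(0.5, 4, 10)
  rel <- relativePowerMap(rbind(m[1:3, ], 1), 1:10)
  bp <- bandProfile(rel, c(2, 5))
  expect_equal(profileValues(bp)[1:3], rep(0.5, 3))
  # single-bin band equals that column
  vals <- matrix(runif(12), 4, 3)
  vals <- sweep(vals, 2, apply(vals, 2, max), "/")
  rel2 <- relativePowerMap(vals, c(10, 20, 30))
  expect_equal(profileValues(bandProfile(rel2, c(19, 21))), vals[, 2])
  # two-bin arithmetic mean
  v3 <- cbind(c(0.2, 1), c(0.6, 1))
  rel3 <- relativePowerMap(v3, c(10, 11))
  expect_equal(profileValues(bandProfile(rel3, c(10, 11)))[1], 0.4)
  expect_error(bandProfile(rel3, c(200, 300)), "outside")
})

test_that("band profile of a column-constant map is that constant", {
  vals <- matrix(rep(c(0.3, 0.7, 1), each = 5), 5, 3)  # columns constant
  rel <- relativePower(powerMap(vals, c(5, 10, 15)))
  for (band in list(c(5, 10), c(10, 15), c(5, 15)))
    expect_true(all(abs(diff(profileValues(bandProfile(rel, band)))) < 1e-12))
})

test_that("depth standardization interpolates linearly", {
  # identity when already on the target grid
  set.seed(4)
  vals <- matrix(runif(24 * 6), 24, 6)
  pm <- powerMap(vals, 1:6)
  expect_equal(powerValues(standardizeDepth(pm, 24L)), vals)
  # 2-channel input becomes a linear ramp
  ramp <- standardizeDepth(powerMap(rbind(0, 1), 1:1), 24L)
  expect_equal(powerValues(ramp)[, 1], seq(0, 1, length.out = 24))
  # 48 -> 24 of a linear-in-depth map stays linear
  lin <- powerMap(matrix(seq(0, 1, length.out = 48), 48, 2), 1:2)
  out <- powerValues(standardizeDepth(lin, 24L))
  expect_equal(out[, 1], seq(0, 1, length.out = 24), tolerance = 1e-12)
  expect_error(standardizeDepth(pm, 1L), "nOut")
})

test_that("depth standardization preserves monotone profile extremes", {
  set.seed(6)
  prof <- sort(runif(30))
  pm <- powerMap(matrix(prof, 30, 1), 1)
  out <- powerValues(standardizeDepth(pm, 24L))[, 1]
  expect_equal(min(out), min(prof), tolerance = 1e-9)
  expect_equal(max(out), max(prof), tolerance = 1e-9)
  expect_true(all(diff(out) >= -1e-12))
})

test_that("frequency re-binning averages adjacent bins and renormalizes", {
  vals <- matrix(seq(0.2, 1, by = 0.2), 1, 5)
  pm <- powerMap(vals, 1:5)
  rb <- rebinFrequencies(pm, 5)
  expect_equal(powerValues(rb)[1, 1], 0.6)
  expect_equal(freqs(rb), 3)
  set.seed(5)
  rel <- relativePower(powerMap(matrix(runif(8 * 10) + 0.1, 8, 10), 1:10))
  rb2 <- rebinFrequencies(rel, 5)
  expect_equal(unname(apply(relPower(rb2), 2, max)), c(1, 1))
  wide <- rebinFrequencies(powerMap(matrix(runif(10), 1, 10), 1:10), 5)
  expect_error(rebinFrequencies(wide, 7), "multiple")
})

test_that("bad channels are flagged and repaired from nearest neighbours", {
  flat <- matrix(1, 10, 20)
  pm <- powerMap(flat, 1:20)
  r0 <- repairBadChannels(pm)
  expect_length(r0$flagged, 0)
  expect_equal(powerValues(r0$map), flat)
  # one 10x outlier
  bad <- flat; bad[5, ] <- 10
  r1 <- repairBadChannels(powerMap(bad, 1:20))
  expect_equal(r1$flagged, 5L)
  expect_equal(powerValues(r1$map)[5, ], rep(1, 20))  # mean of ch 4 and 6
  # two adjacent outliers on a longer probe (the s.d. includes the
  # outliers, so a pair is only detectable when the probe is long enough)
  flat24 <- matrix(1, 24, 20)
  bad2 <- flat24; bad2[4, ] <- 8; bad2[5, ] <- 8
  r2 <- repairBadChannels(powerMap(bad2, 1:20))
  expect_setequal(r2$flagged, c(4L, 5L))
  expect_equal(powerValues(r2$map)[4, ], rep(1, 20))  # mean of ch 3 and 6
  expect_equal(powerValues(r2$map)[5, ], rep(1, 20))
  # edge outlier repaired one-sided
  bad3 <- flat; bad3[1, ] <- 12
  r3 <- repairBadChannels(powerMap(bad3, 1:20))
  expect_equal(r3$flagged, 1L)
  expect_equal(powerValues(r3$map)[1, ], rep(1, 20))
})

test_that("profiles commute with depth reversal (equivariance)", {
  rel <- canonical_probe()$rel
  flipped <- relativePowerMap(relPower(rel)[24:1, ], freqs(rel))
  for (band in list(c(10, 30), c(50, 150))) {
    a <- profileValues(bandProfile(rel, band))
    b <- profileValues(bandProfile(flipped, band))
    expect_equal(rev(a), b)
  }
})
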