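test_that("FLIP identifies a canonical synthetic probe and its landmarks", {
  cp <- canonical_probe()
  fr <- flip(cp$pm)
  expect_true(isIdentifiable(fr))
  expect_equal(orientation(fr), "upright")
  expect_gt(gValue(fr), 0.265)
  expect_lte(abs(crossoverChannel(fr) - cp$gp$truth$crossoverChannelStd), 1)
  # landmark ordering: gamma peak superficial to crossover, alpha-beta deep
  expect_lt(gammaPeakChannel(fr), crossoverChannel(fr))
  expect_gt(alphabetaPeakChannel(fr), crossoverChannel(fr))
  # landmarks are mapped back to original channels and micrometer depths
  expect_false(is.na(fr@crossoverChannelOriginal))
  expect_equal(fr@crossoverDepthUm,
               (fr@crossoverChannelOriginal - 1) * 100, tolerance = 100)
})

test_that("depth reversal mirrors landmarks and flips the sign of G", {
  cp <- canonical_probe()
  fr <- flip(cp$rel)
  rev_map <- relativePowerMap(relPower(cp$rel)[24:1, ], freqs(cp$rel))
  fr2 <- flip(rev_map)
  expect_equal(gValue(fr2), -gValue(fr), tolerance = 1e-9)
  expect_equal(orientation(fr2), "inverted")
  expect_equal(crossoverChannel(fr2), 25L - crossoverChannel(fr))
  expect_equal(gammaPeakChannel(fr2), 25L - gammaPeakChannel(fr))
  expect_equal(alphabetaPeakChannel(fr2), 25L - alphabetaPeakChannel(fr))
})

test_that("FLIP is invariant to positive rescaling of the map", {
  cp <- canonical_probe()
  scaled <- powerMap(powerValues(cp$pm) * 7.3, freqs(cp$pm),
                     channelSpacing = 100)
  f1 <- flip(cp$pm); f2 <- flip(scaled)
  expect_equal(gValue(f2), gValue(f1), tolerance = 1e-12)
  expect_equal(crossoverChannel(f2), crossoverChannel(f1))
})

test_that("a white-noise probe is not identifiable", {
  set.seed(50)
  miss <- sapply(1:5, function(i) {
    v <- array(rnorm(24 * 1000 * 4), c(24, 1000, 4))
    rec <- laminarRecording(v, 1000, 100)
    isIdentifiable(flip(computePowerMap(rec)))
  })
  expect_lte(mean(miss), 0.2)
})

test_that("within-range renormalization order barely matters on canonical maps", {
  cp <- canonical_probe()
  cfg <- analysisConfig()
  fr <- flip(cp$rel, cfg)
  # alternative order: band-average globally, then fit the best range on
  # the fixed profiles (profile-level renormalization is a positive
  # rescaling and cannot change the fit)
  pA <- bandProfile(cp$rel, cfg$flipLowBand)
  pG <- bandProfile(cp$rel, cfg$flipHighBand)
  alt <- findOptimalRange(pA, pG, cfg$minRangeChannels)
  expect_equal(sign(alt@G), sign(gValue(fr)))
  expect_equal(abs(alt@G), abs(gValue(fr)), tolerance = 0.15)
})

test_that("vFLIP enumerates only legal band pairs and beats FLIP when the motif moves", {
  pairs <- spectrolaminar:::.vflip_band_pairs(10)
  expect_gt(length(pairs), 100)
  for (p in pairs) {
    expect_lte(p$low[2], 70)
    expect_lt(p$low[2], p$high[1])
    expect_gt(p$high[1], 30)
    expect_equal(p$high[2], 150)
    expect_true(all(c(p$low, p$high) %% 10 == 0))
  }
  # low-frequency gradient planted at 40-60 Hz: fixed-band FLIP fails or
  # scores lower; vFLIP recovers a band overlapping 40-60
  gp <- generateProbe(syntheticProbeSpec(seed = 6L, lowBand = c(40, 60),
                                         gammaBand = c(80, 150)))
  pm <- computePowerMap(gp$recording)
  vr <- vflip(pm)
  fr <- flip(pm)
  expect_true(isIdentifiable(vr))
  expect_gt(abs(gValue(vr)), abs(gValue(fr)))
  expect_lt(lowBand(vr)[1], 60)
  expect_gt(lowBand(vr)[2], 40)
})

test_that("on a canonical probe vFLIP's optimum is at least as good as FLIP's", {
  cp <- canonical_probe()
  vr <- vflip(cp$pm)
  fr <- flip(cp$pm)
  expect_gte(abs(gValue(vr)), abs(gValue(fr)) - 1e-9)
  expect_true(lowBand(vr)[1] <= 30 && lowBand(vr)[2] >= 10)  # overlaps 10-30
})

test_that("maps with too few channels are rejected", {
  small <- powerMap(matrix(runif(5 * 150) + 0.1, 5, 150), 1:150)
  expect_error(flip(small), "at least 8 channels")
})
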