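test_that("image similarity is 1 for identical maps and symmetric", {
  set.seed(70)
  m <- matrix(runif(24 * 150), 24, 150)
  expect_equal(imageSimilarity(m, m), 1, tolerance = 1e-9)
  m2 <- matrix(runif(24 * 150), 24, 150)
  expect_equal(imageSimilarity(m, m2), imageSimilarity(m2, m))
  expect_error(imageSimilarity(m, m2[, 1:100]), "dimensions")
})

test_that("image similarity matches reference SSIM values on fixed images", {
  # deterministic fixtures; reference values computed once with
  # scikit-image structural_similarity (gaussian_weights, sigma = 1.5,
  # use_sample_covariance = FALSE, data_range = 1) and frozen. Tolerance
  # reflects the different border handling (valid-region convolution here
  # vs reflect-padding there); negative reference values map to the
  # clamped 0.
  i <- matrix(1:24, 24, 150); j <- matrix(1:150, 24, 150, byrow = TRUE)
  R1 <- (sin(i * 12.9898 + j * 78.233) * 43758.5453) %% 1
  R2 <- (sin(i * 93.9898 + j * 67.345) * 24634.6345) %% 1
  x <- (i - 1) / 23
  C <- ifelse(j <= 30, 0.2 + 0.8 * x, 1 - 0.8 * x)
  D <- ifelse(j <= 30, 0.2 + 0.8 * x^1.3, 1 - 0.8 * x^1.2)
  expect_equal(imageSimilarity(C, D), 0.988203, tolerance = 0.02)
  expect_equal(imageSimilarity(C, R1), 0.010208, tolerance = 0.02)
  expect_equal(imageSimilarity(R1, R2), max(-0.00126, 0), tolerance = 0.02)
})

test_that("independent random maps score well below similar maps", {
  set.seed(71)
  vals <- replicate(20, imageSimilarity(matrix(runif(24 * 150), 24, 150),
                                        matrix(runif(24 * 150), 24, 150)))
  expect_true(all(vals < 0.5))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the group IS procedure yields 5 within and 20 between values", {
  cpA <- canonical_population(n = 8L, seed = 21L)
  cpB <- canonical_population(n = 8L, seed = 31L)
  g <- groupIS(cpA$maps, cpB$maps, nReps = 5, seed = 9)
  expect_length(g@withinA, 5L)
  expect_length(g@withinB, 5L)
  expect_length(g@between, 20L)
  expect_true(all(c(g@withinA, g@withinB, g@between) >= 0 &
                  c(g@withinA, g@withinB, g@between) <= 1))
  expect_equal(g@grandBetween, mean(g@between))
  # same partitions, same seed: reproducible
  g2 <- groupIS(cpA$maps, cpB$maps, nReps = 5, seed = 9)
  expect_equal(g@between, g2@between)
  expect_error(groupIS(cpA$maps[1:3], cpB$maps, seed = 1), "at least 4")
})

test_that("distinct populations are less similar between than within", {
  cpA <- canonical_population(n = 8L, seed = 21L)
  popB <- generatePopulation(8, syntheticProbeSpec(crossoverDepth = 0.3,
                                                   gammaBand = c(60, 150),
                                                   gradientContrast = 4),
                             seed = 22)
  mapsB <- lapply(popB, function(p)
    standardizeDepth(relativePower(computePowerMap(p$recording)), 24L))
  g <- groupIS(cpA$maps, mapsB, nReps = 5, seed = 9)
  expect_gt(mean(c(g@grandWithinA, g@grandWithinB)), g@grandBetween)
})

test_that("channel shuffling collapses identifiability", {
  cp <- canonical_population(n = 6L, seed = 21L)
  sh <- shuffleIdentifiability(cp$maps[1:6], nShuffles = 25,
                               method = "flip", seed = 5)
  expect_equal(sh$unshuffledFraction, 1)
  expect_lt(sh$fraction, sh$unshuffledFraction)
  # identity permutation equals the unshuffled result by construction
  one <- shuffleIdentifiability(cp$maps[1], nShuffles = 5, seed = 5)
  expect_true(one$perProbe >= 0 && one$perProbe <= 1)
  # determinism
  sh2 <- shuffleIdentifiability(cp$maps[1:6], nShuffles = 25,
                                method = "flip", seed = 5)
  expect_equal(sh$fraction, sh2$fraction)
})
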