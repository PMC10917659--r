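test_that("G is the regularized product of opposing fits", {
  p <- opposing_profiles(8L)
  fit <- goodnessOfFit(p$alphabeta, p$gamma, 1L, 8L)
  expect_equal(fit@fReg, 0.04 * 7 + 0.72)       # = 1.00
  expect_equal(fit@G, 1.0, tolerance = 1e-12)
  expect_equal(fit@r2AlphaBeta, 1, tolerance = 1e-12)
  expect_equal(fit@r2Gamma, 1, tolerance = 1e-12)
  p13 <- opposing_profiles(13L)
  fit13 <- goodnessOfFit(p13$alphabeta, p13$gamma, 1L, 13L)
  expect_equal(fit13@fReg, 1.20)                 # f(12) = 0.04*12 + 0.72
  expect_equal(fit13@G, 1.20, tolerance = 1e-12)
})

test_that("flat profiles give G = 0 with non-significant fits", {
  fit <- goodnessOfFit(rep(0.5, 10), rep(0.2, 10), 1L, 10L)
  expect_equal(fit@G, 0)
  expect_equal(fit@pAlphaBeta, 1)
  expect_equal(fit@pGamma, 1)
})

test_that("reversing both profiles flips the sign of G, not its size", {
  set.seed(10)
  pA <- sort(runif(12)); pG <- rev(sort(runif(12))) * 0.9
  f1 <- goodnessOfFit(pA, pG, 1L, 12L)
  f2 <- goodnessOfFit(rev(pA), rev(pG), 1L, 12L)
  expect_equal(f2@G, -f1@G, tolerance = 1e-12)
  expect_gt(f1@G, 0)
})

test_that("parallel gradients score zero regardless of fit quality", {
  ramp <- seq(0.1, 1, length.out = 10)
  expect_equal(goodnessOfFit(ramp, ramp * 0.8, 1L, 10L)@G, 0)
})

test_that("the range search matches an independent exhaustive lm-based scan", {
  set.seed(20)
  for (i in 1:50) {
    pA <- runif(24); pG <- runif(24)
    got <- findOptimalRange(pA, pG)
    want <- oracle_range_scan(pA, pG)
    expect_equal(got@Di, want$Di)
    expect_equal(got@Df, want$Df)
    expect_equal(got@G, want$G, tolerance = 1e-9)
  }
})

test_that("the range search prefers the planted window and breaks ties to the larger span", {
  # perfect opposing lines on channels 5-15, flat elsewhere
  pA <- rep(0.5, 24); pG <- rep(0.5, 24)
  pA[5:15] <- seq(0.1, 1, length.out = 11)
  pG[5:15] <- seq(1, 0.1, length.out = 11)
  fit <- findOptimalRange(pA, pG)
  want <- oracle_range_scan(pA, pG)
  expect_gte(abs(fit@G), abs(want$G) * 0.95)
  expect_true(fit@Di >= 4 && fit@Df <= 16)
  # globally perfect lines: tie-break takes the full probe
  p <- opposing_profiles(24L)
  full <- findOptimalRange(p$alphabeta, p$gamma)
  expect_equal(c(full@Di, full@Df), c(1L, 24L))
  expect_equal(full@G, 0.04 * 23 + 0.72, tolerance = 1e-12)
})

test_that("shuffling destroys the range search's goodness of fit", {
  p <- opposing_profiles(24L)
  base <- abs(findOptimalRange(p$alphabeta, p$gamma)@G)
  set.seed(30)
  shuf <- replicate(100, {
    abs(findOptimalRange(sample(p$alphabeta), sample(p$gamma))@G)
  })
  expect_lt(median(shuf), 0.265)
  expect_lt(median(shuf), base / 2)
})

test_that("crossover selection finds the sign change and maximizes deltaP", {
  pA <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  pG <- c(1.0, 0.8, 0.6, 0.4, 0.2)
  fit <- goodnessOfFit(pA, pG, 1L, 5L, minSpan = 4L)
  expect_equal(selectCrossover(pA, pG, fit)$channel, 3L)
  # gamma dominant everywhere: no crossover
  expect_error(selectCrossover(pA, pA + 0.5, fit), "no .*crossover")
  # multiple sign changes; deltaP decides between the candidates.
  # d = pG - pA = (0.5, -0.2, 0.1, -0.6, -0.8): sign changes at 1-2, 2-3
  # and 3-4, collapsing to candidate channels 2 and 3 (smaller |d| at each
  # crossing). Hand enumeration from the definition:
  #   deltaP(2) = (0.5 - 0.2) + (0.2 - 0.1 + 0.6 + 0.8) = 1.8
  #   deltaP(3) = (0.5 - 0.2 + 0.1) + (-0.1 + 0.6 + 0.8) = 1.7
  pA2 <- c(0.2, 0.6, 0.4, 0.9, 1.0)
  pG2 <- c(0.7, 0.4, 0.5, 0.3, 0.2)
  fit2 <- goodnessOfFit(pA2, pG2, 1L, 5L, minSpan = 4L)
  got <- selectCrossover(pA2, pG2, fit2)
  expect_equal(got$channel, 2L)
  expect_equal(got$deltaP, 1.8, tolerance = 1e-12)
})

test_that("peak selection picks the local maxima nearest the range limits", {
  fit <- new("RangeFit", Di = 5L, Df = 20L, G = 1, fReg = 0.04 * 15 + 0.72,
             r2AlphaBeta = 1, r2Gamma = 1, slopeSignAlphaBeta = 1,
             slopeSignGamma = -1, pAlphaBeta = 0, pGamma = 0)
  # gamma maxima at 3 and 10; |5-3| < |10-5| -> 3
  pG <- rep(0.2, 24); pG[3] <- 1; pG[10] <- 0.9
  # unimodal alpha-beta peaking at 18
  pA <- c(seq(0.1, 1, length.out = 18), seq(0.95, 0.4, length.out = 6))
  pk <- selectPeaks(pA, pG, fit)
  expect_equal(pk$gammaPeak, 3L)
  expect_equal(pk$alphabetaPeak, 18L)
  expect_false(pk$alphabetaBoundary)
  # strictly increasing alpha-beta: deepest channel with boundary flag
  pk2 <- selectPeaks(seq(0.1, 1, length.out = 24), pG, fit)
  expect_equal(pk2$alphabetaPeak, 24L)
  expect_true(pk2$alphabetaBoundary)
  # plateau collapses to its centre
  pG3 <- rep(0.2, 24); pG3[7:9] <- 1
  expect_equal(selectPeaks(pA, pG3, fit)$gammaPeak, 8L)
})

test_that("|G| never exceeds the span regularizer", {
  set.seed(40)
  for (i in 1:25) {
    pA <- runif(24); pG <- runif(24)
    fit <- findOptimalRange(pA, pG)
    expect_lte(abs(fit@G), fit@fReg + 1e-12)
  }
})
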