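test_that("the CSD stencil annihilates depth-affine voltage", {
  n <- 9
  affine <- array(rep(2 + 3 * seq_len(n), 20), c(n, 10, 2))
  rec <- laminarRecording(affine, 1000, 100)
  raw <- computeCsd(rec)
  expect_true(all(abs(raw$csd[raw$validChannels, , ]) < 1e-9))
  expect_true(all(is.na(raw$csd[c(1, 2, n - 1, n), , ])))
  const <- laminarRecording(array(5, c(n, 10, 2)), 1000, 100)
  expect_true(all(abs(computeCsd(const)$csd[3:(n - 2), , ]) < 1e-12))
})

test_that("quadratic voltage gives the closed-form CSD -2*sigma/s^2", {
  n <- 8; s_um <- 1000  # 1 mm spacing so s = 1 in mm units
  v <- array(rep((seq_len(n))^2, 6), c(n, 3, 2))
  rec <- laminarRecording(v, 1000, s_um, conductivity = 2)
  raw <- computeCsd(rec)
  # (c-2)^2 - 2c^2 + (c+2)^2 = 8 -> -sigma*8/(2s)^2 = -2*sigma/s^2
  expect_equal(unique(as.vector(raw$csd[3:(n - 2), , ])), -2 * 2 / 1,
               tolerance = 1e-12)
})

test_that("CSD is linear in the voltage and equivariant to depth reversal", {
  set.seed(60)
  v <- array(rnorm(10 * 20 * 3), c(10, 20, 3))
  rec1 <- laminarRecording(v, 1000, 100)
  rec2 <- laminarRecording(3 * v, 1000, 100)
  expect_equal(computeCsd(rec2)$csd, 3 * computeCsd(rec1)$csd)
  recR <- laminarRecording(v[10:1, , ], 1000, 100)
  a <- computeCsd(rec1)$csd
  b <- computeCsd(recR)$csd
  expect_equal(b[3:8, , ], a[8:3, , ])
})

test_that("fewer than five channels is a stencil error", {
  expect_error(computeCsd(laminarRecording(array(0, c(4, 10, 1)), 1000, 100)),
               "at least 5")
})

test_that("z-scoring is invariant to constant offsets and guards zero s.e.m.", {
  set.seed(61)
  v <- array(rnorm(8 * 400 * 6), c(8, 400, 6))
  rec1 <- laminarRecording(v, 1000, 100, stimulusOnset = 201L)
  rec2 <- laminarRecording(v + 42, 1000, 100, stimulusOnset = 201L)
  z1 <- normalizeCsd(computeCsd(rec1))
  z2 <- normalizeCsd(computeCsd(rec2))
  expect_equal(csdValues(z1), csdValues(z2), tolerance = 1e-9)
  # identical trials: zero s.e.m. points become NA, never infinite
  vi <- array(rep(rnorm(8 * 400), 2), c(8, 400, 2))
  zi <- normalizeCsd(computeCsd(laminarRecording(vi, 1000, 100,
                                                 stimulusOnset = 201L)))
  vals <- csdValues(zi)[validChannels(zi), ]
  expect_true(all(is.na(vals)))
  # single trial: s.e.m. undefined
  expect_error(normalizeCsd(computeCsd(
    laminarRecording(array(rnorm(8 * 100), c(8, 100, 1)), 1000, 100))),
    ">= 2 trials")
})

test_that("baseline z-values behave like standardized noise", {
  set.seed(62)
  v <- array(rnorm(12 * 500 * 25), c(12, 500, 25))
  rec <- laminarRecording(v, 1000, 100, stimulusOnset = 251L)
  z <- normalizeCsd(computeCsd(rec))
  tb <- timeAxis(z) >= -200 & timeAxis(z) < 0
  base <- csdValues(z)[validChannels(z), tb]
  expect_lt(abs(mean(base)), 0.1)      # centred on zero by construction
  expect_equal(sd(base), 1, tolerance = 0.15)  # ~ unit z-scores
})

test_that("the planted evoked sink is recovered and absent thresholds return NULL", {
  ge <- generateEvoked(syntheticProbeSpec(seed = 7L))
  z <- normalizeCsd(computeCsd(ge$recording))
  s <- detectEarlySink(z)
  expect_false(is.null(s))
  expect_lte(abs(s$channel - ge$truth$sinkChannel), 1)
  expect_lte(abs(s$latencyMs - ge$truth$sinkLatencyMs), 10)
  expect_null(detectEarlySink(z, zThresh = -Inf))
})

test_that("doubling the evoked amplitude roughly doubles the peak |z|", {
  base <- syntheticProbeSpec(seed = 8L,
                             evoked = list(sink_depth_fraction = 0.5,
                                           latency_ms = 40, duration_ms = 30,
                                           amplitude = 5))
  peak <- function(sp) {
    z <- normalizeCsd(computeCsd(generateProbe(sp)$recording))
    sel <- timeAxis(z) >= 0 & timeAxis(z) <= 150
    min(csdValues(z)[validChannels(z), sel], na.rm = TRUE)
  }
  p1 <- peak(base)
  p2 <- peak(modifyProbeSpec(base, evoked = list(sink_depth_fraction = 0.5,
                                                 latency_ms = 40,
                                                 duration_ms = 30,
                                                 amplitude = 10)))
  expect_equal(p2 / p1, 2, tolerance = 0.35)
})
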