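test_that("recording round-trips exactly through the binary container", {
  v <- array(rnorm(32 * 100 * 10), c(32, 100, 10))
  rec <- laminarRecording(v, samplingRate = 1000, channelSpacing = 100,
                          stimulusOnset = 51L, probeId = "p1")
  d <- withr::local_tempdir()
  writeRecording(rec, file.path(d, "rec.bin"), file.path(d, "rec.json"))
  back <- readRecording(file.path(d, "rec.bin"), file.path(d, "rec.json"))
  expect_identical(dim(voltage(back)), c(32L, 100L, 10L))
  expect_identical(voltage(back), v)
  expect_equal(samplingRate(back), 1000)
  expect_equal(channelSpacing(back), 100)
  expect_identical(stimulusOnset(back), 51L)
})

test_that("recording round-trips through the text container", {
  v <- array(rnorm(4 * 50 * 2), c(4, 50, 2))
  rec <- laminarRecording(v, 500, 150)
  d <- withr::local_tempdir()
  writeRecording(rec, file.path(d, "rec.txt"), file.path(d, "rec.json"),
                 format = "text")
  back <- readRecording(file.path(d, "rec.txt"), file.path(d, "rec.json"))
  expect_equal(voltage(back), v, tolerance = 1e-12)
})

test_that("missing or contradictory metadata is a format error", {
  v <- array(0, c(3, 10, 1))
  d <- withr::local_tempdir()
  writeRecording(laminarRecording(v, 1000, 100),
                 file.path(d, "r.bin"), file.path(d, "r.json"))
  meta <- jsonlite::read_json(file.path(d, "r.json"), simplifyVector = TRUE)
  meta$sampling_rate_hz <- NULL
  jsonlite::write_json(meta, file.path(d, "bad.json"), auto_unbox = TRUE)
  expect_error(readRecording(file.path(d, "r.bin"), file.path(d, "bad.json")),
               "sampling_rate_hz")
  meta2 <- jsonlite::read_json(file.path(d, "r.json"), simplifyVector = TRUE)
  meta2$n_channels <- 7
  jsonlite::write_json(meta2, file.path(d, "bad2.json"), auto_unbox = TRUE)
  expect_error(readRecording(file.path(d, "r.bin"), file.path(d, "bad2.json")),
               "contradictory")
})

test_that("non-finite voltage is rejected naming the offending channels", {
  v <- array(0, c(4, 10, 1))
  v[3, 5, 1] <- NaN
  expect_error(laminarRecording(v, 1000, 100), "channel\\(s\\) 3")
})

test_that("deep_first input is flipped on ingestion and flagged", {
  v <- array(seq_len(4 * 5 * 1), c(4, 5, 1))
  rec <- laminarRecording(v, 1000, 100, channelOrder = "deep_first")
  expect_equal(channelOrder(rec), "superficial_first")
  expect_true(rec@flippedOnIngest)
  expect_equal(voltage(rec)[1, , 1], v[4, , 1])
})

test_that("maps round-trip through TSV within formatting precision", {
  m <- matrix(runif(24 * 150), 24, 150)
  rel <- relativePower(powerMap(m, 1:150))
  d <- withr::local_tempdir()
  writeResult(rel, file.path(d, "map.tsv"))
  lines <- readLines(file.path(d, "map.tsv"))
  expect_length(lines, 25L)                        # header + 24 channel rows
  expect_match(lines[1L], "^channel\tfreq_1\t")
  back <- readMap(file.path(d, "map.tsv"), type = "relative")
  expect_equal(relPower(back), relPower(rel), tolerance = 1e-12)
  expect_equal(freqs(back), 1:150)
})

test_that("a FLIP result record carries the full landmark schema", {
  fr <- flip(canonical_probe()$pm)
  d <- withr::local_tempdir()
  writeResult(fr, file.path(d, "flip.tsv"))
  rec <- readResultRecord(file.path(d, "flip.tsv"))
  need <- c("G", "D_i", "D_f", "crossover_channel", "gamma_peak_channel",
            "alphabeta_peak_channel", "identifiable", "orientation")
  expect_true(all(need %in% names(rec)))
  expect_equal(as.numeric(rec$G), gValue(fr), tolerance = 1e-12)
  vr <- vflip(canonical_probe()$pm)
  writeResult(vr, file.path(d, "vflip.tsv"))
  rec2 <- readResultRecord(file.path(d, "vflip.tsv"))
  expect_true(all(c("low_band_hz", "high_band_hz") %in% names(rec2)))
})
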