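#' @include accessors.R config.R
NULL

#' Trial-averaged multitaper power map
#'
#' Computes the multitaper power spectrum of every channel on every trial
#' over the configured analysis window and averages across trials. The
#' time-bandwidth product is chosen so the half-bandwidth equals
#' \code{cfg$spectralSmoothing} (2 Hz on the default 1-s window: TW = 2,
#' 3 tapers). Power is reported on regular frequency bins of width
#' \code{cfg$frequencyBins} Hz from the first bin up to \code{cfg$maxFreq}
#' Hz; the DC bin is excluded.
#'
#' When the recording carries stimulus onsets the window is taken relative
#' to each trial's onset; otherwise the full trial is analysed.
#'
#' @param rec a \code{\linkS4class{LaminarRecording}}.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return a \code{\linkS4class{PowerMap}}.
#' @examples
#' rec <- laminarRecording(array(rnorm(4 * 1000 * 3), c(4, 1000, 3)),
#'                         samplingRate = 1000, channelSpacing = 100)
#' pm <- computePowerMap(rec)
#' dim(powerValues(pm))
#' @export
setMethod("computePowerMap", "LaminarRecording", function(rec, cfg, ...) {
  tp <- trialPowerArray(rec, cfg)
  pw <- rowMeans(tp$power, dims = 2L)
  powerMap(pw, tp$freqs, nTrialsAveraged = dim(tp$power)[3L],
           channelSpacing = rec@channelSpacing)
})

#' Per-trial multitaper power
#'
#' The unaveraged counterpart of \code{\link{computePowerMap}}: multitaper
#' power of every channel on every trial, on the same windows and
#' frequency grid. Useful for averaging over arbitrary trial subsets, e.g.
#' when studying how landmark estimates stabilize with signal duration.
#'
#' @inheritParams computePowerMap
#' @return \code{list(freqs, power)} with \code{power} an array
#'   \code{[n_channels, n_freqs, n_trials]}.
#' @export
trialPowerArray <- function(rec, cfg = analysisConfig()) {
  v <- rec@voltage
  d <- dim(v)
  fs <- rec@samplingRate
  onset <- rec@stimulusOnset
  if (length(onset)) {
    onset <- rep_len(onset, d[3L])
    i0 <- onset + as.integer(round(cfg$analysisWindow[1L] * fs / 1000))
    i1 <- onset + as.integer(round(cfg$analysisWindow[2L] * fs / 1000)) - 1L
    if (any(i0 < 1L) || any(i1 > d[2L]))
      stop("analysis window [", cfg$analysisWindow[1L], ", ",
           cfg$analysisWindow[2L], "] ms falls outside the recorded samples")
    len <- unique(i1 - i0 + 1L)
    segs <- vapply(seq_len(d[3L]), function(j)
      matrix(v[, i0[j]:i1[j], j], nrow = d[1L]),
      matrix(0, d[1L], len))
    x <- matrix(aperm(segs, c(2L, 1L, 3L)), nrow = len)
  } else {
    len <- d[2L]
    x <- matrix(aperm(v, c(2L, 1L, 3L)), nrow = len)
  }
  if (len / fs < 1 / cfg$frequencyBins)
    stop("analysis window too short to resolve the lowest requested ",
         "frequency bin (", cfg$frequencyBins, " Hz)")
  sp <- .mtm_psd(x, fs, cfg$spectralSmoothing)
  bn <- .bin_freqs(sp$freqs, sp$psd, cfg$frequencyBins, cfg$maxFreq)
  # columns of x run channel-fastest within trial: fold back to 3-d
  p3 <- array(bn$psd, c(length(bn$freqs), d[1L], d[3L]))
  list(freqs = bn$freqs, power = aperm(p3, c(2L, 1L, 3L)))
}

#' Detect and repair bad channels of a power map
#'
#' Channels whose mean power across all frequency bins exceeds the
#' across-channel mean by more than 2 standard deviations (computed over
#' all channels, outliers included) are flagged and replaced by the average
#' of their nearest non-flagged neighbours above and below (one-sided at
#' the probe edges). The criterion is applied once, not iterated.
#'
#' @param map a \code{\linkS4class{PowerMap}}.
#' @return \code{list(map = repaired PowerMap, flagged = integer vector)}.
#' @export
repairBadChannels <- function(map) {
  stopifnot(is(map, "PowerMap"))
  p <- map@power
  n <- nrow(p)
  if (n < 3L) stop("bad-channel repair requires at least 3 channels")
  meanP <- rowMeans(p)
  flagged <- which(meanP > mean(meanP) + 2 * stats::sd(meanP))
  if (length(flagged) > n / 2)
    stop("probe rejected: more than half of the channels (",
         length(flagged), "/", n, ") are bad")
  if (length(flagged)) {
    clean <- setdiff(seq_len(n), flagged)
    for (c0 in flagged) {
      below <- clean[clean < c0]
      above <- clean[clean > c0]
      nb <- c(if (length(below)) max(below), if (length(above)) min(above))
      p[c0, ] <- colMeans(p[nb, , drop = FALSE])
    }
  }
  list(map = powerMap(p, map@freqs, map@nTrialsAveraged, map@channelSpacing),
       flagged = flagged)
}

#' Normalize a power map per frequency column
#'
#' Divides every frequency column by its across-channel maximum, so each
#' column attains exactly 1 at the channel with the highest power at that
#' frequency. Applying it to an already-relative map is a no-op
#' (idempotence).
#'
#' @param map a \code{\linkS4class{PowerMap}} or
#'   \code{\linkS4class{RelativePowerMap}}.
#' @return a \code{\linkS4class{RelativePowerMap}}.
#' @examples
#' pm <- powerMap(matrix(c(2, 4, 8), 3, 1), freqs = 10)
#' relPower(relativePower(pm))   # 0.25 0.5 1
#' @export
relativePower <- function(map) {
  if (is(map, "RelativePowerMap")) {
    vals <- map@relPower
    al <- map@alignedTo
  } else if (is(map, "PowerMap")) {
    vals <- map@power
    al <- "none"
  } else stop("map must be a PowerMap or RelativePowerMap")
  cmax <- apply(vals, 2L, max)
  zero <- which(cmax <= 0)
  if (length(zero))
    stop("normalization undefined: all-zero power at frequency bin(s) ",
         paste(utils::head(map@freqs[zero], 5L), collapse = ", "), " Hz")
  relativePowerMap(sweep(vals, 2L, cmax, "/"), map@freqs, alignedTo = al,
                   channelSpacing = map@channelSpacing)
}

#' Band-averaged depth profile of a relative power map
#'
#' Averages, at each channel, the relative power over all frequency bins
#' with centre inside \code{[band[1], band[2]]} Hz.
#'
#' @param map a \code{\linkS4class{RelativePowerMap}}.
#' @param band \code{c(low, high)} Hz.
#' @return a \code{\linkS4class{BandProfile}}.
#' @export
bandProfile <- function(map, band) {
  stopifnot(is(map, "RelativePowerMap"), length(band) == 2L,
            band[1L] < band[2L])
  f <- map@freqs
  sel <- f >= band[1L] & f <= band[2L]
  if (!any(sel) || band[1L] > max(f) || band[2L] < min(f))
    stop("band ", band[1L], "-", band[2L],
         " Hz is outside the map's frequency range")
  vals <- rowMeans(map@relPower[, sel, drop = FALSE])
  new("BandProfile", band = as.numeric(band), values = vals,
      depthAxis = seq_len(nrow(map@relPower)))
}

.interp_channels <- function(vals, nOut) {
  n <- nrow(vals)
  xout <- seq(1, n, length.out = nOut)
  apply(vals, 2L, function(col)
    stats::approx(seq_len(n), col, xout = xout)$y)
}

#' @describeIn standardizeDepth linear interpolation of the channel axis of
#'   a power map onto \code{nOut} equally spaced depths spanning the first
#'   to last input channel.
#' @param map a power or relative power map.
#' @param nOut number of interpolated channels (default 24).
#' @export
setMethod("standardizeDepth", "PowerMap", function(map, nOut = 24L) {
  if (nOut < 2L) stop("nOut must be >= 2")
  if (nrow(map@power) < 2L) stop("need at least 2 channels to interpolate")
  powerMap(.interp_channels(map@power, nOut), map@freqs,
           map@nTrialsAveraged, map@channelSpacing)
})

#' @describeIn standardizeDepth relative maps are re-normalized per column
#'   after interpolation so the per-column maximum of 1 is restored.
#' @export
setMethod("standardizeDepth", "RelativePowerMap", function(map, nOut = 24L) {
  if (nOut < 2L) stop("nOut must be >= 2")
  if (nrow(map@relPower) < 2L) stop("need at least 2 channels to interpolate")
  vals <- .interp_channels(map@relPower, nOut)
  relativePower(relativePowerMap(sweep(vals, 2L, apply(vals, 2L, max), "/"),
                                 map@freqs, map@alignedTo,
                                 map@channelSpacing))
})

.rebin <- function(vals, f, width) {
  src <- unique(round(diff(f), 10))
  if (length(src) != 1L)
    stop("frequency bins must be regular before re-binning")
  ratio <- width / src
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("target bin width (", width,
         " Hz) must be an integer multiple of the source width (", src, " Hz)")
  ratio <- as.integer(round(ratio))
  nf <- length(f)
  if (nf %% ratio != 0L)
    stop("number of frequency bins (", nf,
         ") is not divisible by the re-binning factor (", ratio, ")")
  grp <- rep(seq_len(nf %/% ratio), each = ratio)
  newvals <- t(rowsum(t(vals), grp) / ratio)
  dimnames(newvals) <- NULL
  newf <- as.vector(rowsum(f, grp) / ratio)
  list(vals = newvals, freqs = newf)
}

#' @describeIn rebinFrequencies non-overlapping averaging of adjacent bins.
#' @param map a power or relative power map with regular frequency bins.
#' @param binWidth target bin width, Hz; must be an integer multiple of the
#'   source width.
#' @export
setMethod("rebinFrequencies", "PowerMap", function(map, binWidth = 5) {
  rb <- .rebin(map@power, map@freqs, binWidth)
  powerMap(rb$vals, rb$freqs, map@nTrialsAveraged, map@channelSpacing)
})

#' @describeIn rebinFrequencies relative maps are re-normalized per column
#'   after averaging.
#' @export
setMethod("rebinFrequencies", "RelativePowerMap", function(map, binWidth = 5) {
  rb <- .rebin(map@relPower, map@freqs, binWidth)
  relativePower(powerMap(rb$vals, rb$freqs,
                         channelSpacing = map@channelSpacing))
})
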