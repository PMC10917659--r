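#' @import methods
NULL

.CHANNEL_ORDERS <- c("superficial_first", "deep_first", "unknown")

#' LaminarRecording: multi-channel, multi-trial LFP voltage
#'
#' Container for a laminar-probe local field potential recording:
#' a channels x samples x trials voltage array (microvolts) plus the probe
#' geometry and stimulus metadata needed by all downstream analyses.
#'
#' Channel index 1 is the most superficial contact whenever the insertion
#' orientation is known. Recordings declared \code{deep_first} are flipped
#' on construction so this invariant always holds afterwards; the
#' \code{flippedOnIngest} slot records that this happened. \code{unknown}
#' order is permitted: the sign of the FLIP goodness-of-fit G resolves
#' orientation downstream.
#'
#' @slot voltage numeric array \code{[n_channels, n_samples, n_trials]}, uV.
#' @slot samplingRate sampling rate, Hz.
#' @slot channelSpacing inter-contact spacing, um (the \code{s} of the CSD
#'   second-spatial-difference estimator).
#' @slot channelOrder one of \code{"superficial_first"}, \code{"deep_first"},
#'   \code{"unknown"}; always \code{"superficial_first"} after a
#'   \code{deep_first} input has been flipped.
#' @slot stimulusOnset integer vector of stimulus-onset sample indices, one
#'   per trial (length 1 is recycled), or \code{integer(0)} when the
#'   recording has no stimulus alignment.
#' @slot conductivity tissue conductivity sigma, S/m; default 1 means CSD is
#'   reported in relative units.
#' @slot probeId free-text probe identifier.
#' @slot areaLabel free-text cortical area label.
#' @slot flippedOnIngest TRUE if the channel axis was reversed on
#'   construction because the input was declared \code{deep_first}.
#' @export
setClass("LaminarRecording",
  representation(
    voltage = "array",
    samplingRate = "numeric",
    channelSpacing = "numeric",
    channelOrder = "character",
    stimulusOnset = "integer",
    conductivity = "numeric",
    probeId = "character",
    areaLabel = "character",
    flippedOnIngest = "logical"
  ),
  prototype(
    channelOrder = "superficial_first",
    stimulusOnset = integer(0),
    conductivity = 1,
    probeId = NA_character_,
    areaLabel = NA_character_,
    flippedOnIngest = FALSE
  )
)

setValidity("LaminarRecording", function(object) {
  msg <- character(0)
  d <- dim(object@voltage)
  if (length(d) != 3L)
    msg <- c(msg, "voltage must be a 3-d array [channels x samples x trials]")
  else if (any(d < 1L))
    msg <- c(msg, "n_channels, n_samples and n_trials must all be >= 1")
  if (!all(is.finite(object@voltage))) {
    bad <- which(apply(!is.finite(object@voltage), 1L, any))
    msg <- c(msg, paste0("non-finite voltage on channel(s) ",
                         paste(bad, collapse = ", ")))
  }
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number (Hz)")
  if (length(object@channelSpacing) != 1L ||
      !is.finite(object@channelSpacing) || object@channelSpacing <= 0)
    msg <- c(msg, "channelSpacing must be a single positive number (um)")
  if (!object@channelOrder %in% .CHANNEL_ORDERS)
    msg <- c(msg, paste0("channelOrder must be one of: ",
                         paste(.CHANNEL_ORDERS, collapse = ", ")))
  if (length(object@stimulusOnset) &&
      length(d) == 3L &&
      !(length(object@stimulusOnset) %in% c(1L, d[3L])))
    msg <- c(msg, "stimulusOnset must have length 1 or n_trials")
  if (length(object@stimulusOnset) &&
      (any(object@stimulusOnset < 1L) ||
       (length(d) == 3L && any(object@stimulusOnset > d[2L]))))
    msg <- c(msg, "stimulusOnset sample indices out of range")
  if (length(object@conductivity) != 1L || !is.finite(object@conductivity) ||
      object@conductivity <= 0)
    msg <- c(msg, "conductivity must be a single positive number (S/m)")
  if (length(msg)) msg else TRUE
})

#' PowerMap: trial-averaged LFP power per channel and frequency
#'
#' @slot power numeric matrix \code{[n_channels, n_freqs]}, uV^2/Hz;
#'   non-negative.
#' @slot freqs frequency bin centres, Hz, strictly increasing.
#' @slot nTrialsAveraged number of trials averaged into the map.
#' @slot channelSpacing inter-contact spacing of the source probe, um
#'   (\code{NA} when unknown); carried so landmark channels can be mapped
#'   back to depths.
#' @export
setClass("PowerMap",
  representation(
    power = "matrix",
    freqs = "numeric",
    nTrialsAveraged = "integer",
    channelSpacing = "numeric"
  ),
  prototype(nTrialsAveraged = 1L, channelSpacing = NA_real_)
)

setValidity("PowerMap", function(object) {
  msg <- character(0)
  if (ncol(object@power) != length(object@freqs))
    msg <- c(msg, "ncol(power) must equal length(freqs)")
  if (any(!is.finite(object@power)) || any(object@power < 0))
    msg <- c(msg, "power must be finite and non-negative")
  if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RelativePowerMap: power map normalized per frequency column
#'
#' Each frequency column is divided by its across-channel maximum, so every
#' column attains exactly 1 at the channel with the highest power at that
#' frequency and all values lie in [0, 1].
#'
#' @slot relPower numeric matrix \code{[n_channels, n_freqs]} in [0, 1].
#' @slot freqs frequency bin centres, Hz.
#' @slot alignedTo \code{"none"} or \code{"crossover"} (after row-shifting
#'   maps to a common crossover channel for group comparisons).
#' @slot channelSpacing see \code{\linkS4class{PowerMap}}.
#' @export
setClass("RelativePowerMap",
  representation(
    relPower = "matrix",
    freqs = "numeric",
    alignedTo = "character",
    channelSpacing = "numeric"
  ),
  prototype(alignedTo = "none", channelSpacing = NA_real_)
)

setValidity("RelativePowerMap", function(object) {
  msg <- character(0)
  if (ncol(object@relPower) != length(object@freqs))
    msg <- c(msg, "ncol(relPower) must equal length(freqs)")
  if (any(!is.finite(object@relPower)))
    msg <- c(msg, "relPower must be finite")
  else {
    if (any(object@relPower < 0) || any(object@relPower > 1 + 1e-8))
      msg <- c(msg, "relPower values must lie in [0, 1]")
    cmax <- apply(object@relPower, 2L, max)
    if (nrow(object@relPower) >= 1L && any(abs(cmax - 1) > 1e-8))
      msg <- c(msg, "every frequency column must attain a maximum of 1")
  }
  if (!object@alignedTo %in% c("none", "crossover"))
    msg <- c(msg, "alignedTo must be 'none' or 'crossover'")
  if (length(msg)) msg else TRUE
})

#' BandProfile: band-averaged relative power as a function of depth
#'
#' @slot band \code{c(low, high)} Hz.
#' @slot values per-channel mean relative power over the band, in [0, 1].
#' @slot depthAxis channel indices, superficial to deep.
#' @export
setClass("BandProfile",
  representation(band = "numeric", values = "numeric", depthAxis = "integer")
)

setValidity("BandProfile", function(object) {
  msg <- character(0)
  if (length(object@band) != 2L || object@band[1L] >= object@band[2L])
    msg <- c(msg, "band must be c(low, high) with low < high")
  if (length(object@values) != length(object@depthAxis))
    msg <- c(msg, "values and depthAxis must have the same length")
  if (any(!is.finite(object@values)) || any(object@values < -1e-8) ||
      any(object@values > 1 + 1e-8))
    msg <- c(msg, "values must be finite and in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RangeFit: goodness-of-fit of the spectrolaminar pattern over a depth range
#'
#' Result of fitting opposing linear depth gradients to the alpha-beta and
#' gamma band profiles over channels \code{Di..Df}. The signed score is
#' G = ((s_ab - s_g)/2) * R2_ab * R2_g * f with the span regularizer
#' f = 0.04 * (Df - Di) + 0.72: +1 for a perfect upright motif (alpha-beta
#' rising, gamma falling with depth) over a span of 7, -1 for its mirror
#' image, 0 when the two gradients do not oppose.
#'
#' @slot Di,Df superficial and deep channel limits of the range.
#' @slot G signed goodness-of-fit.
#' @slot fReg the regularization term f.
#' @slot r2AlphaBeta,r2Gamma coefficients of determination of the two fits.
#' @slot slopeSignAlphaBeta,slopeSignGamma signs (+1/-1) of the fitted
#'   slopes; 0 when a profile has no variance over the range.
#' @slot pAlphaBeta,pGamma two-sided slope t-test p-values.
#' @export
setClass("RangeFit",
  representation(
    Di = "integer", Df = "integer",
    G = "numeric", fReg = "numeric",
    r2AlphaBeta = "numeric", r2Gamma = "numeric",
    slopeSignAlphaBeta = "numeric", slopeSignGamma = "numeric",
    pAlphaBeta = "numeric", pGamma = "numeric"
  )
)

setValidity("RangeFit", function(object) {
  msg <- character(0)
  if (object@Df <= object@Di)
    msg <- c(msg, "Df must exceed Di")
  expected_f <- 0.04 * (object@Df - object@Di) + 0.72
  if (is.finite(object@fReg) && abs(object@fReg - expected_f) > 1e-10)
    msg <- c(msg, "fReg must equal 0.04*(Df - Di) + 0.72")
  for (s in c("r2AlphaBeta", "r2Gamma")) {
    v <- slot(object, s)
    if (is.finite(v) && (v < -1e-10 || v > 1 + 1e-10))
      msg <- c(msg, paste(s, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' FlipResult: outcome of the frequency-based layer identification procedure
#'
#' A probe is identifiable when both band regressions over the optimal
#' depth range are significant (slope p < 0.05) and |G| exceeds the
#' threshold G_t (default 0.265). Landmark channels (gamma peak, alpha-beta
#' peak, alpha-beta/gamma crossover -> layers 2/3, 5/6, 4) are reported on
#' the standardized depth grid and, when the source probe geometry is
#' known, mapped back to original channels and depths in um.
#'
#' @slot bestFit the winning \code{\linkS4class{RangeFit}}.
#' @slot identifiable logical.
#' @slot orientation \code{"upright"} (G > 0, superficial-to-deep
#'   insertion), \code{"inverted"} (G < 0) or \code{"undetermined"}.
#' @slot crossoverChannel,gammaPeakChannel,alphabetaPeakChannel landmark
#'   channels on the standardized grid; NA when not identifiable.
#' @slot deltaP crossover selection objective at the chosen channel.
#' @slot gammaPeakBoundary,alphabetaPeakBoundary TRUE when the profile was
#'   monotone and the reported peak is a boundary channel, not a local
#'   maximum.
#' @slot nChannelsStd,nChannelsOriginal sizes of the standardized and the
#'   source channel grids.
#' @slot crossoverChannelOriginal,gammaPeakChannelOriginal,alphabetaPeakChannelOriginal
#'   landmarks mapped back to nearest original channels.
#' @slot crossoverDepthUm,gammaPeakDepthUm,alphabetaPeakDepthUm landmark
#'   depths from the most superficial contact, um (NA when spacing unknown).
#' @export
setClass("FlipResult",
  representation(
    bestFit = "RangeFit",
    identifiable = "logical",
    orientation = "character",
    crossoverChannel = "integer",
    gammaPeakChannel = "integer",
    alphabetaPeakChannel = "integer",
    deltaP = "numeric",
    gammaPeakBoundary = "logical",
    alphabetaPeakBoundary = "logical",
    nChannelsStd = "integer",
    nChannelsOriginal = "integer",
    crossoverChannelOriginal = "integer",
    gammaPeakChannelOriginal = "integer",
    alphabetaPeakChannelOriginal = "integer",
    crossoverDepthUm = "numeric",
    gammaPeakDepthUm = "numeric",
    alphabetaPeakDepthUm = "numeric"
  ),
  prototype(
    identifiable = FALSE,
    orientation = "undetermined",
    crossoverChannel = NA_integer_,
    gammaPeakChannel = NA_integer_,
    alphabetaPeakChannel = NA_integer_,
    deltaP = NA_real_,
    gammaPeakBoundary = FALSE,
    alphabetaPeakBoundary = FALSE,
    nChannelsOriginal = NA_integer_,
    crossoverChannelOriginal = NA_integer_,
    gammaPeakChannelOriginal = NA_integer_,
    alphabetaPeakChannelOriginal = NA_integer_,
    crossoverDepthUm = NA_real_,
    gammaPeakDepthUm = NA_real_,
    alphabetaPeakDepthUm = NA_real_
  )
)

setValidity("FlipResult", function(object) {
  msg <- character(0)
  if (!object@orientation %in% c("upright", "inverted", "undetermined"))
    msg <- c(msg, "orientation must be upright, inverted or undetermined")
  if (!object@identifiable && !is.na(object@crossoverChannel))
    msg <- c(msg, "landmarks must be NA when the probe is not identifiable")
  if (length(msg)) msg else TRUE
})

#' VFlipResult: frequency-variable FLIP outcome
#'
#' Extends \code{\linkS4class{FlipResult}} with the low/high frequency band
#' pair (searched on a 10-Hz grid) that maximized |G|.
#'
#' @slot lowBand winning low-frequency band \code{c(low, high)}, Hz.
#' @slot highBand winning high-frequency band \code{c(low, 150)}, Hz.
#' @export
setClass("VFlipResult",
  contains = "FlipResult",
  representation(lowBand = "numeric", highBand = "numeric")
)

setValidity("VFlipResult", function(object) {
  msg <- character(0)
  lb <- object@lowBand; hb <- object@highBand
  if (length(lb) != 2L || length(hb) != 2L)
    msg <- c(msg, "lowBand and highBand must each be c(low, high)")
  else {
    if (lb[2L] > 70) msg <- c(msg, "low band upper boundary must be <= 70 Hz")
    if (lb[2L] >= hb[1L])
      msg <- c(msg, "low band upper boundary must be below high band lower")
    if (hb[1L] <= 30) msg <- c(msg, "high band lower boundary must be > 30 Hz")
    if (any(c(lb, hb) %% 10 != 0))
      msg <- c(msg, "band boundaries must be multiples of 10 Hz")
  }
  if (length(msg)) msg else TRUE
})

#' CsdMap: z-scored current source density
#'
#' CSD(c,t) = -sigma * (V(c-2,t) - 2 V(c,t) + V(c+2,t)) / (2 s)^2, averaged
#' over trials, baseline-subtracted and divided by the across-trial s.e.m.
#' The first two and last two channels are undefined by the 5-point stencil
#' and excluded from \code{validChannels}.
#'
#' @slot csd numeric matrix \code{[n_channels, n_time]}, z-score units;
#'   invalid edge channels are NA rows.
#' @slot timeAxis time, ms relative to the stimulus.
#' @slot validChannels indices of channels with defined CSD.
#' @slot baselineWindow \code{c(start, end)} ms of the baseline used for
#'   normalization.
#' @slot nTrials number of trials the s.e.m. was computed across.
#' @export
setClass("CsdMap",
  representation(
    csd = "matrix",
    timeAxis = "numeric",
    validChannels = "integer",
    baselineWindow = "numeric",
    nTrials = "integer"
  )
)

setValidity("CsdMap", function(object) {
  msg <- character(0)
  if (ncol(object@csd) != length(object@timeAxis))
    msg <- c(msg, "ncol(csd) must equal length(timeAxis)")
  nch <- nrow(object@csd)
  if (any(object@validChannels < 3L) || any(object@validChannels > nch - 2L))
    msg <- c(msg, "validChannels must exclude the first two and last two channels")
  if (length(msg)) msg else TRUE
})

#' SimilarityResult: within- vs between-group image similarity of power maps
#'
#' @slot grandWithinA,grandWithinB grand within-area IS per group.
#' @slot grandBetween grand between-area IS.
#' @slot withinA,withinB per-repetition within-group IS values.
#' @slot between per-repetition between-group IS values (4 per repetition).
#' @slot nRepetitions number of random-halving repetitions.
#' @export
setClass("SimilarityResult",
  representation(
    grandWithinA = "numeric", grandWithinB = "numeric",
    grandBetween = "numeric",
    withinA = "numeric", withinB = "numeric", between = "numeric",
    nRepetitions = "integer"
  )
)

setValidity("SimilarityResult", function(object) {
  vals <- c(object@withinA, object@withinB, object@between)
  if (any(vals < -1e-8 | vals > 1 + 1e-8))
    "all IS values must lie in [0, 1]"
  else TRUE
})

#' SyntheticProbeSpec: ground-truth parameters for a synthetic laminar probe
#'
#' Defines the planted spectrolaminar motif: band-limited oscillations whose
#' amplitudes follow opposing linear depth gradients (gamma peaking
#' superficially, a low-frequency band peaking deep) over a 1/f^chi
#' background, with a configurable crossover depth and an optional
#' stimulus-evoked dipole producing a mid-depth current sink.
#'
#' @slot nChannels,channelSpacingUm,samplingRateHz,trialLengthMs,nTrials
#'   probe geometry and trial structure.
#' @slot crossoverDepth crossover location as a fraction of the probe span
#'   (0 = most superficial contact, 1 = deepest).
#' @slot gammaBand,lowBand \code{c(low, high)} Hz of the two planted
#'   oscillation bands.
#' @slot gradientContrast peak-to-trough ratio of band amplitude across
#'   depth (> 1 plants a motif; 1 plants none).
#' @slot noiseExponent chi of the 1/f^chi background power spectrum.
#' @slot snr in-band signal-to-background power ratio at the band's best
#'   channel.
#' @slot orientation \code{"upright"} or \code{"inverted"} (channel axis
#'   reversed after synthesis).
#' @slot evoked empty list, or a list with elements
#'   \code{sink_depth_fraction}, \code{latency_ms}, \code{duration_ms},
#'   \code{amplitude} describing the planted evoked sink.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticProbeSpec",
  representation(
    nChannels = "integer",
    channelSpacingUm = "numeric",
    samplingRateHz = "numeric",
    trialLengthMs = "numeric",
    nTrials = "integer",
    crossoverDepth = "numeric",
    gammaBand = "numeric",
    lowBand = "numeric",
    gradientContrast = "numeric",
    noiseExponent = "numeric",
    snr = "numeric",
    orientation = "character",
    evoked = "list",
    seed = "integer"
  )
)

setValidity("SyntheticProbeSpec", function(object) {
  msg <- character(0)
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  if (object@crossoverDepth <= 0 || object@crossoverDepth >= 1)
    msg <- c(msg, "crossoverDepth must lie strictly in (0, 1)")
  if (object@gradientContrast < 1)
    msg <- c(msg, "gradientContrast must be >= 1")
  if (length(object@lowBand) != 2L || length(object@gammaBand) != 2L ||
      object@lowBand[1L] >= object@lowBand[2L] ||
      object@gammaBand[1L] >= object@gammaBand[2L])
    msg <- c(msg, "lowBand and gammaBand must each be c(low, high), low < high")
  else if (max(object@lowBand[1L], object@gammaBand[1L]) <
           min(object@lowBand[2L], object@gammaBand[2L]))
    msg <- c(msg, "lowBand and gammaBand must not overlap")
  if (max(object@lowBand[2L], object@gammaBand[2L]) >
      object@samplingRateHz / 2)
    msg <- c(msg, "band edges must lie below the Nyquist frequency")
  if (!object@orientation %in% c("upright", "inverted"))
    msg <- c(msg, "orientation must be 'upright' or 'inverted'")
  if (length(object@evoked)) {
    need <- c("sink_depth_fraction", "latency_ms", "duration_ms", "amplitude")
    if (!all(need %in% names(object@evoked)))
      msg <- c(msg, paste0("evoked must contain: ", paste(need, collapse = ", ")))
    else if (object@evoked$latency_ms + object@evoked$duration_ms >=
             object@trialLengthMs)
      msg <- c(msg, "evoked latency + duration must fit inside the trial")
  }
  if (length(msg)) msg else TRUE
})
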