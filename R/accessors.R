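#' @include AllGenerics.R
NULL

#' Construct a LaminarRecording
#'
#' @param voltage numeric array \code{[n_channels, n_samples, n_trials]}
#'   (a matrix is treated as a single trial), microvolts.
#' @param samplingRate sampling rate, Hz.
#' @param channelSpacing inter-contact spacing, um.
#' @param channelOrder \code{"superficial_first"}, \code{"deep_first"} or
#'   \code{"unknown"}. \code{deep_first} input is flipped so that channel 1
#'   is the most superficial contact, and the flip is recorded in
#'   \code{flippedOnIngest}.
#' @param stimulusOnset stimulus-onset sample index per trial (length 1
#'   recycled), or \code{NULL}.
#' @param conductivity tissue conductivity, S/m (default 1: CSD in relative
#'   units).
#' @param probeId,areaLabel free-text identifiers.
#' @return a validated \code{\linkS4class{LaminarRecording}}.
#' @examples
#' rec <- laminarRecording(array(rnorm(4 * 100 * 2), c(4, 100, 2)),
#'                         samplingRate = 1000, channelSpacing = 100)
#' nChannels(rec)
#' @export
laminarRecording <- function(voltage, samplingRate, channelSpacing,
                             channelOrder = "superficial_first",
                             stimulusOnset = NULL, conductivity = 1,
                             probeId = NA_character_,
                             areaLabel = NA_character_) {
  if (is.matrix(voltage))
    voltage <- array(voltage, c(nrow(voltage), ncol(voltage), 1L))
  flipped <- FALSE
  if (identical(channelOrder, "deep_first")) {
    voltage <- voltage[rev(seq_len(dim(voltage)[1L])), , , drop = FALSE]
    channelOrder <- "superficial_first"
    flipped <- TRUE
  }
  new("LaminarRecording",
      voltage = voltage,
      samplingRate = as.numeric(samplingRate),
      channelSpacing = as.numeric(channelSpacing),
      channelOrder = channelOrder,
      stimulusOnset = if (is.null(stimulusOnset)) integer(0)
                      else as.integer(stimulusOnset),
      conductivity = as.numeric(conductivity),
      probeId = as.character(probeId),
      areaLabel = as.character(areaLabel),
      flippedOnIngest = flipped)
}

#' Construct a PowerMap
#' @param power non-negative matrix \code{[n_channels, n_freqs]}.
#' @param freqs frequency bin centres, Hz.
#' @param nTrialsAveraged trials averaged into the map.
#' @param channelSpacing source probe spacing, um, or NA.
#' @export
powerMap <- function(power, freqs, nTrialsAveraged = 1L,
                     channelSpacing = NA_real_) {
  new("PowerMap", power = as.matrix(power), freqs = as.numeric(freqs),
      nTrialsAveraged = as.integer(nTrialsAveraged),
      channelSpacing = as.numeric(channelSpacing))
}

#' Construct a RelativePowerMap (values must already be column-normalized)
#' @param relPower matrix in [0,1] with per-column maxima of 1.
#' @param freqs frequency bin centres, Hz.
#' @param alignedTo "none" or "crossover".
#' @param channelSpacing source probe spacing, um, or NA.
#' @seealso [relativePower()] to normalize a \code{PowerMap}.
#' @export
relativePowerMap <- function(relPower, freqs, alignedTo = "none",
                             channelSpacing = NA_real_) {
  new("RelativePowerMap", relPower = as.matrix(relPower),
      freqs = as.numeric(freqs), alignedTo = alignedTo,
      channelSpacing = as.numeric(channelSpacing))
}

## -- accessors ---------------------------------------------------------------

#' @describeIn laminarRecording the voltage array.
#' @param x a package object.
#' @export
setMethod("voltage", "LaminarRecording", function(x) x@voltage)
#' @export
setMethod("samplingRate", "LaminarRecording", function(x) x@samplingRate)
#' @export
setMethod("channelSpacing", "LaminarRecording", function(x) x@channelSpacing)
#' @export
setMethod("channelSpacing", "PowerMap", function(x) x@channelSpacing)
#' @export
setMethod("channelSpacing", "RelativePowerMap", function(x) x@channelSpacing)
#' @export
setMethod("channelOrder", "LaminarRecording", function(x) x@channelOrder)
#' @export
setMethod("stimulusOnset", "LaminarRecording", function(x) x@stimulusOnset)
#' @export
setMethod("nChannels", "LaminarRecording", function(x) dim(x@voltage)[1L])
#' @export
setMethod("nChannels", "PowerMap", function(x) nrow(x@power))
#' @export
setMethod("nChannels", "RelativePowerMap", function(x) nrow(x@relPower))
#' @export
setMethod("nTrials", "LaminarRecording", function(x) dim(x@voltage)[3L])
#' @export
setMethod("freqs", "PowerMap", function(x) x@freqs)
#' @export
setMethod("freqs", "RelativePowerMap", function(x) x@freqs)
#' @export
setMethod("powerValues", "PowerMap", function(x) x@power)
#' @export
setMethod("relPower", "RelativePowerMap", function(x) x@relPower)
#' @export
setMethod("profileValues", "BandProfile", function(x) x@values)
#' @export
setMethod("csdValues", "CsdMap", function(x) x@csd)
#' @export
setMethod("timeAxis", "CsdMap", function(x) x@timeAxis)
#' @export
setMethod("validChannels", "CsdMap", function(x) x@validChannels)
#' @export
setMethod("gValue", "RangeFit", function(x) x@G)
#' @export
setMethod("gValue", "FlipResult", function(x) x@bestFit@G)
#' @export
setMethod("isIdentifiable", "FlipResult", function(x) x@identifiable)
#' @export
setMethod("orientation", "FlipResult", function(x) x@orientation)
#' @export
setMethod("crossoverChannel", "FlipResult", function(x) x@crossoverChannel)
#' @export
setMethod("gammaPeakChannel", "FlipResult", function(x) x@gammaPeakChannel)
#' @export
setMethod("alphabetaPeakChannel", "FlipResult",
          function(x) x@alphabetaPeakChannel)
#' @export
setMethod("bestFit", "FlipResult", function(x) x@bestFit)
#' @export
setMethod("lowBand", "VFlipResult", function(x) x@lowBand)
#' @export
setMethod("highBand", "VFlipResult", function(x) x@highBand)

## -- show --------------------------------------------------------------------

setMethod("show", "LaminarRecording", function(object) {
  d <- dim(object@voltage)
  cat("LaminarRecording:", d[1L], "channels x", d[2L], "samples x",
      d[3L], "trials\n")
  cat("  sampling rate:", object@samplingRate, "Hz; spacing:",
      object@channelSpacing, "um; order:", object@channelOrder,
      if (object@flippedOnIngest) "(flipped on ingest)" else "", "\n")
  if (length(object@stimulusOnset))
    cat("  stimulus onset at sample(s):",
        paste(utils::head(unique(object@stimulusOnset), 3L), collapse = ", "),
        "\n")
})

setMethod("show", "PowerMap", function(object) {
  cat("PowerMap:", nrow(object@power), "channels x", length(object@freqs),
      "frequency bins (", min(object@freqs), "-", max(object@freqs),
      "Hz ), averaged over", object@nTrialsAveraged, "trial(s)\n")
})

setMethod("show", "RelativePowerMap", function(object) {
  cat("RelativePowerMap:", nrow(object@relPower), "channels x",
      length(object@freqs), "frequency bins (", min(object@freqs), "-",
      max(object@freqs), "Hz ), aligned to:", object@alignedTo, "\n")
})

setMethod("show", "BandProfile", function(object) {
  cat("BandProfile", paste0(object@band[1L], "-", object@band[2L]), "Hz over",
      length(object@values), "channels\n")
})

setMethod("show", "RangeFit", function(object) {
  cat(sprintf("RangeFit: channels %d-%d, G = %.3f (f = %.2f, R2_ab = %.3f, R2_g = %.3f)\n",
              object@Di, object@Df, object@G, object@fReg,
              object@r2AlphaBeta, object@r2Gamma))
})

setMethod("show", "FlipResult", function(object) {
  cat("FlipResult:", if (object@identifiable) "identifiable"
      else "NOT identifiable",
      sprintf("(G = %.3f, orientation = %s)\n",
              object@bestFit@G, object@orientation))
  cat(sprintf("  optimal range: channels %d-%d of %d standardized\n",
              object@bestFit@Di, object@bestFit@Df, object@nChannelsStd))
  if (object@identifiable)
    cat(sprintf("  landmarks (std grid): gamma peak %d (L2/3), crossover %d (L4), alpha-beta peak %d (L5/6)\n",
                object@gammaPeakChannel, object@crossoverChannel,
                object@alphabetaPeakChannel))
})

setMethod("show", "VFlipResult", function(object) {
  callNextMethod()
  cat(sprintf("  bands: low %g-%g Hz, high %g-%g Hz\n",
              object@lowBand[1L], object@lowBand[2L],
              object@highBand[1L], object@highBand[2L]))
})

setMethod("show", "CsdMap", function(object) {
  cat("CsdMap:", nrow(object@csd), "channels x", ncol(object@csd),
      "time bins (", min(object@timeAxis), "to", max(object@timeAxis),
      "ms ), z-scored across", object@nTrials, "trials\n")
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult (%d repetitions):\n", object@nRepetitions))
  cat(sprintf("  grand within-area IS: A = %.3f, B = %.3f\n",
              object@grandWithinA, object@grandWithinB))
  cat(sprintf("  grand between-area IS: %.3f\n", object@grandBetween))
})

setMethod("show", "SyntheticProbeSpec", function(object) {
  cat("SyntheticProbeSpec:", object@nChannels, "channels,",
      object@nTrials, "trials of", object@trialLengthMs, "ms at",
      object@samplingRateHz, "Hz\n")
  cat(sprintf("  motif: low band %g-%g Hz (deep), gamma %g-%g Hz (superficial), crossover at depth %.2f, contrast %.1f, snr %.1f, 1/f^%.1f background, %s\n",
              object@lowBand[1L], object@lowBand[2L],
              object@gammaBand[1L], object@gammaBand[2L],
              object@crossoverDepth, object@gradientContrast, object@snr,
              object@noiseExponent, object@orientation))
  if (length(object@evoked))
    cat(sprintf("  evoked sink at depth %.2f, latency %g ms\n",
                object@evoked$sink_depth_fraction, object@evoked$latency_ms))
})
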