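#' Analysis configuration
#'
#' Bundles the tunable parameters of the spectrolaminar pipeline. Defaults
#' follow the published procedure: a 1-s analysis window (500 ms pre- to
#' 500 ms post-stimulus), 2-Hz multitaper spectral smoothing, 1-Hz
#' frequency bins from 1 to 150 Hz (the DC bin is excluded; recordings are
#' AC-coupled), FLIP subranges alpha-beta 10-19 Hz and gamma 75-150 Hz,
#' identifiability threshold G_t = 0.265, minimum depth-range span of 7
#' channels, and depth standardization to 24 interpolated channels.
#'
#' @param analysisWindow \code{c(start, end)} ms relative to stimulus onset
#'   (used when the recording has stimulus onsets; otherwise the full trial
#'   is analysed).
#' @param spectralSmoothing half-bandwidth of the multitaper estimate, Hz.
#' @param frequencyBins output bin width, Hz (use 5 for cross-species map
#'   comparison).
#' @param maxFreq highest analysed frequency, Hz.
#' @param flipLowBand,flipHighBand FLIP's fixed regression subranges, Hz.
#' @param gThreshold identifiability threshold on |G|.
#' @param minRangeChannels minimum |Df - Di| of the depth-range search.
#' @param nInterpChannels standardized depth-grid size.
#' @param displayBands named list of the three display bands, Hz.
#' @param alpha significance level of the slope t-tests.
#' @param vflipGridStart lowest allowed low-band lower boundary for the
#'   vFLIP band grid, Hz.
#' @param rngSeed seed recorded in run manifests.
#' @return a validated list of class \code{"AnalysisConfig"}.
#' @examples
#' cfg <- analysisConfig(frequencyBins = 5)
#' cfg$flipLowBand
#' @export
analysisConfig <- function(analysisWindow = c(-500, 500),
                           spectralSmoothing = 2,
                           frequencyBins = 1,
                           maxFreq = 150,
                           flipLowBand = c(10, 19),
                           flipHighBand = c(75, 150),
                           gThreshold = 0.265,
                           minRangeChannels = 7L,
                           nInterpChannels = 24L,
                           displayBands = list(delta_theta = c(1, 6),
                                               alpha_beta = c(10, 30),
                                               gamma = c(50, 150)),
                           alpha = 0.05,
                           vflipGridStart = 10,
                           rngSeed = NA_integer_) {
  stopifnot(length(analysisWindow) == 2L,
            analysisWindow[1L] < analysisWindow[2L],
            spectralSmoothing > 0, frequencyBins > 0, maxFreq > 0)
  bands <- c(list(flipLowBand, flipHighBand), displayBands)
  for (b in bands)
    if (length(b) != 2L || b[1L] >= b[2L])
      stop("every band must be c(low, high) with low < high")
  if (gThreshold <= 0) stop("gThreshold must be positive")
  if (minRangeChannels < 2L) stop("minRangeChannels must be >= 2")
  if (nInterpChannels < 2L) stop("nInterpChannels must be >= 2")
  structure(list(analysisWindow = analysisWindow,
                 spectralSmoothing = spectralSmoothing,
                 frequencyBins = frequencyBins,
                 maxFreq = maxFreq,
                 flipLowBand = flipLowBand,
                 flipHighBand = flipHighBand,
                 gThreshold = gThreshold,
                 minRangeChannels = as.integer(minRangeChannels),
                 nInterpChannels = as.integer(nInterpChannels),
                 displayBands = displayBands,
                 alpha = alpha,
                 vflipGridStart = vflipGridStart,
                 rngSeed = rngSeed),
            class = "AnalysisConfig")
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig:\n")
  cat("  analysis window:", x$analysisWindow[1L], "to", x$analysisWindow[2L],
      "ms;  smoothing: +/-", x$spectralSmoothing, "Hz;  bins:",
      x$frequencyBins, "Hz up to", x$maxFreq, "Hz\n")
  cat("  FLIP bands:", paste(x$flipLowBand, collapse = "-"), "Hz vs",
      paste(x$flipHighBand, collapse = "-"), "Hz;  G_t =", x$gThreshold,
      ";  min span =", x$minRangeChannels, ";  standardized channels =",
      x$nInterpChannels, "\n")
  invisible(x)
}
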