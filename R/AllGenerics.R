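#' @include AllClasses.R
NULL

#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("channelSpacing", function(x) standardGeneric("channelSpacing"))
#' @export
setGeneric("channelOrder", function(x) standardGeneric("channelOrder"))
#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))
#' @export
setGeneric("powerValues", function(x) standardGeneric("powerValues"))
#' @export
setGeneric("relPower", function(x) standardGeneric("relPower"))
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @export
setGeneric("csdValues", function(x) standardGeneric("csdValues"))
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @export
setGeneric("validChannels", function(x) standardGeneric("validChannels"))
#' @export
setGeneric("gValue", function(x) standardGeneric("gValue"))
#' @export
setGeneric("isIdentifiable", function(x) standardGeneric("isIdentifiable"))
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @export
setGeneric("crossoverChannel", function(x) standardGeneric("crossoverChannel"))
#' @export
setGeneric("gammaPeakChannel", function(x) standardGeneric("gammaPeakChannel"))
#' @export
setGeneric("alphabetaPeakChannel",
           function(x) standardGeneric("alphabetaPeakChannel"))
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))
#' @export
setGeneric("lowBand", function(x) standardGeneric("lowBand"))
#' @export
setGeneric("highBand", function(x) standardGeneric("highBand"))

#' Compute the trial-averaged multitaper power map of a recording
#' @export
setGeneric("computePowerMap",
           function(rec, cfg = analysisConfig(), ...)
             standardGeneric("computePowerMap"))

#' Standardize the depth (channel) axis of a map by linear interpolation
#' @export
setGeneric("standardizeDepth",
           function(map, nOut = 24L) standardGeneric("standardizeDepth"))

#' Average adjacent frequency bins into wider bins
#' @export
setGeneric("rebinFrequencies",
           function(map, binWidth = 5) standardGeneric("rebinFrequencies"))

#' Run FLIP on a power map
#' @export
setGeneric("flip",
           function(map, cfg = analysisConfig(), ...) standardGeneric("flip"))

#' Run frequency-variable FLIP on a power map
#' @export
setGeneric("vflip",
           function(map, cfg = analysisConfig(), ...) standardGeneric("vflip"))

#' Compute raw per-trial current source density
#' @export
setGeneric("computeCsd", function(rec, ...) standardGeneric("computeCsd"))

#' Serialize an analysis result to a delimited-text file
#' @export
setGeneric("writeResult",
           function(result, path, ...) standardGeneric("writeResult"))
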