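#' @include flip.R
NULL

.band_cols <- function(freqs, band) {
  which(freqs >= band[1L] & freqs <= band[2L])
}

# Shared FLIP engine: optimal-range search on a standardized relative map
# for a given band pair, identifiability decision and landmark extraction.
.flip_core <- function(rel, cfg, low, high, nOrig, spacing) {
  f <- rel@freqs
  li <- .band_cols(f, low); hi <- .band_cols(f, high)
  if (!length(li) || !length(hi))
    stop("no frequency bins inside band ",
         if (!length(li)) paste(low, collapse = "-")
         else paste(high, collapse = "-"), " Hz")
  fit <- .search_map_ranges(rel@relPower[, li, drop = FALSE],
                            rel@relPower[, hi, drop = FALSE],
                            cfg$minRangeChannels)
  .flip_assemble(rel, cfg, low, high, fit, nOrig, spacing)
}

.flip_assemble <- function(rel, cfg, low, high, fit, nOrig, spacing) {
  n <- nrow(rel@relPower)
  identifiable <- is.finite(fit@G) &&
    fit@pAlphaBeta < cfg$alpha && fit@pGamma < cfg$alpha &&
    abs(fit@G) > cfg$gThreshold
  orient <- "undetermined"
  cross <- gpk <- apk <- NA_integer_
  dP <- NA_real_
  gbd <- abd <- FALSE
  if (identifiable) {
    orient <- if (fit@G > 0) "upright" else "inverted"
    pA <- bandProfile(rel, low)@values
    pG <- bandProfile(rel, high)@values
    mirrored <- fit@G < 0
    if (mirrored) {
      pA <- rev(pA); pG <- rev(pG)
      fitm <- fit
      fitm@Di <- n + 1L - fit@Df
      fitm@Df <- n + 1L - fit@Di
    } else fitm <- fit
    co <- tryCatch(selectCrossover(pA, pG, fitm), error = function(e) NULL)
    if (is.null(co)) {
      identifiable <- FALSE
      orient <- "undetermined"
    } else {
      pk <- selectPeaks(pA, pG, fitm)
      cross <- co$channel; dP <- co$deltaP
      gpk <- pk$gammaPeak; apk <- pk$alphabetaPeak
      gbd <- pk$gammaBoundary; abd <- pk$alphabetaBoundary
      if (mirrored) {
        cross <- n + 1L - cross
        gpk <- n + 1L - gpk
        apk <- n + 1L - apk
      }
    }
  }
  to_orig <- function(ch) {
    if (is.na(ch) || is.na(nOrig)) return(list(ch = NA_integer_, um = NA_real_))
    pos <- 1 + (ch - 1) * (nOrig - 1) / (n - 1)
    list(ch = as.integer(round(pos)),
         um = if (is.na(spacing)) NA_real_ else (pos - 1) * spacing)
  }
  oc <- to_orig(cross); og <- to_orig(gpk); oa <- to_orig(apk)
  new("FlipResult",
      bestFit = fit,
      identifiable = identifiable,
      orientation = orient,
      crossoverChannel = as.integer(cross),
      gammaPeakChannel = as.integer(gpk),
      alphabetaPeakChannel = as.integer(apk),
      deltaP = dP,
      gammaPeakBoundary = gbd,
      alphabetaPeakBoundary = abd,
      nChannelsStd = n,
      nChannelsOriginal = as.integer(nOrig),
      crossoverChannelOriginal = oc$ch,
      gammaPeakChannelOriginal = og$ch,
      alphabetaPeakChannelOriginal = oa$ch,
      crossoverDepthUm = oc$um,
      gammaPeakDepthUm = og$um,
      alphabetaPeakDepthUm = oa$um)
}

.as_rel_std <- function(map, cfg) {
  nOrig <- nChannels(map)
  if (nOrig < cfg$minRangeChannels + 1L)
    stop("FLIP needs at least ", cfg$minRangeChannels + 1L,
         " channels; the map has ", nOrig)
  rel <- relativePower(map)
  std <- if (nOrig == cfg$nInterpChannels) rel
         else standardizeDepth(rel, cfg$nInterpChannels)
  list(rel = std, nOrig = nOrig, spacing = map@channelSpacing)
}

#' Frequency-based layer identification procedure (FLIP)
#'
#' Runs the full procedure on a power map: depth standardization to
#' \code{cfg$nInterpChannels} interpolated channels, band profiles over the
#' fixed alpha-beta (10-19 Hz) and gamma (75-150 Hz) subranges with
#' within-range renormalization at every candidate depth range, exhaustive
#' optimal-range search maximizing |G|, the identifiability decision (both
#' slope p-values < \code{cfg$alpha} and |G| > \code{cfg$gThreshold}), and
#' landmark extraction. The gamma peak, alpha-beta/gamma crossover and
#' alpha-beta peak mark layers 2/3, 4 and 5/6 respectively. G > 0 indicates
#' an upright (superficial-to-deep) insertion; G < 0 an inverted one, in
#' which case landmarks are extracted on the mirrored profiles and mapped
#' back. Non-identifiable probes return \code{identifiable = FALSE} with
#' full diagnostics and no landmarks.
#'
#' @param map a \code{\linkS4class{PowerMap}} or
#'   \code{\linkS4class{RelativePowerMap}} with at least 8 channels.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return a \code{\linkS4class{FlipResult}}.
#' @examples
#' spec <- syntheticProbeSpec(seed = 1L)
#' rec <- generateProbe(spec)$recording
#' flip(computePowerMap(rec))
#' @export
setMethod("flip", "PowerMap", function(map, cfg = analysisConfig(), ...) {
  s <- .as_rel_std(map, cfg)
  .flip_core(s$rel, cfg, cfg$flipLowBand, cfg$flipHighBand, s$nOrig,
             s$spacing)
})

#' @rdname flip
#' @export
setMethod("flip", "RelativePowerMap",
          function(map, cfg = analysisConfig(), ...) {
  s <- .as_rel_std(map, cfg)
  .flip_core(s$rel, cfg, cfg$flipLowBand, cfg$flipHighBand, s$nOrig,
             s$spacing)
})

# all legal vFLIP band pairs on the 10-Hz grid:
# low (a, b): b <= 70, b < high lower; high (c, 150): c > 30.
.vflip_band_pairs <- function(gridStart = 10) {
  pairs <- list()
  for (a in seq(gridStart, 60, by = 10))
    for (b in seq(a + 10, 70, by = 10))
      for (cc in seq(max(40, b + 10), 140, by = 10))
        pairs[[length(pairs) + 1L]] <-
          list(low = c(a, b), high = c(cc, 150))
  pairs
}

.vflip_impl <- function(map, cfg) {
  s <- .as_rel_std(map, cfg)
  rel <- s$rel
  f <- rel@freqs
  if (max(f) < 150 - cfg$frequencyBins * 2)
    stop("vFLIP requires the frequency axis to reach 150 Hz")
  pairs <- .vflip_band_pairs(cfg$vflipGridStart)
  bestFit <- NULL; bestPair <- NULL
  for (p in pairs) {
    li <- .band_cols(f, p$low); hi <- .band_cols(f, p$high)
    if (!length(li) || !length(hi)) next
    fit <- .search_map_ranges(rel@relPower[, li, drop = FALSE],
                              rel@relPower[, hi, drop = FALSE],
                              cfg$minRangeChannels)
    if (is.null(bestFit) || abs(fit@G) > abs(bestFit@G) + 1e-12) {
      bestFit <- fit; bestPair <- p
    }
  }
  if (is.null(bestFit))
    stop("the frequency grid cannot form any legal vFLIP band pair")
  fr <- .flip_assemble(rel, cfg, bestPair$low, bestPair$high, bestFit,
                       s$nOrig, s$spacing)
  new("VFlipResult", fr, lowBand = as.numeric(bestPair$low),
      highBand = as.numeric(bestPair$high))
}

#' Frequency-variable FLIP (vFLIP)
#'
#' Repeats the FLIP analysis for every legal combination of a
#' lower-frequency versus higher-frequency band on a 10-Hz grid and keeps
#' the combination (bands plus depth range) yielding the highest |G|.
#' Legal pairs satisfy: the low band's upper boundary is at most 70 Hz and
#' below the high band's lower boundary; the high band's lower boundary
#' exceeds 30 Hz; the high band's upper boundary is fixed at 150 Hz; all
#' boundaries are multiples of 10 Hz.
#'
#' @inheritParams flip
#' @return a \code{\linkS4class{VFlipResult}}.
#' @export
setMethod("vflip", "PowerMap", function(map, cfg = analysisConfig(), ...)
  .vflip_impl(map, cfg))

#' @rdname vflip
#' @export
setMethod("vflip", "RelativePowerMap",
          function(map, cfg = analysisConfig(), ...) .vflip_impl(map, cfg))
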