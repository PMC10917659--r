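#' @include io.R spectral.R flip-run.R csd.R
NULL

#' Load an analysis configuration from a JSON file
#'
#' The file holds a JSON object whose names match the arguments of
#' \code{\link{analysisConfig}}; unknown names are rejected. Flags given in
#' \code{...} override the file.
#'
#' @param path JSON file, or \code{NULL} for defaults.
#' @param ... overrides.
#' @export
loadConfig <- function(path = NULL, ...) {
  base <- if (is.null(path)) list()
          else jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  base[names(over)] <- over
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(base), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(analysisConfig, base)
}

#' Run the full spectrolaminar pipeline on a recording
#'
#' Reads the recording, computes the trial-averaged power map, repairs bad
#' channels, derives the relative power map, runs FLIP and vFLIP, computes
#' the z-scored CSD when the recording has stimulus onsets and at least two
#' trials, and writes every artifact plus a JSON run manifest (command,
#' configuration snapshot, input hashes, seed, package version, timestamp)
#' to \code{outDir}. Non-identifiable probes are a normal outcome, not an
#' error.
#'
#' @param recPath,metaPath recording container and sidecar
#'   (\code{\link{readRecording}}).
#' @param cfgPath optional JSON configuration (\code{\link{loadConfig}}).
#' @param outDir output directory (created if needed).
#' @param seed seed recorded in the manifest and used for any stochastic
#'   step.
#' @param verbose print progress.
#' @return invisibly, \code{list(powerMap, flaggedChannels, relativeMap,
#'   flipResult, vflipResult, csdMap, manifestPath)}.
#' @export
runPipeline <- function(recPath, metaPath, cfgPath = NULL,
                        outDir = ".", seed = NA_integer_, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  cfg <- loadConfig(cfgPath, rngSeed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rec <- readRecording(recPath, metaPath)
  say("recording: ", nChannels(rec), " channels, ", nTrials(rec), " trials")
  pm <- computePowerMap(rec, cfg)
  rep <- repairBadChannels(pm)
  if (length(rep$flagged))
    say("repaired bad channel(s): ", paste(rep$flagged, collapse = ", "))
  rel <- relativePower(rep$map)
  writeResult(rep$map, file.path(outDir, "power_map.tsv"))
  writeResult(rel, file.path(outDir, "relative_power_map.tsv"))
  fr <- flip(rel, cfg)
  writeResult(fr, file.path(outDir, "flip_result.tsv"))
  say("FLIP: ", if (fr@identifiable) "identifiable" else "not identifiable",
      sprintf(" (G = %.3f)", fr@bestFit@G))
  vr <- vflip(rel, cfg)
  writeResult(vr, file.path(outDir, "vflip_result.tsv"))
  cm <- NULL
  if (length(stimulusOnset(rec)) && nTrials(rec) >= 2L &&
      nChannels(rec) >= 5L) {
    cm <- normalizeCsd(computeCsd(rec))
    writeResult(cm, file.path(outDir, "csd_map.tsv"))
  } else {
    say("CSD stage skipped (needs stimulus onsets, >= 2 trials and >= 5 channels)")
  }
  manifest <- list(
    command = "run_pipeline",
    config = unclass(cfg),
    inputs = list(data = unname(tools::md5sum(recPath)),
                  metadata = unname(tools::md5sum(metaPath))),
    seed = seed,
    tool_version = as.character(utils::packageVersion("spectrolaminar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(powerMap = rep$map, flaggedChannels = rep$flagged,
                 relativeMap = rel, flipResult = fr, vflipResult = vr,
                 csdMap = cm, manifestPath = mp))
}
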