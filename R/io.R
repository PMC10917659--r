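#' @include accessors.R
NULL

.meta_schema <- c("sampling_rate_hz", "channel_spacing_um", "n_channels",
                  "n_samples", "n_trials")

#' Read a laminar recording from a matrix container plus metadata sidecar
#'
#' The voltage array lives in a flat container — either raw little-endian
#' float64 (\code{data_format = "binary_float64"}) or whitespace-delimited
#' text — in channel-fastest order (channel, then sample, then trial). The
#' JSON sidecar names every field with explicit units
#' (\code{sampling_rate_hz}, \code{channel_spacing_um}, ...) and carries
#' the dimensions. Channel order is propagated from the sidecar, never
#' inferred; \code{deep_first} data are flipped on ingestion so channel 1
#' is superficial (see \code{\link{laminarRecording}}).
#'
#' @param path data file.
#' @param metadataPath JSON sidecar.
#' @return a validated \code{\linkS4class{LaminarRecording}}.
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, metadataPath) {
  if (!file.exists(path)) stop("data file not found: ", path)
  if (!file.exists(metadataPath))
    stop("metadata sidecar not found: ", metadataPath)
  meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  missing <- setdiff(.meta_schema, names(meta))
  if (length(missing))
    stop("metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  dims <- c(meta$n_channels, meta$n_samples, meta$n_trials)
  fmt <- if (is.null(meta$data_format)) "binary_float64" else meta$data_format
  vals <- switch(fmt,
    binary_float64 = readBin(path, what = "double", n = prod(dims) + 1L,
                             size = 8L, endian = "little"),
    text = scan(path, what = numeric(), quiet = TRUE),
    stop("unknown data_format: ", fmt))
  if (length(vals) != prod(dims))
    stop("container holds ", length(vals), " values but metadata declares ",
         paste(dims, collapse = " x "), " = ", prod(dims),
         " (contradictory n_channels/n_samples/n_trials)")
  laminarRecording(array(vals, dims),
                   samplingRate = meta$sampling_rate_hz,
                   channelSpacing = meta$channel_spacing_um,
                   channelOrder = if (is.null(meta$channel_order))
                     "unknown" else meta$channel_order,
                   stimulusOnset = meta$stimulus_onset_sample,
                   conductivity = if (is.null(meta$conductivity_s_per_m)) 1
                                  else meta$conductivity_s_per_m,
                   probeId = if (is.null(meta$probe_id)) NA_character_
                             else meta$probe_id,
                   areaLabel = if (is.null(meta$area_label)) NA_character_
                               else meta$area_label)
}

#' Write a laminar recording and its metadata sidecar
#'
#' @param rec a \code{\linkS4class{LaminarRecording}}.
#' @param path data file to write.
#' @param metadataPath JSON sidecar to write.
#' @param format \code{"binary_float64"} (default; preferred for
#'   multi-trial data) or \code{"text"}.
#' @export
writeRecording <- function(rec, path, metadataPath,
                           format = c("binary_float64", "text")) {
  format <- match.arg(format)
  d <- dim(rec@voltage)
  meta <- list(sampling_rate_hz = rec@samplingRate,
               channel_spacing_um = rec@channelSpacing,
               n_channels = d[1L], n_samples = d[2L], n_trials = d[3L],
               channel_order = rec@channelOrder,
               stimulus_onset_sample = rec@stimulusOnset,
               conductivity_s_per_m = rec@conductivity,
               probe_id = rec@probeId,
               area_label = rec@areaLabel,
               data_format = format)
  jsonlite::write_json(meta, metadataPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (format == "binary_float64")
    writeBin(as.vector(rec@voltage), path, size = 8L, endian = "little")
  else
    writeLines(formatC(as.vector(rec@voltage), format = "g", digits = 17),
               path)
  invisible(path)
}

.write_map_tsv <- function(vals, colHeads, colPrefix, path) {
  df <- data.frame(channel = seq_len(nrow(vals)),
                   formatC(vals, format = "g", digits = 17),
                   check.names = FALSE)
  names(df) <- c("channel", paste0(colPrefix, colHeads))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn writeResult power maps: TSV with channels as rows and one
#'   column per frequency bin (header row gives the bin centres).
#' @param result the object to serialize.
#' @param path output file.
#' @export
setMethod("writeResult", "PowerMap", function(result, path, ...) {
  .write_map_tsv(result@power, result@freqs, "freq_", path)
})

#' @rdname writeResult
#' @export
setMethod("writeResult", "RelativePowerMap", function(result, path, ...) {
  .write_map_tsv(result@relPower, result@freqs, "freq_", path)
})

#' @rdname writeResult
#' @export
setMethod("writeResult", "CsdMap", function(result, path, ...) {
  .write_map_tsv(result@csd, result@timeAxis, "time_ms_", path)
})

.flip_record <- function(x) {
  fit <- x@bestFit
  rows <- list(
    c("G", formatC(fit@G, format = "g", digits = 17), "dimensionless"),
    c("f_reg", formatC(fit@fReg, format = "g", digits = 17), "dimensionless"),
    c("D_i", fit@Di, "channel_std"),
    c("D_f", fit@Df, "channel_std"),
    c("R2_alphabeta", formatC(fit@r2AlphaBeta, format = "g", digits = 17), ""),
    c("R2_gamma", formatC(fit@r2Gamma, format = "g", digits = 17), ""),
    c("p_alphabeta", formatC(fit@pAlphaBeta, format = "g", digits = 17), ""),
    c("p_gamma", formatC(fit@pGamma, format = "g", digits = 17), ""),
    c("identifiable", tolower(as.character(x@identifiable)), ""),
    c("orientation", x@orientation, ""),
    c("crossover_channel", x@crossoverChannel, "channel_std"),
    c("gamma_peak_channel", x@gammaPeakChannel, "channel_std"),
    c("alphabeta_peak_channel", x@alphabetaPeakChannel, "channel_std"),
    c("delta_P", formatC(x@deltaP, format = "g", digits = 17), ""),
    c("crossover_channel_original", x@crossoverChannelOriginal, "channel"),
    c("gamma_peak_channel_original", x@gammaPeakChannelOriginal, "channel"),
    c("alphabeta_peak_channel_original", x@alphabetaPeakChannelOriginal,
      "channel"),
    c("crossover_depth_um", formatC(x@crossoverDepthUm, format = "g",
                                    digits = 17), "um"),
    c("gamma_peak_depth_um", formatC(x@gammaPeakDepthUm, format = "g",
                                     digits = 17), "um"),
    c("alphabeta_peak_depth_um", formatC(x@alphabetaPeakDepthUm,
                                         format = "g", digits = 17), "um"),
    c("n_channels_std", x@nChannelsStd, "count"),
    c("n_channels_original", x@nChannelsOriginal, "count"))
  if (is(x, "VFlipResult"))
    rows <- c(rows, list(
      c("low_band_hz", paste(x@lowBand, collapse = "-"), "Hz"),
      c("high_band_hz", paste(x@highBand, collapse = "-"), "Hz")))
  rows
}

#' @describeIn writeResult FLIP/vFLIP results: a structured-text record of
#'   \code{key<TAB>value<TAB>units} lines in deterministic order.
#' @export
setMethod("writeResult", "FlipResult", function(result, path, ...) {
  rows <- .flip_record(result)
  writeLines(vapply(rows, function(r)
    paste(as.character(r), collapse = "\t"), character(1)), path)
  invisible(path)
})

#' Read a map written by writeResult back into a map object
#'
#' @param path TSV file with a \code{channel} column and
#'   \code{freq_*}/\code{time_ms_*} columns.
#' @param type \code{"relative"}, \code{"power"} or \code{"csd"}.
#' @export
readMap <- function(path, type = c("relative", "power", "csd")) {
  type <- match.arg(type)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(vals) <- NULL
  heads <- names(df)[-1L]
  ax <- as.numeric(sub("^(freq_|time_ms_)", "", heads))
  switch(type,
         relative = relativePower(powerMap(vals, ax)),
         power = powerMap(vals, ax),
         csd = new("CsdMap", csd = vals, timeAxis = ax,
                   validChannels =
                     as.integer(3:(nrow(vals) - 2L)),
                   baselineWindow = c(NA_real_, NA_real_),
                   nTrials = NA_integer_))
}

#' Read a structured-text result record into a named list
#' @param path file written by \code{writeResult} for a FLIP result.
#' @export
readResultRecord <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("key", "value", "units"),
                          colClasses = "character", fill = TRUE)
  out <- as.list(df$value)
  names(out) <- df$key
  out
}
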