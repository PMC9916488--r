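#' Read a urodynamic recording from delimited text
#'
#' Reads the CSV dialect written by [writeRecording()]: optional `#`-prefixed
#' `key=value` metadata lines, then a header row and comma-separated data.
#' Mandatory columns are time and pressure; EMG and volume are optional.
#' The sampling rate is taken from the metadata header when present and
#' inferred from the time column otherwise.
#'
#' @param path file to read.
#' @param formatSpec named list mapping channels to column names; defaults to
#'   `list(time = "time_s", pressure = "pressure_cmh2o", emg = "emg_v",
#'   volume = "volume_ul")`.
#' @return A validated [UDIRecording-class].
#' @examples
#' sim <- simulateRecording(simParams("sham", durationS = 300, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' writeRecording(sim$recording, f)
#' rec <- readRecording(f)
#' rec
#' @export
readRecording <- function(path, formatSpec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- list(time = "time_s", pressure = "pressure_cmh2o",
               emg = "emg_v", volume = "volume_ul")
  if (!is.null(formatSpec)) spec[names(formatSpec)] <- formatSpec

  # metadata header
  con <- file(path, "r")
  meta <- character(0)
  nSkip <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    meta <- c(meta, ln)
    nSkip <- nSkip + 1L
  }
  close(con)
  kv <- list()
  for (ln in meta) {
    body <- trimws(sub("^#", "", ln))
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      kv[[key]] <- val
    }
  }
  num <- function(key) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else NULL

  dt <- data.table::fread(path, skip = nSkip, header = TRUE, sep = ",")
  for (ch in c("time", "pressure")) {
    if (!spec[[ch]] %in% names(dt))
      stop("mandatory column missing: ", spec[[ch]])
  }
  timeS <- dt[[spec$time]]
  if (any(diff(timeS) < 0)) stop("non-monotone time column")

  fs <- num("sampling_rate_hz")
  if (is.null(fs)) fs <- (length(timeS) - 1) / (timeS[length(timeS)] - timeS[1])
  infusion <- num("infusion_rate_ul_min")
  if (is.null(infusion)) infusion <- 10
  volRate <- num("volume_rate_hz")
  if (is.null(volRate)) volRate <- NA_real_
  chr <- function(key, default = NA_character_)
    if (!is.null(kv[[key]])) kv[[key]] else default
  wk <- num("week")

  UDIRecording(
    time = timeS, pressure = dt[[spec$pressure]],
    emg = if (spec$emg %in% names(dt)) dt[[spec$emg]] else NULL,
    volume = if (spec$volume %in% names(dt)) dt[[spec$volume]] else NULL,
    samplingRate = fs, volumeRate = volRate, infusionRate = infusion,
    animalId = chr("animal_id"), group = chr("group"),
    week = if (is.null(wk)) NA_real_ else wk)
}

#' Write a urodynamic recording as delimited text
#'
#' Writes `#`-prefixed metadata (sampling rate, infusion rate, scale rate,
#' animal/group/week labels) followed by a comma-separated table with columns
#' `time_s`, `pressure_cmh2o` and, when the channels are present, `emg_v` and
#' `volume_ul`. Numeric values are written at full round-trip precision, so
#' [readRecording()] recovers an equal recording.
#'
#' @param recording a [UDIRecording-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "UDIRecording"))
  validObject(recording)
  meta <- c(
    "# udi_recording v1",
    sprintf("# sampling_rate_hz=%.12g", recording@samplingRate),
    sprintf("# infusion_rate_ul_min=%.12g", recording@infusionRate))
  if (!is.na(recording@volumeRate))
    meta <- c(meta, sprintf("# volume_rate_hz=%.12g", recording@volumeRate))
  if (!is.na(recording@animalId))
    meta <- c(meta, paste0("# animal_id=", recording@animalId))
  if (!is.na(recording@group))
    meta <- c(meta, paste0("# group=", recording@group))
  if (!is.na(recording@week))
    meta <- c(meta, sprintf("# week=%.12g", recording@week))
  dt <- data.table::data.table(time_s = recording@time,
                               pressure_cmh2o = recording@pressure)
  if (length(recording@emg)) dt[, emg_v := recording@emg]
  if (length(recording@volume)) dt[, volume_ul := recording@volume]
  writeLines(meta, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, sep = ",")
  invisible(path)
}

#' Write / read simulator ground truth as a JSON side-car
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @return `writeGroundTruth` returns `path` invisibly; `readGroundTruth`
#'   returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(list(
    void_times_s = truth@voidTimes,
    pmax_times_s = truth@pmaxTimes,
    thresh_times_s = truth@threshTimes,
    emg_pattern = truth@emgPattern,
    trapped_void_flags = truth@trappedVoidFlags,
    recorded_void_volumes_ul = truth@recordedVoidVolumes,
    pressure_range_cmh2o = truth@pressureRange
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # empty JSON arrays simplify to empty lists; unlist() flattens either way
  asNum <- function(v) as.numeric(unlist(v))
  new("GroundTruth",
    voidTimes = asNum(x$void_times_s),
    pmaxTimes = asNum(x$pmax_times_s),
    threshTimes = asNum(x$thresh_times_s),
    emgPattern = as.character(unlist(x$emg_pattern)),
    trappedVoidFlags = as.logical(unlist(x$trapped_void_flags)),
    recordedVoidVolumes = asNum(x$recorded_void_volumes_ul),
    pressureRange = asNum(x$pressure_range_cmh2o))
}
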