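# On-disk session layout (all plain text):
#   position.csv     time_s,x_cm,y_cm[,speed_cm_s]
#   units.csv        unit_id,region,spike_width_ms
#   spikes.csv       unit_id,time_s
#   lfp.csv          time_s,<ch>...   + lfp.json {sample_rate_hz, channel_ids, t0_s}
#   wells.csv        well_id,x_cm,y_cm,radius_cm
#   well_events.csv  time_s,well_id,kind
#   epochs.csv       label,start_s,end_s
#   metadata.json
# Numerics are written as %.17g so read(write(S)) is an exact identity and
# repeated writes are byte-identical.

sessionFiles <- c("position.csv", "units.csv", "spikes.csv", "lfp.csv",
                  "lfp.json", "wells.csv", "well_events.csv", "epochs.csv")

#' Write a session to a directory
#'
#' Serialises every component of a \linkS4class{Session} to the plain-text
#' layout documented in the package vignette. Output is deterministic:
#' writing the same session twice produces byte-identical files, and
#' \code{readSession(writeSession(s))} reproduces \code{s} exactly.
#'
#' @param session a valid \linkS4class{Session}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @seealso \code{\link{readSession}}
#' @export
writeSession <- function(session, dir) {
  validObject(session)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  p <- session@position
  pos <- data.frame(time_s = p@timeS, x_cm = p@xCm, y_cm = p@yCm)
  if (length(p@speedCmS)) pos$speed_cm_s <- p@speedCmS
  writeCsv17(pos, file.path(dir, "position.csv"))

  units <- data.frame(
    unit_id = vapply(session@units, function(u) u@unitId, character(1)),
    region = vapply(session@units, function(u) u@region, character(1)),
    spike_width_ms = vapply(session@units, function(u) u@spikeWidthMs, numeric(1)))
  writeCsv17(units, file.path(dir, "units.csv"))

  spikes <- data.frame(
    unit_id = rep(units$unit_id,
                  vapply(session@units, function(u) length(u@spikeTimes), integer(1))),
    time_s = unlist(lapply(session@units, function(u) u@spikeTimes), use.names = FALSE))
  writeCsv17(spikes, file.path(dir, "spikes.csv"))

  lfp <- session@lfp
  n <- nrow(lfp@samples)
  lfpDf <- data.frame(time_s = lfp@t0S + (seq_len(n) - 1L) / lfp@sampleRateHz)
  for (j in seq_along(lfp@channelIds)) lfpDf[[lfp@channelIds[j]]] <- lfp@samples[, j]
  writeCsv17(lfpDf, file.path(dir, "lfp.csv"))
  writeLines(jsonlite::toJSON(list(sample_rate_hz = lfp@sampleRateHz,
                                   channel_ids = lfp@channelIds,
                                   t0_s = lfp@t0S),
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "lfp.json"))

  writeCsv17(session@wells, file.path(dir, "wells.csv"))
  writeCsv17(session@wellEvents, file.path(dir, "well_events.csv"))
  writeCsv17(session@epochs, file.path(dir, "epochs.csv"))
  writeLines(jsonlite::toJSON(session@metadata, auto_unbox = TRUE, digits = NA),
             file.path(dir, "metadata.json"))
  invisible(dir)
}

readCsvChecked <- function(path, required) {
  if (!file.exists(path)) stop("missing session file: ", path)
  df <- as.data.frame(data.table::fread(path, colClasses = NULL))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("malformed %s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")))
  df
}

#' Read a session from a directory
#'
#' Parses the on-disk layout written by \code{\link{writeSession}} and
#' returns a fully validated \linkS4class{Session}. Violations of the data
#' contract (unsorted spike times, units without spikes, unknown well ids,
#' missing files or columns) raise descriptive errors naming the offending
#' file and unit.
#'
#' @param dir session directory.
#' @return A \linkS4class{Session}.
#' @export
readSession <- function(dir) {
  if (!dir.exists(dir)) stop("session directory not found: ", dir)
  pos <- readCsvChecked(file.path(dir, "position.csv"),
                        c("time_s", "x_cm", "y_cm"))
  if (anyNA(pos$time_s) || anyNA(pos$x_cm) || anyNA(pos$y_cm))
    stop("malformed position.csv: non-numeric row")
  position <- PositionTrace(pos$time_s, pos$x_cm, pos$y_cm,
                            if ("speed_cm_s" %in% names(pos)) pos$speed_cm_s
                            else numeric(0))

  units <- readCsvChecked(file.path(dir, "units.csv"),
                          c("unit_id", "region", "spike_width_ms"))
  spikes <- readCsvChecked(file.path(dir, "spikes.csv"), c("unit_id", "time_s"))
  if (anyNA(spikes$time_s)) stop("malformed spikes.csv: non-numeric spike time")
  spikeList <- split(spikes$time_s, factor(spikes$unit_id, levels = units$unit_id))
  trains <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    uid <- as.character(units$unit_id[i])
    st <- spikeList[[uid]]
    if (is.null(st) || !length(st))
      stop(sprintf("spikes.csv: unit '%s' has zero spikes", uid))
    if (any(diff(st) <= 0))
      stop(sprintf("spikes.csv: spike times of unit '%s' are not strictly increasing", uid))
    trains[[i]] <- SpikeTrain(uid, units$region[i], st, units$spike_width_ms[i])
  }
  names(trains) <- as.character(units$unit_id)

  meta <- file.path(dir, "lfp.json")
  if (!file.exists(meta)) stop("missing session file: ", meta)
  lfpMeta <- jsonlite::fromJSON(meta)
  lfpDf <- readCsvChecked(file.path(dir, "lfp.csv"), "time_s")
  chans <- as.character(lfpMeta$channel_ids)
  if (!all(chans %in% names(lfpDf)))
    stop("malformed lfp.csv: channel columns do not match lfp.json channel_ids")
  lfp <- LfpBundle(unname(as.matrix(lfpDf[, chans, drop = FALSE])),
                   sampleRateHz = as.numeric(lfpMeta$sample_rate_hz),
                   channelIds = chans, t0S = as.numeric(lfpMeta$t0_s))

  wells <- readCsvChecked(file.path(dir, "wells.csv"),
                          c("well_id", "x_cm", "y_cm", "radius_cm"))
  wells$well_id <- as.character(wells$well_id)
  wellEvents <- readCsvChecked(file.path(dir, "well_events.csv"),
                               c("time_s", "well_id", "kind"))
  wellEvents$well_id <- as.character(wellEvents$well_id)
  wellEvents$kind <- as.character(wellEvents$kind)
  epochsPath <- file.path(dir, "epochs.csv")
  epochs <- if (file.exists(epochsPath))
    readCsvChecked(epochsPath, c("label", "start_s", "end_s"))
  else data.frame(label = character(0), start_s = numeric(0), end_s = numeric(0))
  epochs$label <- as.character(epochs$label)

  metaPath <- file.path(dir, "metadata.json")
  metadata <- if (file.exists(metaPath)) as.list(jsonlite::fromJSON(metaPath)) else list()

  s <- Session(position, trains, lfp, wells, wellEvents, epochs, metadata)
  validObject(s)
  s
}

#' Write generator ground truth as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output file path (JSON).
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  writeLines(jsonlite::toJSON(list(unit_labels = truth@unitLabels,
                                   swr_truth = truth@swrTruth,
                                   bout_schedule = truth@boutSchedule),
                              auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' Read generator ground truth from JSON
#' @param path file written by \code{\link{writeGroundTruth}}.
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::fromJSON(path)
  new("GroundTruth", unitLabels = as.data.frame(x$unit_labels),
      swrTruth = as.data.frame(x$swr_truth),
      boutSchedule = as.data.frame(x$bout_schedule))
}
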