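# Recording artifact I/O: timestamped CSV with a Marker column, zipped with
# session/device/manifest JSON metadata. The ZIP container is written
# directly (store method, no compression) so no external archiver is
# needed; reading uses R's internal unzip.

.leBytes <- function(x, nbytes) {
  x <- as.double(x)
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  out
}

# Write a standard ZIP archive with stored (uncompressed) members.
# `members` is a named list of raw vectors.
zipWrite <- function(path, members) {
  con <- file(path, "wb")
  on.exit(close(con))
  # DOS date 1980-01-01, time 00:00
  dosTime <- .leBytes(0, 2)
  dosDate <- .leBytes(33, 2)
  offsets <- numeric(length(members))
  crcs <- numeric(length(members))
  offset <- 0
  for (i in seq_along(members)) {
    nm <- charToRaw(names(members)[i])
    dat <- members[[i]]
    crcs[i] <- .crc32_raw(dat)
    offsets[i] <- offset
    hdr <- c(.leBytes(0x04034b50, 4), .leBytes(20, 2), .leBytes(0, 2),
             .leBytes(0, 2), dosTime, dosDate, .leBytes(crcs[i], 4),
             .leBytes(length(dat), 4), .leBytes(length(dat), 4),
             .leBytes(length(nm), 2), .leBytes(0, 2), nm)
    writeBin(hdr, con)
    writeBin(dat, con)
    offset <- offset + length(hdr) + length(dat)
  }
  cdStart <- offset
  cdSize <- 0
  for (i in seq_along(members)) {
    nm <- charToRaw(names(members)[i])
    dat <- members[[i]]
    cd <- c(.leBytes(0x02014b50, 4), .leBytes(20, 2), .leBytes(20, 2),
            .leBytes(0, 2), .leBytes(0, 2), dosTime, dosDate,
            .leBytes(crcs[i], 4), .leBytes(length(dat), 4),
            .leBytes(length(dat), 4), .leBytes(length(nm), 2),
            .leBytes(0, 2), .leBytes(0, 2), .leBytes(0, 2), .leBytes(0, 2),
            .leBytes(0, 4), .leBytes(offsets[i], 4), nm)
    writeBin(cd, con)
    cdSize <- cdSize + length(cd)
  }
  eocd <- c(.leBytes(0x06054b50, 4), .leBytes(0, 2), .leBytes(0, 2),
            .leBytes(length(members), 2), .leBytes(length(members), 2),
            .leBytes(cdSize, 4), .leBytes(cdStart, 4), .leBytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

deviceSpecToList <- function(dev) {
  list(name = dev@name, channel_names = as.list(dev@channelNames),
       sampling_rate_hz = dev@samplingRate, reference = dev@reference,
       provisional = dev@provisional)
}

deviceSpecFromList <- function(x) {
  new("DeviceSpec", name = x$name,
      channelNames = unlist(x$channel_names),
      samplingRate = x$sampling_rate_hz, reference = x$reference,
      provisional = isTRUE(x$provisional))
}

#' Write a recording to its ZIP archive
#'
#' Serializes the recording as a standard ZIP containing
#' `data.csv` (header `timestamp,<ch1>,...,<chK>,Marker`, one row per
#' sample, voltages at full round-trip precision), `session.json` (echo of
#' the session configuration), `device.json` and `manifest.json` (format
#' version, creation time). Timestamps are seconds from session start;
#' marker 0 means "no event".
#'
#' @param recording An [EEGRecording-class].
#' @param path Output `.zip` path.
#' @param created Creation timestamp string for the manifest; the default
#'   uses the current time, while callers that need byte-reproducible
#'   archives (the CLI) pass a fixed value.
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(recording, path,
                           created = format(Sys.time(),
                                            "%Y-%m-%dT%H:%M:%S%z")) {
  validObject(recording)
  df <- data.table::as.data.table(t(recording@data))
  data.table::setnames(df, channelNames(recording))
  df <- cbind(data.table::data.table(timestamp = recording@timestamps), df,
              data.table::data.table(Marker = recording@marker))
  csvFile <- tempfile(fileext = ".csv")
  on.exit(unlink(csvFile))
  data.table::fwrite(df, csvFile)
  sessionList <- if (is.null(recording@session)) list()
                 else sessionConfigToList(recording@session)
  manifest <- list(
    format = "remoteeeg-recording",
    format_version = 1L,
    created = created,
    software = as.character(utils::packageVersion("remoteEEG")),
    n_samples = nSamples(recording),
    n_channels = length(channelNames(recording)),
    metadata = recording@metadata
  )
  members <- list(
    "data.csv" = readBin(csvFile, "raw", file.info(csvFile)$size),
    "session.json" = charToRaw(as.character(jsonlite::toJSON(
      sessionList, auto_unbox = TRUE, digits = NA))),
    "device.json" = charToRaw(as.character(jsonlite::toJSON(
      deviceSpecToList(recording@device), auto_unbox = TRUE, digits = NA))),
    "manifest.json" = charToRaw(as.character(jsonlite::toJSON(
      manifest, auto_unbox = TRUE, digits = NA)))
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  zipWrite(path, members)
  invisible(path)
}

#' Read a recording from its ZIP archive
#'
#' Inverse of [writeRecording()]: `read(write(r))` reproduces timestamps
#' and voltages to at least nine significant digits (in practice exactly,
#' via round-trip decimal formatting) and markers exactly. Structural
#' defects — missing members, header mismatch with the device montage,
#' non-monotone timestamps — raise format errors naming the defect.
#'
#' @param path Path to an archive produced by [writeRecording()].
#' @return An [EEGRecording-class].
#' @export
readRecording <- function(path) {
  stopIf(!file.exists(path), "recording archive '%s' does not exist", path)
  listing <- tryCatch(
    utils::unzip(path, list = TRUE, unzip = "internal"),
    error = function(e) stop(sprintf("'%s' is not a readable ZIP archive: %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  need <- c("data.csv", "session.json", "device.json", "manifest.json")
  for (m in need)
    stopIf(!m %in% listing$Name, "format error: %s absent from '%s'", m,
           path)
  exdir <- tempfile("rec")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir, unzip = "internal")

  manifest <- jsonlite::fromJSON(file.path(exdir, "manifest.json"),
                                 simplifyVector = FALSE)
  stopIf(is.null(manifest$format_version) || manifest$format_version != 1L,
         "format error: unsupported format_version in manifest.json")
  dev <- deviceSpecFromList(jsonlite::fromJSON(
    file.path(exdir, "device.json"), simplifyVector = FALSE))
  sessionList <- jsonlite::fromJSON(file.path(exdir, "session.json"),
                                    simplifyVector = FALSE)
  session <- if (length(sessionList))
    sessionConfigFromList(sessionList, where = "session.json") else NULL

  df <- data.table::fread(file.path(exdir, "data.csv"))
  cols <- names(df)
  stopIf(cols[1L] != "timestamp" || cols[length(cols)] != "Marker",
         "format error: data.csv header must be timestamp,<channels>,Marker")
  chans <- cols[-c(1L, length(cols))]
  stopIf(!identical(chans, dev@channelNames),
         "format error: data.csv channels (%s) do not match device.json (%s)",
         paste(chans, collapse = ","),
         paste(dev@channelNames, collapse = ","))
  ts <- df$timestamp
  stopIf(length(ts) > 1L && any(diff(ts) <= 0),
         "format error: timestamps in data.csv are not strictly increasing")
  dat <- t(as.matrix(df[, chans, with = FALSE]))
  rownames(dat) <- chans
  meta <- manifest$metadata
  new("EEGRecording", timestamps = ts, data = dat,
      marker = as.integer(df$Marker), device = dev, session = session,
      metadata = if (is.null(meta)) list() else meta)
}
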