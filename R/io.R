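#' Write an epoch to a directory of per-channel CSV files
#'
#' Each channel is written to `<NAME>.csv` with a first comment line
#' `# units=<u> rate=<r>`, a `t_seconds,value` header, and one row per
#' sample. Missing samples are written as `NA`. Epoch identifiers go to
#' `epoch.json`. The round trip through [read_epoch()] is lossless for
#' timestamps, values, units, names and missingness.
#'
#' @param epoch A `pfr_epoch`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_epoch <- function(epoch, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- epoch_meta(epoch)
  for (nm in meta$channel) {
    ch <- epoch_channel(epoch, nm)
    m <- meta[meta$channel == nm, ]
    f <- file.path(path, paste0(nm, ".csv"))
    hdr <- sprintf("# units=%s rate=%s", m$units[1L],
                   if (is.na(m$rate[1L])) "NA" else format(m$rate[1L]))
    writeLines(c(hdr, "t_seconds,value"), f)
    readr::write_csv(
      tibble::tibble(t_seconds = ch$t, value = ch$v),
      f, append = TRUE, col_names = FALSE, na = "NA"
    )
  }
  jsonlite::write_json(
    list(patient_id = attr(epoch, "patient_id"),
         epoch_id = attr(epoch, "epoch_id"),
         channels = meta$channel),
    file.path(path, "epoch.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read an epoch from a directory of per-channel CSV files
#'
#' Inverse of [write_epoch()]. Unknown channel names (absent from the
#' canonical inventory) and non-monotone timestamps are rejected; the
#' offending row index is reported for the latter.
#'
#' @param path Directory produced by [write_epoch()] (or following its
#'   layout).
#' @return A `pfr_epoch`.
#' @export
read_epoch <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such epoch directory: %s", path),
                              call. = FALSE)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("epoch directory contains no channel files",
                                call. = FALSE)
  ids <- if (file.exists(file.path(path, "epoch.json"))) {
    jsonlite::read_json(file.path(path, "epoch.json"), simplifyVector = TRUE)
  } else list(patient_id = "P0", epoch_id = basename(path))
  channels <- lapply(files, function(f) {
    nm <- sub("\\.csv$", "", basename(f))
    if (!nm %in% names(.channel_units)) {
      stop(sprintf("unknown channel name '%s' in %s", nm, f), call. = FALSE)
    }
    hdr <- readLines(f, n = 1L)
    units <- sub(".*units=(\\S+).*", "\\1", hdr)
    rate <- sub(".*rate=(\\S+).*", "\\1", hdr)
    rate <- if (rate == "NA") NULL else as.numeric(rate)
    dat <- readr::read_csv(f, skip = 2L,
                           col_names = c("t_seconds", "value"),
                           col_types = "dd", na = "NA", progress = FALSE)
    if (nrow(dat) > 1L && any(diff(dat$t_seconds) <= 0)) {
      bad <- which(diff(dat$t_seconds) <= 0)[1L] + 1L
      stop(sprintf("non-monotone timestamps in %s at row %d", f, bad),
           call. = FALSE)
    }
    channel_series(dat$t_seconds, dat$value, nm, units = units, rate = rate)
  })
  as_epoch(channels, patient_id = ids$patient_id, epoch_id = ids$epoch_id)
}
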