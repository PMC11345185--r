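#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @useDynLib icpfr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
## usethis namespace: end
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# canonical channel inventory: name -> expected units
.channel_units <- c(
  ABP   = "mmHg",
  ICP   = "mmHg",
  CPP   = "mmHg",
  PERF  = "mL/hg/min",
  CBF   = "mL/s",
  PBTO2 = "mmHg",
  ICT   = "degC",
  SPO2  = "%",
  ETCO2 = "mmHg",
  HR    = "beats/min",
  RR    = "breaths/min"
)

#' Construct a single monitored channel series
#'
#' A channel series is a tibble with columns `t` (seconds since epoch start)
#' and `v` (measured values), carrying the channel name, physical units and
#' nominal sampling rate as attributes. Missing data are encoded as explicit
#' `NA` values and are never dropped.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param v Numeric vector of values, same length as `t`.
#' @param name Channel identifier, e.g. `"ABP"`, `"ICP"`, `"PERF"`.
#' @param units Physical units; defaults to the canonical units for `name`.
#' @param rate Nominal sampling rate in Hz.
#'
#' @return A tibble of class `pfr_channel` with columns `t` and `v`.
#' @export
channel_series <- function(t, v, name, units = NULL, rate = NULL) {
  if (length(t) != length(v)) {
    stop("`t` and `v` must have the same length", call. = FALSE)
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stop(sprintf("timestamps must be strictly increasing (row %d)", bad),
         call. = FALSE)
  }
  name <- as.character(name)[1L]
  if (is.null(units)) {
    if (!name %in% names(.channel_units)) {
      stop(sprintf("unknown channel name '%s'; supply `units` explicitly", name),
           call. = FALSE)
    }
    units <- .channel_units[[name]]
  }
  if (name %in% names(.channel_units) && units != .channel_units[[name]]) {
    stop(sprintf("units '%s' inconsistent with channel '%s' (expected '%s')",
                 units, name, .channel_units[[name]]), call. = FALSE)
  }
  out <- tibble::tibble(t = as.numeric(t), v = as.numeric(v))
  attr(out, "channel") <- name
  attr(out, "units") <- units
  attr(out, "rate") <- rate
  class(out) <- c("pfr_channel", class(out))
  out
}

channel_name <- function(x) attr(x, "channel")
channel_units <- function(x) attr(x, "units")
channel_rate <- function(x) attr(x, "rate")

#' Assemble channels into a patient epoch
#'
#' A patient epoch bundles one or more channel series recorded over a common
#' time origin. It is stored in long form (columns `channel`, `t`, `v`) with
#' per-channel units and rates in the `meta` attribute, so the usual dplyr
#' verbs apply directly.
#'
#' @param channels List of [channel_series()] objects, at most one per name.
#' @param patient_id,epoch_id Identifiers carried through the pipeline.
#'
#' @return A tibble of class `pfr_epoch` with columns `channel`, `t`, `v`.
#' @export
as_epoch <- function(channels, patient_id = "P0", epoch_id = "E0") {
  nms <- vapply(channels, channel_name, character(1))
  if (anyDuplicated(nms)) {
    stop("at most one channel per name in an epoch", call. = FALSE)
  }
  meta <- tibble::tibble(
    channel = nms,
    units = vapply(channels, channel_units, character(1)),
    rate = vapply(channels, function(x) {
      r <- channel_rate(x)
      if (is.null(r)) NA_real_ else as.numeric(r)
    }, numeric(1))
  )
  out <- purrr::map2_dfr(channels, nms, function(ch, nm) {
    tibble::tibble(channel = nm, t = ch$t, v = ch$v)
  })
  attr(out, "meta") <- meta
  attr(out, "patient_id") <- patient_id
  attr(out, "epoch_id") <- epoch_id
  class(out) <- c("pfr_epoch", class(out))
  out
}

epoch_meta <- function(epoch) attr(epoch, "meta")

#' Extract one channel from an epoch
#'
#' @param epoch A `pfr_epoch`.
#' @param name Channel name.
#' @return A `pfr_channel` tibble, or `NULL` if the channel is absent.
#' @export
epoch_channel <- function(epoch, name) {
  meta <- epoch_meta(epoch)
  if (is.null(meta) || !name %in% meta$channel) return(NULL)
  rows <- epoch[epoch$channel == name, , drop = FALSE]
  m <- meta[meta$channel == name, ]
  channel_series(rows$t, rows$v, name, units = m$units[1L],
                 rate = if (is.na(m$rate[1L])) NULL else m$rate[1L])
}

#' @export
print.pfr_epoch <- function(x, ...) {
  meta <- epoch_meta(x)
  cat(sprintf(
    "<pfr_epoch %s/%s: %s; %.1f min>\n",
    attr(x, "patient_id") %||% "?", attr(x, "epoch_id") %||% "?",
    paste(meta$channel, collapse = ", "),
    (max(x$t) - min(x$t)) / 60
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restore epoch attributes after a dplyr operation that stripped them.
rebuild_epoch <- function(df, template) {
  attr(df, "meta") <- epoch_meta(template)
  attr(df, "patient_id") <- attr(template, "patient_id")
  attr(df, "epoch_id") <- attr(template, "epoch_id")
  if (!inherits(df, "pfr_epoch")) class(df) <- c("pfr_epoch", class(df))
  df
}
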