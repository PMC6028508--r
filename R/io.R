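#' Table of flow-cytometry events (one intensity per event)
#'
#' @param intensities Finite, positive event intensities.
#' @param channel_name Name of the fluorescence channel.
#' @param source Path the events came from.
#' @param acquisition_label Free-text label (e.g. "day-0", "day-6").
#' @return A list of class \code{"event_table"}.
#' @export
event_table <- function(intensities, channel_name = "intensity",
                        source = NA_character_,
                        acquisition_label = NA_character_) {
  if (length(intensities) == 0L) stop("no events", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (any(intensities <= 0)) {
    warning(sum(intensities <= 0),
            " non-positive intensities dropped", call. = FALSE)
    intensities <- intensities[intensities > 0]
    if (!length(intensities)) stop("no positive events", call. = FALSE)
  }
  structure(list(intensities = as.numeric(intensities),
                 channel_name = channel_name, source = source,
                 acquisition_label = acquisition_label),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events, channel '%s'",
              length(x$intensities), x$channel_name))
  if (!is.na(x$acquisition_label)) cat(" (", x$acquisition_label, ")",
                                       sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.event_table <- function(x) length(x$intensities)

#' Read per-event intensities from a file
#'
#' Reads the plain CSV event dialect (header row including an
#' \code{intensity} column, one row per event; the [export_experiment()]
#' output). FCS files are recognized by their magic bytes but binary FCS
#' parsing is not provided — export the channel of interest to CSV
#' upstream.
#'
#' @param path File path.
#' @param channel Column to read; default \code{"intensity"}.
#' @param acquisition_label Optional label stored on the result.
#' @return An [event_table()].
#' @export
read_events <- function(path, channel = "intensity",
                        acquisition_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 3L)
  if (identical(rawToChar(magic), "FCS"))
    stop("'", path, "' is a binary FCS file; export the channel to the ",
         "CSV event dialect (header 'cell_id,intensity') first",
         call. = FALSE)
  d <- utils::read.csv(path)
  if (!channel %in% names(d))
    stop("column '", channel, "' not found; available: ",
         paste(names(d), collapse = ", "), call. = FALSE)
  event_table(d[[channel]], channel_name = channel, source = path,
              acquisition_label = acquisition_label)
}

#' Read a ground-truth sidecar written by [export_experiment()]
#'
#' @param path Path to a \code{truth_*.csv} file.
#' @return Data frame with \code{cell_id}, \code{population},
#'   \code{divisions}.
#' @export
read_ground_truth <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "population", "divisions")
  if (!all(need %in% names(d)))
    stop("ground-truth file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Default bin axis derived from a day-0 sample
#'
#' 256 log-spaced bins between the autofluorescence floor (default 1
#' percent of the day-0 median) and the day-0 99.9th percentile. Choosing
#' the axis once from the day-0 sample and reusing it for chase samples
#' keeps all histograms on a common axis.
#'
#' @param day0 Day-0 intensities (or an [event_table()]).
#' @param n_bins Number of bins.
#' @param floor,ceiling Optional overrides of the axis limits.
#' @return An [intensity_bins()] axis.
#' @export
default_bins <- function(day0, n_bins = 256L, floor = NULL,
                         ceiling = NULL) {
  if (inherits(day0, "event_table")) day0 <- day0$intensities
  if (is.null(floor)) floor <- 0.01 * stats::median(day0)
  if (is.null(ceiling)) ceiling <- stats::quantile(day0, 0.999,
                                                   names = FALSE)
  intensity_bins(floor, ceiling, n_bins)
}

#' Parse a duration flag with hour/day suffix
#'
#' \code{"144h"} and \code{"6d"} both give 144; a bare number is taken as
#' hours.
#'
#' @param x Character or numeric duration.
#' @return Duration in hours.
#' @export
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(x)
  m <- regmatches(x, regexec("^([0-9.]+)\\s*([hd]?)$", x))[[1L]]
  if (length(m) != 3L || m[2L] == "")
    stop("cannot parse duration '", x, "' (use e.g. '144h' or '6d')",
         call. = FALSE)
  val <- as.numeric(m[2L])
  if (m[3L] == "d") val * 24 else val
}
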