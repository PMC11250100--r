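#' @keywords internal
"_PACKAGE"

STIMULUS_LEVELS <- c("background", "auditory", "visual", "tactile",
                     "experimental_noxious", "control_lance", "heel_lance")
AGE_GROUP_LEVELS <- c("premature1", "premature2", "term")

#' Construct a single-channel EEG epoch
#'
#' An epoch is one fixed-length segment of single-channel EEG cut around a
#' stimulus. The canonical epoch is 1.5 s long (-0.5 s to +1.0 s around the
#' event) sampled at 2 kHz, i.e. 3000 samples with the stimulus at sample
#' 1001. Epoch-local time runs `-event_offset ... n/fs - event_offset`
#' seconds so the stimulus sits at t = 0.
#'
#' @param samples Numeric vector of voltages in microvolts.
#' @param fs Sampling rate in Hz.
#' @param event_offset Seconds from epoch start to the stimulus (0.5 by
#'   convention; use 0 for background segments cut without an event).
#' @param stimulus One of `stimulus_levels()`.
#' @param infant_id Opaque subject identifier (grouping key for
#'   cross-validation).
#' @param age_group One of `age_group_levels()`.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs = 2000, event_offset = 0.5,
                      stimulus = "background", infant_id = "unknown",
                      age_group = "term") {
  ep <- structure(
    list(samples = as.numeric(samples), fs = fs,
         event_offset = event_offset, stimulus = stimulus,
         infant_id = as.character(infant_id), age_group = age_group),
    class = "eeg_epoch")
  validate_epoch(ep)
  ep
}

#' @rdname eeg_epoch
#' @export
stimulus_levels <- function() STIMULUS_LEVELS

#' @rdname eeg_epoch
#' @export
age_group_levels <- function() AGE_GROUP_LEVELS

#' Validate an epoch
#'
#' Checks finiteness of the samples, admissible enum values and the event
#' offset lying inside the epoch. Called by all constructors and loaders;
#' rejects rather than repairs.
#'
#' @param ep An `eeg_epoch`.
#' @return `ep`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_epoch <- function(ep) {
  stopifnot(inherits(ep, "eeg_epoch"))
  if (!is.numeric(ep$fs) || length(ep$fs) != 1L || ep$fs <= 0)
    stop("epoch: fs must be a positive scalar")
  if (length(ep$samples) < 1L)
    stop("epoch: empty sample vector")
  if (anyNA(ep$samples) || any(!is.finite(ep$samples)))
    stop("epoch: samples contain NaN/Inf or missing values")
  n <- length(ep$samples)
  if (ep$event_offset < 0 || ep$event_offset > n / ep$fs)
    stop("epoch: event_offset outside [0, n/fs]")
  if (!ep$stimulus %in% STIMULUS_LEVELS)
    stop("epoch: unknown stimulus '", ep$stimulus, "'")
  if (!ep$age_group %in% AGE_GROUP_LEVELS)
    stop("epoch: unknown age_group '", ep$age_group, "'")
  invisible(ep)
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d samples @ %g Hz (%.3f s), stimulus=%s, infant=%s, age=%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$stimulus, x$infant_id, x$age_group))
  invisible(x)
}

#' Metadata registry for a list of epochs
#'
#' @param epochs List of `eeg_epoch` objects.
#' @return A data.frame with one row per epoch: `infant_id`, `age_group`,
#'   `stimulus`, `fs`, `event_offset`, `n_samples`, in input order.
#' @export
epoch_registry <- function(epochs) {
  data.frame(
    infant_id = vapply(epochs, function(e) e$infant_id, character(1)),
    age_group = vapply(epochs, function(e) e$age_group, character(1)),
    stimulus = vapply(epochs, function(e) e$stimulus, character(1)),
    fs = vapply(epochs, function(e) e$fs, numeric(1)),
    event_offset = vapply(epochs, function(e) e$event_offset, numeric(1)),
    n_samples = vapply(epochs, function(e) length(e$samples), integer(1)),
    stringsAsFactors = FALSE)
}

#' Construct a continuous single-channel recording
#'
#' @param samples Numeric voltages in microvolts.
#' @param fs Sampling rate in Hz.
#' @param events data.frame with columns `time` (seconds, strictly inside the
#'   recording, ascending) and `stimulus` (values from `stimulus_levels()`).
#' @param channel_name Channel label, canonically `"Cz"`.
#' @param infant_id,age_group Subject metadata propagated to extracted epochs.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, events = NULL, channel_name = "Cz",
                          infant_id = "unknown", age_group = "term") {
  if (is.null(events))
    events <- data.frame(time = numeric(0), stimulus = character(0),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(events), all(c("time", "stimulus") %in% names(events)))
  dur <- length(samples) / fs
  if (nrow(events)) {
    if (any(events$time <= 0 | events$time >= dur))
      stop("recording: event times must lie strictly inside the recording")
    if (is.unsorted(events$time, strictly = FALSE))
      stop("recording: events must be sorted ascending by time")
    bad <- setdiff(unique(events$stimulus), STIMULUS_LEVELS)
    if (length(bad))
      stop("recording: unknown stimulus label(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, events = events,
         channel_name = channel_name, infant_id = as.character(infant_id),
         age_group = age_group),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %.2f s @ %g Hz, %d events, infant=%s\n",
              x$channel_name, length(x$samples) / x$fs, x$fs,
              nrow(x$events), x$infant_id))
  invisible(x)
}
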