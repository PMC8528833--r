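#' Multichannel signal container
#'
#' Bundles a channel-by-time sample matrix (microvolts) with its sampling rate
#' and channel labels. This is the in-memory form of a continuous recording,
#' e.g. one read from an EDF/EDF+ file with [read_edf()].
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz (> 0); shared by all channels.
#' @param channel_labels character vector of unique channel names, one per row.
#' @param start_time recording start offset in seconds (default 0).
#'
#' @return An object of class `signal_set`.
#' @seealso [preprocess()], [extract_epochs()]
#' @export
signal_set <- function(samples, fs, channel_labels = NULL, start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort_glue("`samples` must be a numeric channel x time matrix.")
  }
  check_number(fs, "fs", positive = TRUE)
  nch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nch) {
    abort_glue("`channel_labels` must have one entry per channel (", nch, ").")
  }
  if (anyDuplicated(channel_labels)) {
    abort_glue("channel labels must be unique.")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         start_time = start_time),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set> ", nrow(x$samples), " channel(s) x ", ncol(x$samples),
      " samples @ ", x$fs, " Hz (", round(ncol(x$samples) / x$fs, 3),
      " s)\n", sep = "")
  cat("  channels: ", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Annotated events of a recording
#'
#' @param onset event onsets in seconds from the recording start
#'   (non-negative; stored sorted ascending).
#' @param label character label per event (recycled if length 1).
#'
#' @return An object of class `event_set`: a tibble with columns `onset`,
#'   `label`, carrying the class for dispatch.
#' @export
event_set <- function(onset = numeric(), label = character()) {
  onset <- as.numeric(onset)
  if (length(onset) && any(!is.finite(onset) | onset < 0)) {
    abort_glue("event onsets must be finite and non-negative.")
  }
  if (length(label) == 0L) label <- rep("event", length(onset))
  if (length(label) == 1L) label <- rep(label, length(onset))
  if (length(label) != length(onset)) {
    abort_glue("`label` must match `onset` in length.")
  }
  ord <- order(onset)
  out <- tibble::tibble(onset = onset[ord], label = as.character(label)[ord])
  class(out) <- c("event_set", class(out))
  out
}

#' Event-locked epoch container
#'
#' Stores epochs cut around annotated events as an epoch x channel x sample
#' tensor. The event occurs at sample `t0_index` (1-based) of every epoch, so
#' the epoch time axis is `(seq_len(n_samples) - t0_index) / fs` seconds
#' relative to the event.
#'
#' @param data numeric array `[epoch, channel, sample]` (uV).
#' @param fs sampling rate (Hz).
#' @param t0_index 1-based sample index of the event within each epoch.
#' @param channel_labels character vector, one label per channel.
#'
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, t0_index = 1L, channel_labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_glue("`data` must be a 3-d array [epoch, channel, sample].")
  }
  check_number(fs, "fs", positive = TRUE)
  d <- dim(data)
  if (d[1] < 1L) abort_glue("at least one epoch is required.")
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > d[3]) {
    abort_glue("`t0_index` must lie within [1, ", d[3], "].")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[2]))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != d[2] || anyDuplicated(channel_labels)) {
    abort_glue("`channel_labels` must be ", d[2], " unique labels.")
  }
  structure(
    list(data = data, fs = fs, t0_index = t0_index,
         channel_labels = channel_labels),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> ", d[1], " epoch(s) x ", d[2], " channel(s) x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  tax <- epoch_time(x)
  cat("  time axis: [", round(tax[1], 4), ", ", round(tax[length(tax)], 4),
      "] s relative to event\n", sep = "")
  invisible(x)
}

#' Epoch time axis relative to the event
#'
#' @param epochs an [epoch_array()].
#' @return numeric vector of times (s), zero at the event sample.
#' @export
epoch_time <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  (seq_len(dim(epochs$data)[3]) - epochs$t0_index) / epochs$fs
}

n_epochs <- function(epochs) dim(epochs$data)[1]
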