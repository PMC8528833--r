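# rational approximation p/q of a resampling ratio, q bounded
rational_ratio <- function(r, max_den = 10000L) {
  best <- c(round(r), 1L)
  err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      best <- c(p, q)
      err <- e
      if (e < 1e-12) break
    }
  }
  if (err > 1e-9 * max(r, 1)) {
    abort_glue("cannot express resampling ratio ", r,
               " as a small rational p/q.")
  }
  best
}

# rational-rate polyphase resampling: zero-stuff by p, zero-phase FIR
# anti-alias/anti-image low-pass (Hamming fir1, integer group delay
# compensated exactly), decimate by q
resample_channel <- function(x, target_fs, fs) {
  pq <- rational_ratio(target_fs / fs)
  p <- pq[1]; q <- pq[2]
  if (p == q) return(x)
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, by = p, length.out = n)] <- x
  n_ord <- 2L * ceiling(10 * max(p, q) / 2)      # even -> integer delay
  h <- p * signal::fir1(n_ord, 1 / max(p, q))
  gd <- n_ord / 2L
  full <- stats::convolve(up, rev(h), type = "open")
  aligned <- full[(gd + 1):(gd + length(up))]
  aligned[seq(1, length(up), by = q)]
}

#' Standard preprocessing of a recording
#'
#' Channel selection (in the requested order), polyphase FIR resampling with
#' anti-alias filtering (phase integrity matters downstream, where coherency
#' phases carry the lead-lag information), optional per-channel mean
#' (baseline) removal and optional linear detrending.
#'
#' @param sig a [signal_set()].
#' @param channels character labels to keep, in order (`NULL` = all).
#' @param target_fs new sampling rate, Hz; must not exceed `sig$fs`.
#' @param baseline subtract the per-channel mean.
#' @param detrend remove a per-channel linear trend (implies mean removal).
#' @return A new [signal_set()].
#' @export
preprocess <- function(sig, channels = NULL, target_fs = NULL,
                       baseline = FALSE, detrend = FALSE) {
  stopifnot(inherits(sig, "signal_set"))
  samples <- sig$samples
  labs <- sig$channel_labels
  if (!is.null(channels)) {
    idx <- match(channels, labs)
    if (anyNA(idx)) {
      abort_glue("unknown channel(s): ",
                 paste(channels[is.na(idx)], collapse = ", "),
                 ". Valid labels: ", paste(labs, collapse = ", "), ".")
    }
    samples <- samples[idx, , drop = FALSE]
    labs <- labs[idx]
  }
  fs <- sig$fs
  if (!is.null(target_fs)) {
    check_number(target_fs, "target_fs", positive = TRUE)
    if (target_fs > fs) {
      abort_glue("`target_fs` (", target_fs, ") must be <= fs (", fs, ").")
    }
    if (target_fs != fs) {
      rows <- lapply(seq_len(nrow(samples)), function(r)
        resample_channel(samples[r, ], target_fs, fs))
      len <- min(lengths(rows))
      samples <- do.call(rbind, lapply(rows, function(x) x[seq_len(len)]))
      fs <- target_fs
    }
  }
  if (detrend) {
    t_ax <- seq_len(ncol(samples))
    samples <- t(apply(samples, 1, function(x)
      stats::lm.fit(cbind(1, t_ax), x)$residuals))
  } else if (baseline) {
    samples <- samples - rowMeans(samples)
  }
  signal_set(samples, fs, channel_labels = labs,
             start_time = sig$start_time)
}

#' Extract event-locked epochs
#'
#' Cuts a half-open window `[onset - pre_s, onset + post_s)` around each
#' event on the sample grid, so every epoch has exactly
#' `round((pre_s + post_s) * fs)` samples and the event falls on the sample
#' `round(pre_s * fs)` (0-based) of the epoch. Events whose window would
#' extend past either end of the recording are skipped — never zero-padded,
#' which would fabricate COI-free data — and counted in the `skipped`
#' attribute.
#'
#' @param sig a [signal_set()].
#' @param ev an [event_set()].
#' @param pre_s,post_s window extent before/after the event, s (> 0).
#' @param labels optional event labels to keep.
#' @param baseline subtract the per-epoch, per-channel mean.
#' @return An [epoch_array()]; `attr(, "skipped")` counts dropped events.
#'   Zero usable events is an error.
#' @export
extract_epochs <- function(sig, ev, pre_s, post_s, labels = NULL,
                           baseline = FALSE) {
  stopifnot(inherits(sig, "signal_set"))
  check_number(pre_s, "pre_s", positive = TRUE)
  check_number(post_s, "post_s", positive = TRUE)
  onsets <- ev$onset
  if (!is.null(labels)) onsets <- ev$onset[ev$label %in% labels]
  if (!length(onsets)) abort_glue("no events to epoch.")
  n_len <- round((pre_s + post_s) * sig$fs)
  n_pre <- round(pre_s * sig$fs)
  n <- ncol(sig$samples)
  starts <- round(onsets * sig$fs) + 1L - n_pre
  ok <- starts >= 1L & starts + n_len - 1L <= n
  skipped <- sum(!ok)
  if (!any(ok)) {
    abort_glue("all ", length(onsets),
               " event window(s) exceed the recording; nothing to epoch.")
  }
  if (skipped) {
    warning(skipped, " event(s) skipped: window exceeds the recording.",
            call. = FALSE)
  }
  starts <- starts[ok]
  nch <- nrow(sig$samples)
  data <- array(NA_real_, c(length(starts), nch, n_len))
  for (e in seq_along(starts)) {
    cols <- starts[e]:(starts[e] + n_len - 1L)
    data[e, , ] <- sig$samples[, cols, drop = FALSE]
  }
  if (baseline) {
    mu <- apply(data, c(1, 2), mean)
    data <- data - as.vector(mu)   # recycles over the sample dimension
  }
  out <- epoch_array(data, sig$fs, t0_index = n_pre + 1L,
                     channel_labels = sig$channel_labels)
  attr(out, "skipped") <- skipped
  out
}
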