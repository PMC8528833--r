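#' Simulation specification for the synthetic generators
#'
#' All generators in the package are pure functions of this spec (seed
#' included): the same spec always yields bit-identical data.
#'
#' @param fs sampling rate, Hz (default 500).
#' @param duration trial duration, s (default 2).
#' @param n_trials number of event-locked trials/epochs (default 30).
#' @param noise_sd white-noise standard deviation added to each channel
#'   (default 0.05; the oscillatory components have unit amplitude).
#' @param seed integer seed.
#' @param n_channels channels for network fixtures (default 4).
#' @param couplings for [ied_network_sim()]: list of
#'   `list(src, dst, lag_s, band_hz, amplitude)` directed couplings.
#' @param n_events number of events for network fixtures (default 40).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(fs = 500, duration = 2, n_trials = 30, noise_sd = 0.05,
                     seed = 1L, n_channels = 4L, couplings = NULL,
                     n_events = 40L) {
  check_number(fs, "fs", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  if (n_trials < 1L) abort_glue("`n_trials` must be >= 1.")
  if (noise_sd < 0) abort_glue("`noise_sd` must be >= 0.")
  structure(
    list(fs = fs, duration = duration, n_trials = as.integer(n_trials),
         noise_sd = noise_sd, seed = as.integer(seed),
         n_channels = as.integer(n_channels), couplings = couplings,
         n_events = as.integer(n_events)),
    class = "sim_spec"
  )
}

insilico_components <- function(t) {
  list(
    x = cos(2 * pi * 10 * t) * (t >= 0.5 & t < 1.1) +
      cos(2 * pi * 45 * t) * (t >= 0.2 & t < 1.4),
    y = sin(2 * pi * 10 * t) * (t >= 0.7 & t < 1.2) +
      sin(2 * pi * 45 * t) * (t >= 0.5 & t < 1.6)
  )
}

#' The in-silico demonstration pair
#'
#' Generates trials of the piecewise non-stationary test pair: channel `x`
#' carries a 10 Hz cosine gated to `[0.5, 1.1)` s and a 45 Hz cosine gated to
#' `[0.2, 1.4)` s; channel `y` carries the corresponding sines (a quarter-
#' cycle phase offset) gated to `[0.7, 1.2)` s and `[0.5, 1.6)` s. Where two
#' gates overlap the components add; outside all gates only noise remains.
#' Each trial receives fresh white noise of standard deviation
#' `spec$noise_sd` on both channels.
#'
#' @param spec a [sim_spec()]; `duration >= 1.6` s.
#' @return An [epoch_array()] with channels `c("x", "y")`, trial-start
#'   locked (`t0_index = 1`).
#' @export
insilico_pair <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$duration < 1.6) {
    abort_glue("`duration` must be >= 1.6 s to contain all gated components.")
  }
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  comp <- insilico_components(t)
  data <- array(NA_real_, c(spec$n_trials, 2L, n))
  withr::with_seed(spec$seed, {
    for (tr in seq_len(spec$n_trials)) {
      data[tr, 1, ] <- comp$x + stats::rnorm(n, 0, spec$noise_sd)
      data[tr, 2, ] <- comp$y + stats::rnorm(n, 0, spec$noise_sd)
    }
  })
  epoch_array(data, spec$fs, t0_index = 1L, channel_labels = c("x", "y"))
}

one_over_f_noise <- function(n, fs, sd_target = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- fs * c(0, seq_len(n - 1)) / n
  f <- pmin(f, fs - f)        # two-sided
  amp <- ifelse(f > 0, 1 / sqrt(pmax(f, 1)), 0)
  x <- Re(stats::fft(X * amp, inverse = TRUE) / n)
  x * sd_target / stats::sd(x)
}

damped_oscillation <- function(fs, band_hz, dur_s = 0.4, tau_s = 0.08) {
  t <- seq(0, dur_s, by = 1 / fs)
  exp(-t / tau_s) * sin(2 * pi * band_hz * t)
}

#' Event-locked multichannel recording with known directed couplings
#'
#' Produces an IED-like fixture: per-channel independent 1/f background
#' noise, plus, at each annotated event, a damped oscillatory transient on
#' the source channel that is copied to each destination channel delayed by
#' `lag_s` seconds and scaled by `amplitude`. The true directed graph is
#' returned alongside, so end-to-end pipeline tests can score recovery.
#'
#' @param spec a [sim_spec()]; `spec$couplings` is a list of
#'   `list(src, dst, lag_s, band_hz, amplitude)` with channel labels
#'   `"ch1"`, ... Default: one `ch1 -> ch2` coupling at 20 Hz, 20 ms lag.
#' @param spacing_s spacing between events, s (default 4; onsets are
#'   jittered by up to 0.2 s). The first event is placed `spacing_s` into
#'   the recording and a tail margin is kept, so windows up to
#'   `spacing_s - 0.5` s on either side of an event stay inside the record.
#' @param bg_sd background 1/f noise standard deviation (default 0.2; the
#'   transient has unit peak amplitude).
#' @param transient_dur_s,transient_tau_s duration and decay constant of the
#'   damped-oscillation transient, s.
#' @return A list with `signals` ([signal_set()]), `events` ([event_set()]),
#'   and `truth` (tibble `src`, `dst`, `lag_s`, `band_hz`, `amplitude`).
#' @export
ied_network_sim <- function(spec = sim_spec(), spacing_s = 4, bg_sd = 0.2,
                            transient_dur_s = 0.4,
                            transient_tau_s = 0.08) {
  stopifnot(inherits(spec, "sim_spec"))
  labs <- paste0("ch", seq_len(spec$n_channels))
  couplings <- spec$couplings %||% list(
    list(src = "ch1", dst = "ch2", lag_s = 0.02, band_hz = 20,
         amplitude = 0.9))
  truth <- dplyr::bind_rows(
    tibble::tibble(src = character(), dst = character(), lag_s = numeric(),
                   band_hz = numeric(), amplitude = numeric()),
    lapply(couplings, tibble::as_tibble))
  bad <- setdiff(c(truth$src, truth$dst), labs)
  if (length(bad)) {
    abort_glue("couplings reference unknown channel(s): ",
               paste(bad, collapse = ", "))
  }
  if (any(truth$lag_s >= spacing_s / 2)) {
    abort_glue("coupling lags must be shorter than half the event spacing.")
  }
  duration <- (spec$n_events + 1) * spacing_s + 2
  n <- round(duration * spec$fs)
  withr::with_seed(spec$seed, {
    samples <- t(vapply(labs, function(l)
      one_over_f_noise(n, spec$fs, bg_sd), numeric(n)))
    onsets <- spacing_s + (seq_len(spec$n_events) - 1) * spacing_s +
      stats::runif(spec$n_events, -0.2, 0.2)
    for (ev in onsets) {
      for (r in seq_len(nrow(truth))) {
        pulse <- damped_oscillation(spec$fs, truth$band_hz[r],
                                    dur_s = transient_dur_s,
                                    tau_s = transient_tau_s)
        i0 <- round(ev * spec$fs) + 1L
        src <- match(truth$src[r], labs)
        dst <- match(truth$dst[r], labs)
        idx <- i0:(i0 + length(pulse) - 1L)
        samples[src, idx] <- samples[src, idx] + pulse
        lag_n <- round(truth$lag_s[r] * spec$fs)
        samples[dst, idx + lag_n] <- samples[dst, idx + lag_n] +
          truth$amplitude[r] * pulse
      }
    }
  })
  list(signals = signal_set(samples, spec$fs, channel_labels = labs),
       events = event_set(onsets, "IED"),
       truth = truth)
}

#' Independent background noise epochs
#'
#' White-noise epochs matched in shape to analysis epochs — the fixture
#' supplier for bootstrap surrogate construction under the independence
#' null.
#'
#' @param spec a [sim_spec()] (`n_trials >= 2`).
#' @param n_channels number of channels (default 2).
#' @param n_samples samples per epoch (default `round(fs * duration)`).
#' @param channel_labels labels (default `ch1`, ...; pass the analysis
#'   labels to align with a pair).
#' @return An [epoch_array()] of unit-variance white noise.
#' @export
background_epochs <- function(spec = sim_spec(), n_channels = 2L,
                              n_samples = NULL, channel_labels = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_trials < 2L) abort_glue("`n_trials` must be >= 2.")
  n <- n_samples %||% round(spec$fs * spec$duration)
  data <- withr::with_seed(spec$seed, {
    array(stats::rnorm(spec$n_trials * n_channels * n),
          c(spec$n_trials, n_channels, n))
  })
  epoch_array(data, spec$fs, t0_index = 1L,
              channel_labels = channel_labels %||%
                paste0("ch", seq_len(n_channels)))
}
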