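#' Scale discretization for the analytic Morlet wavelet
#'
#' Builds the dyadic scale grid used throughout the coherency engine. Scales
#' are `s0 * 2^(k / voices)` for `k = 0, ..., voices * n_octaves`, with
#' `s0 = 2/fs` (two samples, the finest scale that stays below Nyquist under
#' the analytic Morlet centre-frequency convention). The number of octaves is
#' limited to `floor(log2(fs * duration_s)) - 1` by the record length.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s record duration (s); `fs * duration_s >= 4`.
#' @param n_octaves number of octaves, or `NULL`/`"auto"` for the maximum
#'   valid value.
#' @param voices voices per octave (default 12).
#' @param omega0 non-dimensional Morlet centre frequency (default 6, the
#'   smallest value satisfying the admissibility condition in practice).
#' @param smooth_scales number of adjacent scale bins averaged by the
#'   smoothing operator (default `voices`, i.e. one octave).
#'
#' @return An object of class `wavelet_spec` with elements `omega0`,
#'   `voices_per_octave`, `n_octaves`, `s0`, `scales` (s), `freqs` (Hz,
#'   equivalent Fourier frequency `omega0 / (2 * pi * scale)`), and
#'   `smooth_scales`.
#' @export
build_scales <- function(fs, duration_s, n_octaves = NULL, voices = 12L,
                         omega0 = 6, smooth_scales = voices) {
  check_number(fs, "fs", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  if (fs * duration_s < 4) abort_glue("need fs * duration_s >= 4.")
  voices <- as.integer(voices)
  if (voices < 1L) abort_glue("`voices` must be >= 1.")
  max_oct <- floor(log2(fs * duration_s)) - 1
  if (is.null(n_octaves) || identical(n_octaves, "auto")) {
    n_octaves <- max_oct
  }
  n_octaves <- as.integer(n_octaves)
  if (n_octaves < 1L || n_octaves > max_oct) {
    abort_glue("`n_octaves` must lie in [1, ", max_oct,
               "] for fs = ", fs, ", duration = ", duration_s, " s.")
  }
  s0 <- 2 / fs
  k <- 0:(voices * n_octaves)
  scales <- s0 * 2^(k / voices)
  structure(
    list(omega0 = omega0, voices_per_octave = voices, n_octaves = n_octaves,
         s0 = s0, scales = scales, freqs = omega0 / (2 * pi * scales),
         smooth_scales = as.integer(smooth_scales)),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("<wavelet_spec> analytic Morlet, omega0 = ", x$omega0, ", ",
      x$voices_per_octave, " voices/octave, ", x$n_octaves, " octaves (",
      length(x$scales), " scales)\n", sep = "")
  cat("  equivalent frequencies: ", round(min(x$freqs), 3), " - ",
      round(max(x$freqs), 2), " Hz\n", sep = "")
  invisible(x)
}

# Frequency-domain daughter wavelets, npad x nscale. Analytic Morlet:
# pi^(-1/4) * exp(-(scale*omega - omega0)^2 / 2) for omega > 0, zero otherwise,
# with the L2 normalization sqrt(2*pi*scale*fs).
morlet_daughters <- function(spec, npad, fs) {
  k <- 0:(npad - 1)
  omega <- 2 * pi * fs * ifelse(k <= npad / 2, k, k - npad) / npad
  pos <- omega > 0
  D <- matrix(0, nrow = npad, ncol = length(spec$scales))
  for (s in seq_along(spec$scales)) {
    sc <- spec$scales[s]
    D[pos, s] <- sqrt(2 * pi * sc * fs) * pi^(-1 / 4) *
      exp(-0.5 * (sc * omega[pos] - spec$omega0)^2)
  }
  D
}

#' Continuous wavelet transform with the analytic Morlet wavelet
#'
#' FFT-based CWT on the scale grid of a [build_scales()] spec. Coefficients
#' are linear in the input; the record is zero-padded to the next power of two
#' at least twice its length to suppress wrap-around.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param spec a `wavelet_spec`; default `build_scales(fs, length(x)/fs)`.
#'
#' @return An object of class `cwt_result`: complex `coeffs` (scale x time),
#'   `scales`, `freqs`, `fs`, `spec`, and `coi_boundary` (per-time maximum
#'   valid scale in seconds, see [coi_mask()]).
#' @export
cwt_morlet <- function(x, fs, spec = NULL) {
  if (anyNA(x) || any(!is.finite(x))) abort_glue("input contains NaN/Inf.")
  n <- length(x)
  if (n < 2L) abort_glue("need at least 2 samples.")
  if (is.null(spec)) spec <- build_scales(fs, n / fs)
  npad <- next_pow2(2L * n)
  D <- morlet_daughters(spec, npad, fs)
  xf <- stats::fft(c(x, rep(0, npad - n)))
  W <- stats::mvfft(D * xf, inverse = TRUE) / npad
  coeffs <- t(W[seq_len(n), , drop = FALSE])
  t_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) / fs
  structure(
    list(coeffs = coeffs, scales = spec$scales, freqs = spec$freqs, fs = fs,
         spec = spec, coi_boundary = t_edge / sqrt(2)),
    class = "cwt_result"
  )
}

# Cache for smoothing kernels/normalizers, keyed by geometry.
.smooth_cache <- new.env(parent = emptyenv())

smooth_kernels <- function(spec, ntime, fs) {
  key <- paste(length(spec$scales), ntime, fs, spec$scales[1],
               spec$scales[length(spec$scales)], sep = "|")
  hit <- .smooth_cache[[key]]
  if (!is.null(hit)) return(hit)
  npad <- next_pow2(2L * ntime)
  k <- 0:(npad - 1)
  om <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / npad # rad per sample
  K <- vapply(spec$scales, function(sc) exp(-0.5 * (sc * fs * om)^2),
              numeric(npad))
  ones <- rbind(matrix(1, ntime, length(spec$scales)),
                matrix(0, npad - ntime, length(spec$scales)))
  Fn <- stats::mvfft(ones)
  norm <- Re(stats::mvfft(Fn * K, inverse = TRUE) / npad)[seq_len(ntime), ,
                                                          drop = FALSE]
  out <- list(K = K, norm = norm, npad = npad)
  .smooth_cache[[key]] <- out
  out
}

#' Time-frequency smoothing operator
#'
#' The smoothing operator applied inside the ensemble coherency estimator:
#' convolution in time with a unit-sum Gaussian whose standard deviation
#' equals the scale (in seconds), followed by a unit-sum boxcar over
#' `spec$smooth_scales` adjacent scale bins (truncated and renormalized at the
#' grid edges). Without this local averaging, single-epoch coherency is
#' identically 1.
#'
#' @param field real or complex matrix, scales in rows (matching
#'   `spec$scales`), time in columns.
#' @param spec a `wavelet_spec`.
#' @param fs sampling rate (Hz).
#'
#' @return Smoothed matrix of the same shape and mode. Non-negative real
#'   input yields non-negative output.
#' @export
smooth_tf <- function(field, spec, fs) {
  if (!is.matrix(field)) abort_glue("`field` must be a scale x time matrix.")
  if (nrow(field) != length(spec$scales)) {
    abort_glue("`field` must have one row per scale (", length(spec$scales),
               ").")
  }
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field)))) {
    abort_glue("`field` must be finite.")
  }
  ntime <- ncol(field)
  ker <- smooth_kernels(spec, ntime, fs)
  nonneg <- !is.complex(field) && all(field >= 0)
  pad <- rbind(t(field), matrix(0, ker$npad - ntime, nrow(field)))
  Fp <- stats::mvfft(pad)
  sm <- stats::mvfft(Fp * ker$K, inverse = TRUE) / ker$npad
  sm <- sm[seq_len(ntime), , drop = FALSE] / ker$norm
  if (!is.complex(field)) sm <- Re(sm)
  out <- t(sm)
  # boxcar over adjacent scales, truncated + renormalized
  m <- spec$smooth_scales
  if (m > 1L) {
    ns <- nrow(out)
    h_lo <- (m - 1L) %/% 2L
    h_hi <- m - 1L - h_lo
    cs <- apply(out, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(out))
    lo <- pmax(seq_len(ns) - h_lo, 1L)
    hi <- pmin(seq_len(ns) + h_hi, ns)
    upper <- cs[hi, , drop = FALSE]
    lower <- rbind(if (is.complex(out)) complex(real = 0) + numeric(ncol(out))
                   else numeric(ncol(out)),
                   cs)[lo, , drop = FALSE]
    out <- (upper - lower) / (hi - lo + 1L)
  }
  if (nonneg) out <- pmax(Re(out), 0)
  out
}

#' Cone-of-influence mask
#'
#' Marks the time-scale region unaffected by edge effects. At scale `sigma`
#' the wavelet envelope's e-folding time is `sqrt(2) * sigma` seconds — the
#' operational half wavelet length — so points closer than that to either
#' record edge are invalid.
#'
#' @param spec a `wavelet_spec`.
#' @param n_samples record length in samples (>= 2).
#' @param fs sampling rate (Hz).
#'
#' @return Logical scale x time matrix, `TRUE` inside the valid region. The
#'   mask is symmetric about the record midpoint and the invalid margin widens
#'   monotonically with scale.
#' @export
coi_mask <- function(spec, n_samples, fs) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) abort_glue("`n_samples` must be >= 2.")
  margin <- round(sqrt(2) * spec$scales * fs)
  idx <- seq_len(n_samples)
  mask <- vapply(margin,
                 function(m) (idx - 1L) >= m & (n_samples - idx) >= m,
                 logical(n_samples))
  t(mask)
}
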