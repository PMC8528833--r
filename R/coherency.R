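resolve_channel <- function(epochs, ch) {
  labs <- epochs$channel_labels
  if (is.character(ch)) {
    idx <- match(ch, labs)
    if (is.na(idx)) {
      abort_glue("unknown channel '", ch, "'. Valid channels: ",
                 paste(labs, collapse = ", "), ".")
    }
    return(idx)
  }
  ch <- as.integer(ch)
  if (ch < 1L || ch > length(labs)) abort_glue("channel index out of range.")
  ch
}

new_coherency_map <- function(rhat, valid, epochs, spec, pair_idx) {
  n <- dim(epochs$data)[3]
  structure(
    list(rhat = rhat, valid = valid, n_epochs = n_epochs(epochs),
         scales = spec$scales, freqs = spec$freqs, fs = epochs$fs,
         time = epoch_time(epochs), coi = coi_mask(spec, n, epochs$fs),
         pair = epochs$channel_labels[pair_idx], spec = spec),
    class = "coherency_map"
  )
}

# Accumulate ensemble numerators/denominators for a set of channels and the
# requested ordered pairs, computing each epoch's CWTs once.
ewtc_accumulate <- function(epochs, chans, pairs, spec) {
  d <- dim(epochs$data)
  num <- lapply(pairs, function(p) matrix(0 + 0i, length(spec$scales), d[3]))
  den <- lapply(chans, function(c) matrix(0, length(spec$scales), d[3]))
  names(den) <- as.character(chans)
  for (e in seq_len(d[1])) {
    W <- lapply(chans, function(c)
      cwt_morlet(epochs$data[e, c, ], epochs$fs, spec)$coeffs)
    names(W) <- as.character(chans)
    for (c in seq_along(chans)) {
      den[[c]] <- den[[c]] +
        smooth_tf(Mod(W[[c]])^2, spec, epochs$fs)
    }
    for (p in seq_along(pairs)) {
      wi <- W[[as.character(pairs[[p]][1])]]
      wj <- W[[as.character(pairs[[p]][2])]]
      num[[p]] <- num[[p]] + smooth_tf(wi * Conj(wj), spec, epochs$fs)
    }
  }
  list(num = num, den = den)
}

assemble_rhat <- function(num, den_i, den_j) {
  denom <- sqrt(den_i * den_j)
  valid <- is.finite(denom) & denom > 0
  rhat <- matrix(0 + 0i, nrow(num), ncol(num))
  rhat[valid] <- num[valid] / denom[valid]
  list(rhat = rhat, valid = valid)
}

#' Ensemble wavelet-transform coherency for one channel pair
#'
#' Estimates the complex coherency `R(scale, time)` between channels `i` and
#' `j` from `N` event-locked epochs: per epoch, the cross-wavelet spectrum and
#' both auto-spectra are smoothed locally in time and scale ([smooth_tf()]);
#' the smoothed fields are summed over epochs and the coherency is their
#' normalized ratio, so `|R| <= 1` by the Cauchy-Schwarz inequality. The
#' magnitude is the wavelet-transform coherency (WTC); the imaginary part
#' (IWTC, [iwtc_map()]) discards zero-lag coupling such as volume conduction.
#'
#' @param epochs an [epoch_array()] (`N >= 1`).
#' @param i,j channel labels or indices; must differ.
#' @param spec a `wavelet_spec`; default [build_scales()] for the epoch
#'   length.
#'
#' @return An object of class `coherency_map` with complex `rhat`
#'   (scale x time), `valid` (zero-denominator guard, such bins are set to 0),
#'   `coi` (logical cone-of-influence mask), `time` (s relative to the
#'   event), `freqs`, `scales`, `pair`, `n_epochs`.
#' @export
ensemble_wtc <- function(epochs, i, j, spec = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  ci <- resolve_channel(epochs, i)
  cj <- resolve_channel(epochs, j)
  if (ci == cj) abort_glue("`i` and `j` must be different channels.")
  d <- dim(epochs$data)
  if (is.null(spec)) spec <- build_scales(epochs$fs, d[3] / epochs$fs)
  acc <- ewtc_accumulate(epochs, c(ci, cj), list(c(ci, cj)), spec)
  parts <- assemble_rhat(acc$num[[1]], acc$den[[1]], acc$den[[2]])
  new_coherency_map(parts$rhat, parts$valid, epochs, spec, c(ci, cj))
}

#' @export
print.coherency_map <- function(x, ...) {
  cat("<coherency_map> pair ", x$pair[1], " ~ ", x$pair[2], ", ",
      length(x$scales), " scales x ", length(x$time), " times, N = ",
      x$n_epochs, " epochs\n", sep = "")
  inside <- x$coi & x$valid
  if (any(inside)) {
    cat("  peak WTC inside COI: ", round(max(Mod(x$rhat)[inside]), 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Wavelet-transform coherency magnitude
#'
#' @param map a `coherency_map`.
#' @return Real scale x time matrix `|R|`, clamped to `[0, 1]`.
#' @export
wtc_map <- function(map) {
  stopifnot(inherits(map, "coherency_map"))
  pmin(Mod(map$rhat), 1)
}

#' Imaginary part of the wavelet-transform coherency
#'
#' Zero-lag (in- or anti-phase) coupling — the signature of a common source
#' seen by both electrodes — contributes only to the real part of the
#' coherency, so the imaginary part retains only lagged, physiologically
#' interpretable interaction.
#'
#' @param map a `coherency_map`.
#' @return Real scale x time matrix `Im(R)` in `[-1, 1]`.
#' @export
iwtc_map <- function(map) {
  stopifnot(inherits(map, "coherency_map"))
  Im(map$rhat)
}

#' Phase and lead-lag direction fields
#'
#' @param map a `coherency_map` for ordered pair `(i, j)`.
#' @return A list with `phase` (`arg(R)` in `(-pi, pi]`), `lead` (integer
#'   codes: `+1` = `j` leads `i`, `-1` = `i` leads `j`, `0` = no lag
#'   information, from the sign of `Im(R)`), and `inphase` (`+1` in-phase,
#'   `-1` anti-phase, from the sign of `Re(R)`).
#' @export
phase_field <- function(map) {
  stopifnot(inherits(map, "coherency_map"))
  list(phase = Arg(map$rhat),
       lead = sign(Im(map$rhat)),
       inphase = sign(Re(map$rhat)),
       pair = map$pair)
}

#' Dominant lead-lag direction within a time-frequency window
#'
#' Averages the signed imaginary coherency over the window (inside the COI)
#' and decodes which channel leads. Positive mean `Im(R)` for pair `(i, j)`
#' decodes as "`j` leads `i`", i.e. information flows `j -> i`.
#'
#' @param map a `coherency_map`.
#' @param t_window,f_window numeric `[lo, hi]` windows (s, Hz), or `NULL` for
#'   the full axis.
#' @return A list with `label` (e.g. `"y leads x"`), `score` (mean signed
#'   `Im(R)`), and `mean_phase` (circular mean of the phase over the window).
#' @export
dominant_direction <- function(map, t_window = NULL, f_window = NULL) {
  sel <- window_bins(map, t_window, f_window) & map$coi & map$valid
  if (!any(sel)) abort_glue("window contains no valid bins.")
  score <- mean(Im(map$rhat)[sel])
  z <- mean(map$rhat[sel] / pmax(Mod(map$rhat[sel]), .Machine$double.eps))
  label <- if (score > 0) {
    paste(map$pair[2], "leads", map$pair[1])
  } else if (score < 0) {
    paste(map$pair[1], "leads", map$pair[2])
  } else "no lag"
  list(label = label, score = score, mean_phase = Arg(z))
}

window_bins <- function(map, t_window = NULL, f_window = NULL) {
  tsel <- if (is.null(t_window)) rep(TRUE, length(map$time)) else {
    map$time >= t_window[1] & map$time <= t_window[2]
  }
  fsel <- if (is.null(f_window)) rep(TRUE, length(map$freqs)) else {
    map$freqs >= f_window[1] & map$freqs <= f_window[2]
  }
  if (!any(tsel) || !any(fsel)) {
    abort_glue("time/frequency window does not intersect the map axes.")
  }
  outer(fsel, tsel)
}

#' Ensemble coherency for every channel pair
#'
#' Computes [ensemble_wtc()] maps for all unordered channel pairs, reusing
#' each epoch's per-channel wavelet transforms across pairs. Pairs are
#' ordered lexicographically by channel label; map `(a, b)` with `a < b` is
#' stored, and the reverse pair is its complex conjugate (Hermitian
#' symmetry).
#'
#' @param epochs an [epoch_array()] with >= 2 channels.
#' @param spec a `wavelet_spec`, or `NULL` for the default grid.
#' @param memory_cap_bytes guard on the estimated accumulator size; exceeding
#'   it raises an error advising channel or scale subsetting.
#'
#' @return An object of class `coherency_set`: named list `maps`
#'   (`"a~b"` keys), `labels`, `spec`, plus shared `time`/`freqs` axes.
#' @export
all_pairs_maps <- function(epochs, spec = NULL, memory_cap_bytes = 4e9) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  if (d[2] < 2L) abort_glue("need at least 2 channels.")
  if (is.null(spec)) spec <- build_scales(epochs$fs, d[3] / epochs$fs)
  labs <- epochs$channel_labels
  ord <- order(labs)
  pairs_idx <- utils::combn(ord, 2, simplify = FALSE)
  est <- (length(pairs_idx) + d[2] + d[2]) * length(spec$scales) * d[3] * 16
  if (est > memory_cap_bytes) {
    abort_glue("estimated working set ", format(est, big.mark = ","),
               " bytes exceeds the cap; subset channels or reduce scales.")
  }
  acc <- ewtc_accumulate(epochs, seq_len(d[2]), pairs_idx, spec)
  maps <- vector("list", length(pairs_idx))
  keys <- character(length(pairs_idx))
  for (p in seq_along(pairs_idx)) {
    ij <- pairs_idx[[p]]
    parts <- assemble_rhat(acc$num[[p]], acc$den[[ij[1]]], acc$den[[ij[2]]])
    maps[[p]] <- new_coherency_map(parts$rhat, parts$valid, epochs, spec, ij)
    keys[p] <- pair_key(labs[ij[1]], labs[ij[2]])
  }
  names(maps) <- keys
  structure(
    list(maps = maps, labels = sort(labs), spec = spec,
         time = epoch_time(epochs), freqs = spec$freqs, fs = epochs$fs),
    class = "coherency_set"
  )
}

#' @export
print.coherency_set <- function(x, ...) {
  cat("<coherency_set> ", length(x$maps), " pair map(s) over ",
      length(x$labels), " channels\n", sep = "")
  invisible(x)
}

#' Coherency map of the reversed pair
#'
#' @param map a `coherency_map` for pair `(i, j)`.
#' @return The map for `(j, i)`: `R_ji = Conj(R_ij)`.
#' @export
conj_map <- function(map) {
  stopifnot(inherits(map, "coherency_map"))
  map$rhat <- Conj(map$rhat)
  map$pair <- rev(map$pair)
  map
}
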