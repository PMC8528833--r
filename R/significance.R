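measure_field <- function(rhat, measure) {
  switch(measure,
         wtc = pmin(Mod(rhat), 1),
         iwtc_abs = abs(Im(rhat)),
         abort_glue("unknown measure '", measure,
                    "'; use \"wtc\" or \"iwtc_abs\"."))
}

#' Bootstrap surrogate distribution of coherency under independence
#'
#' Builds the null distribution of a coherency measure from user-selected
#' background epochs. Each of the `B` resamples draws `N_match` epochs with
#' replacement, independently for the two channels of the pair — the
#' cross-channel pairing is broken, which enforces the null hypothesis of
#' independence without any model of the signal spectrum — and computes the
#' ensemble coherency measure on the resampled set.
#'
#' Memory note: the full `B x scale x time` sample array is kept, so size the
#' background record and `B` accordingly.
#'
#' @param background an [epoch_array()] with >= 2 epochs (the user-selected
#'   background activity embodying the null).
#' @param N_match number of epochs per resample; match the analysis `N`.
#' @param B number of bootstrap resamples (>= 1).
#' @param spec a `wavelet_spec`; must match the spec used for the analysis
#'   maps. `NULL` uses the default grid for the background epoch length.
#' @param seed integer seed; the distribution is deterministic given it.
#' @param channels length-2 channel labels/indices of the pair (default the
#'   first two channels).
#' @param measure `"iwtc_abs"` (default, matching IWTC-based networks) or
#'   `"wtc"`.
#' @param pooling `"bin"` (per time-frequency bin thresholds) or `"scale"`
#'   (samples pooled over time within each scale; useful for small `B`).
#'
#' @return An object of class `surrogate_dist`.
#' @export
surrogate_distribution <- function(background, N_match, B, spec = NULL,
                                   seed = 1L, channels = c(1L, 2L),
                                   measure = c("iwtc_abs", "wtc"),
                                   pooling = c("bin", "scale")) {
  stopifnot(inherits(background, "epoch_array"))
  measure <- match.arg(measure)
  pooling <- match.arg(pooling)
  B <- as.integer(B)
  N_match <- as.integer(N_match)
  if (B < 1L) abort_glue("`B` must be >= 1.")
  if (N_match < 1L) abort_glue("`N_match` must be >= 1.")
  d <- dim(background$data)
  if (d[1] < 2L) abort_glue("background must contain >= 2 epochs.")
  ci <- resolve_channel(background, channels[[1]])
  cj <- resolve_channel(background, channels[[2]])
  if (is.null(spec)) spec <- build_scales(background$fs, d[3] / background$fs)
  ns <- length(spec$scales)
  # per-epoch CWTs and smoothed auto-spectra, computed once
  Wi <- vector("list", d[1]); Wj <- vector("list", d[1])
  Pi <- vector("list", d[1]); Pj <- vector("list", d[1])
  for (e in seq_len(d[1])) {
    Wi[[e]] <- cwt_morlet(background$data[e, ci, ], background$fs, spec)$coeffs
    Wj[[e]] <- cwt_morlet(background$data[e, cj, ], background$fs, spec)$coeffs
    Pi[[e]] <- smooth_tf(Mod(Wi[[e]])^2, spec, background$fs)
    Pj[[e]] <- smooth_tf(Mod(Wj[[e]])^2, spec, background$fs)
  }
  samples <- array(NA_real_, c(B, ns, d[3]))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      ai <- sample.int(d[1], N_match, replace = TRUE)
      aj <- sample.int(d[1], N_match, replace = TRUE)
      num <- matrix(0 + 0i, ns, d[3])
      for (k in seq_len(N_match)) {
        num <- num + smooth_tf(Wi[[ai[k]]] * Conj(Wj[[aj[k]]]), spec,
                               background$fs)
      }
      den_i <- Reduce(`+`, Pi[ai])
      den_j <- Reduce(`+`, Pj[aj])
      parts <- assemble_rhat(num, den_i, den_j)
      samples[b, , ] <- measure_field(parts$rhat, measure)
    }
  })
  structure(
    list(samples = samples, B = B, N_match = N_match, measure = measure,
         pooling = pooling, seed = as.integer(seed), scales = spec$scales,
         freqs = spec$freqs, fs = background$fs, ntime = d[3], spec = spec,
         channels = background$channel_labels[c(ci, cj)]),
    class = "surrogate_dist"
  )
}

#' @export
print.surrogate_dist <- function(x, ...) {
  cat("<surrogate_dist> B = ", x$B, " resamples of N = ", x$N_match,
      " epochs, measure = ", x$measure, ", pooling = ", x$pooling, "\n",
      sep = "")
  invisible(x)
}

#' Quantile threshold field of a surrogate distribution
#'
#' @param dist a `surrogate_dist`.
#' @param q quantile level in `(0, 1]`.
#' @return scale x time matrix of thresholds (constant across time under
#'   `"scale"` pooling).
#' @export
surrogate_threshold <- function(dist, q = 0.95) {
  stopifnot(inherits(dist, "surrogate_dist"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    abort_glue("`q` must lie in (0, 1].")
  }
  ns <- length(dist$scales)
  if (dist$pooling == "scale") {
    thr_s <- vapply(seq_len(ns), function(s)
      stats::quantile(dist$samples[, s, ], q, names = FALSE), numeric(1))
    matrix(thr_s, ns, dist$ntime)
  } else {
    apply(dist$samples, c(2, 3), stats::quantile, probs = q, names = FALSE)
  }
}

#' Significance mask from bootstrap surrogate quantiles
#'
#' Flags time-frequency bins whose coherency measure exceeds the `q`-quantile
#' of the surrogate distribution (pointwise by default), intersected with the
#' cone of influence and the map's validity mask — flags are never raised
#' outside the COI.
#'
#' @param map a `coherency_map`.
#' @param dist a `surrogate_dist` computed on compatible axes (same scales,
#'   record length and sampling rate — a background shorter than the analysis
#'   epochs is an error).
#' @param q quantile level (default 0.95, the conventional 95% band).
#'
#' @return An object of class `significance_mask`: logical `flags`
#'   (scale x time), `q`, `B`, `measure`.
#' @export
significance_mask <- function(map, dist, q = 0.95) {
  stopifnot(inherits(map, "coherency_map"), inherits(dist, "surrogate_dist"))
  if (length(map$scales) != length(dist$scales) ||
      max(abs(map$scales - dist$scales)) > 1e-12 ||
      ncol(map$rhat) != dist$ntime || !isTRUE(all.equal(map$fs, dist$fs))) {
    abort_glue("map and surrogate axes do not match ",
               "(scales/record length/sampling rate).")
  }
  thr <- surrogate_threshold(dist, q)
  flags <- measure_field(map$rhat, dist$measure) > thr
  flags <- flags & map$coi & map$valid
  structure(
    list(flags = flags, q = q, B = dist$B, measure = dist$measure,
         pair = map$pair),
    class = "significance_mask"
  )
}

#' @export
print.significance_mask <- function(x, ...) {
  cat("<significance_mask> q = ", x$q, ", B = ", x$B, ", measure = ",
      x$measure, "; ", sum(x$flags), " flagged bin(s)\n", sep = "")
  invisible(x)
}

#' Significance masks for every map of a coherency set
#'
#' Applies [significance_mask()] to each pair map of a [all_pairs_maps()]
#' result against a single surrogate distribution.
#'
#' @param set a `coherency_set`.
#' @param dist a `surrogate_dist`.
#' @param q quantile level.
#' @return Named list of `significance_mask` objects (class
#'   `significance_mask_set`), keyed like `set$maps`.
#' @export
significance_masks <- function(set, dist, q = 0.95) {
  stopifnot(inherits(set, "coherency_set"))
  out <- lapply(set$maps, significance_mask, dist = dist, q = q)
  class(out) <- "significance_mask_set"
  out
}
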