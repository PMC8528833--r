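next_pow2 <- function(n) {
  2L^ceiling(log2(max(n, 2L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_glue <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_glue("`", name, "` must be a single finite number.")
  }
  if (positive && x <= 0) abort_glue("`", name, "` must be > 0.")
  invisible(x)
}

# Deterministic unordered-pair labelling, lexicographic by channel label.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}
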