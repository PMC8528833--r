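# Minimal EDF/EDF+ support: 16-bit records, one annotation signal holding
# TAL-encoded events. Field widths follow the EDF specification; all header
# fields are space-padded ASCII.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_field(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Encodes each channel as 16-bit integers with per-channel physical scaling
#' (full digital range, so the quantization step is
#' `(max - min) / 65535` per channel) and stores events in an
#' `EDF Annotations` signal as standard TALs. Records are 1 s long when the
#' sample count allows, otherwise the whole recording is written as a single
#' record.
#'
#' @param sig a [signal_set()].
#' @param path output file path.
#' @param events optional [event_set()].
#' @param record_s preferred data-record duration, s.
#' @return `path`, invisibly.
#' @export
write_edf <- function(sig, path, events = NULL, record_s = 1) {
  stopifnot(inherits(sig, "signal_set"))
  n <- ncol(sig$samples)
  nch <- nrow(sig$samples)
  spr <- round(sig$fs * record_s)
  if (spr != sig$fs * record_s || n %% spr != 0L) {
    spr <- n
    record_s <- n / sig$fs
  }
  n_rec <- n %/% spr
  has_ann <- !is.null(events)
  ns <- nch + as.integer(has_ann)

  pmin_ <- apply(sig$samples, 1, min)
  pmax_ <- apply(sig$samples, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1

  ann_recs <- NULL
  ann_spr <- 0L
  if (has_ann) {
    rec_of <- pmin(floor(events$onset / record_s) + 1L, n_rec)
    # each TAL is NUL-terminated (raw level: R strings cannot hold NUL);
    # the first TAL of a record is its timestamp
    ann_recs <- lapply(seq_len(n_rec), function(r) {
      tal <- c(charToRaw(sprintf("+%s\x14\x14",
                                 format((r - 1) * record_s, trim = TRUE,
                                        scientific = FALSE))), as.raw(0))
      for (k in which(rec_of == r)) {
        tal <- c(tal,
                 charToRaw(sprintf("+%s\x14%s\x14",
                                   format(events$onset[k], trim = TRUE,
                                          scientific = FALSE),
                                   events$label[k])), as.raw(0))
      }
      tal
    })
    ann_bytes <- max(lengths(ann_recs)) + 2L
    ann_spr <- as.integer(ceiling(ann_bytes / 2))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_field("0", 8))
  wr(edf_field("X X X X", 80))
  wr(edf_field("Startdate 01-JAN-2000 X X X", 80))
  wr(edf_field("01.01.00", 8))
  wr(edf_field("00.00.00", 8))
  wr(edf_num(256L * (1L + ns), 8))
  wr(edf_field(if (has_ann) "EDF+C" else "", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(record_s, 8))
  wr(edf_num(ns, 4))

  labels <- c(sig$channel_labels, if (has_ann) "EDF Annotations")
  for (l in labels) wr(edf_field(l, 16))
  for (l in labels) wr(edf_field("", 80))
  for (k in seq_len(ns)) wr(edf_field(if (k <= nch) "uV" else "", 8))
  for (k in seq_len(ns)) wr(edf_num(if (k <= nch) signif(pmin_[k], 7)
                                    else -1, 8))
  for (k in seq_len(ns)) wr(edf_num(if (k <= nch) signif(pmax_[k], 7)
                                    else 1, 8))
  for (k in seq_len(ns)) wr(edf_num(-32768L, 8))
  for (k in seq_len(ns)) wr(edf_num(32767L, 8))
  for (l in labels) wr(edf_field("", 80))
  for (k in seq_len(ns)) wr(edf_num(if (k <= nch) spr else ann_spr, 8))
  for (l in labels) wr(edf_field("", 32))

  # re-read the written physical bounds so encoding matches the header text
  hdr_pmin <- as.numeric(signif(pmin_, 7))
  hdr_pmax <- as.numeric(signif(pmax_, 7))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (c in seq_len(nch)) {
      x <- sig$samples[c, cols]
      dig <- round((x - hdr_pmin[c]) / (hdr_pmax[c] - hdr_pmin[c]) * 65535 -
                     32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
    if (has_ann) {
      raw_tal <- ann_recs[[r]]
      pad <- raw(2L * ann_spr - length(raw_tal))
      writeBin(c(raw_tal, pad), con)
    }
  }
  invisible(path)
}

parse_tals <- function(bytes) {
  onsets <- numeric(0)
  labels <- character(0)
  # split the raw stream on NUL bytes into TALs: onset[\x15dur]\x14label\x14
  grp <- cumsum(bytes == as.raw(0))
  keep <- bytes != as.raw(0)
  tals <- vapply(split(bytes[keep], grp[keep]), rawToChar, character(1))
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    stamp <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1]
    onset <- suppressWarnings(as.numeric(stamp))
    if (is.na(onset)) next
    anns <- parts[-1]
    anns <- anns[nzchar(anns)]
    for (a in anns) {
      onsets <- c(onsets, onset)
      labels <- c(labels, a)
    }
  }
  list(onset = onsets, label = labels)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, applies each signal's physical scaling, and maps
#' EDF+ annotation TALs to an [event_set()]. Ordinary signals must share one
#' sampling rate unless `target_fs` is given, in which case each channel is
#' resampled to it.
#'
#' @param path path to an EDF or EDF+ file.
#' @param target_fs optional common sampling rate (Hz) to resample
#'   heterogeneous-rate channels to.
#' @return A list with `signals` ([signal_set()]) and `events`
#'   ([event_set()], empty when the file has no annotations).
#' @export
read_edf <- function(path, target_fs = NULL) {
  if (!file.exists(path)) abort_glue("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  rd_num <- function(w) {
    v <- suppressWarnings(as.numeric(trimws(rd(w))))
    if (is.na(v)) abort_glue("corrupt EDF header in '", path, "'.")
    v
  }
  version <- trimws(rd(8))
  if (version != "0") abort_glue("not an EDF file (version field '",
                                 version, "').")
  rd(80); rd(80); rd(8); rd(8)
  rd_num(8)                      # header bytes
  rd(44)
  n_rec <- rd_num(8)
  record_s <- rd_num(8)
  ns <- as.integer(rd_num(4))
  if (ns < 1L || n_rec < 1L) abort_glue("corrupt EDF header in '", path, "'.")

  labels <- trimws(vapply(seq_len(ns), function(k) rd(16), character(1)))
  for (k in seq_len(ns)) rd(80)
  for (k in seq_len(ns)) rd(8)          # physical dimension
  pmin_ <- vapply(seq_len(ns), function(k) rd_num(8), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(k) rd_num(8), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(k) rd_num(8), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(k) rd_num(8), numeric(1))
  for (k in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(k) as.integer(rd_num(8)), integer(1))
  for (k in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  chunks <- lapply(seq_len(ns), function(k) vector("list", n_rec))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      if (is_ann[k]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[k]))
      } else {
        chunks[[k]][[r]] <- readBin(con, "integer", spr[k], size = 2,
                                    signed = TRUE, endian = "little")
      }
    }
  }

  rates <- spr[sig_idx] / record_s
  resample_needed <- length(unique(rates)) > 1L
  if (resample_needed && is.null(target_fs)) {
    abort_glue("channels have heterogeneous sampling rates (",
               paste(unique(rates), collapse = ", "),
               " Hz); pass `target_fs` to resample.")
  }
  fs_out <- target_fs %||% rates[1]
  rows <- lapply(seq_along(sig_idx), function(i) {
    k <- sig_idx[i]
    dig <- unlist(chunks[[k]], use.names = FALSE)
    phys <- (dig - dmin_[k]) * (pmax_[k] - pmin_[k]) / (dmax_[k] - dmin_[k]) +
      pmin_[k]
    if (!is.null(target_fs) && rates[i] != fs_out) {
      phys <- resample_channel(phys, fs_out, rates[i])
    }
    phys
  })
  len <- min(lengths(rows))
  samples <- do.call(rbind, lapply(rows, function(x) x[seq_len(len)]))
  sig <- signal_set(samples, fs_out, channel_labels = labels[sig_idx])
  ev <- if (length(ann_raw)) {
    tal <- parse_tals(ann_raw)
    event_set(tal$onset, if (length(tal$label)) tal$label else character())
  } else {
    event_set()
  }
  list(signals = sig, events = ev)
}
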