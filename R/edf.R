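# Minimal EDF/EDF+ support: one EEG signal plus an "EDF Annotations"
# track carrying stimulus events as TALs (time-stamped annotation lists).
# 16-bit samples, little-endian, record-major layout per the EDF spec.
# Scope is deliberately narrow: single channel in, single channel out.

edf_pad <- function(x, width) {
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF+ file
#'
#' Stores the single EEG channel as a 16-bit EDF+C file with the events
#' encoded as annotations whose text is the stimulus label. The physical
#' dimension is written as `uV`; amplitude resolution is the physical
#' range divided by 65535 (the format's quantisation).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param record_s Data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  spr <- round(fs * record_s)
  if (abs(spr - fs * record_s) > 1e-9)
    stop("write_edf: fs * record_s must be an integer sample count")
  n_rec <- ceiling(length(rec$samples) / spr)
  x <- c(rec$samples, rep(0, n_rec * spr - length(rec$samples)))

  rng <- max(abs(x), 1e-6)
  phys_min <- -rng; phys_max <- rng
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- as.integer(round((x - phys_min) / scale) + dig_min)
  dig <- pmin(pmax(dig, dig_min), dig_max)

  ann_bytes <- 128L                      # per record; 64 two-byte "samples"
  ann_spr <- ann_bytes %/% 2L
  tal <- function(onset, text = NULL) {
    head <- sprintf("+%.4f", onset)
    body <- if (is.null(text)) "\x14\x14" else paste0("\x14", text, "\x14")
    c(charToRaw(paste0(head, body)), as.raw(0L))   # NUL-terminated TAL
  }
  ann_records <- lapply(seq_len(n_rec), function(r) {
    onset <- (r - 1L) * record_s
    b <- tal(onset)                      # mandatory record-keeping TAL
    ev <- rec$events[rec$events$time >= onset &
                     rec$events$time < onset + record_s, , drop = FALSE]
    for (k in seq_len(nrow(ev)))
      b <- c(b, tal(ev$time[k], ev$stimulus[k]))
    if (length(b) > ann_bytes)
      stop("write_edf: too many events in one data record")
    c(b, raw(ann_bytes - length(b)))
  })

  ns <- 2L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(edf_pad(s, w)), con)
  wr("0", 8L)
  wr(sprintf("infant %s", rec$infant_id), 80L)
  wr(sprintf("Startdate 01-JAN-2000 %s channel", rec$channel_name), 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(as.character(header_bytes), 8L)
  wr("EDF+C", 44L)
  wr(as.character(n_rec), 8L)
  wr(sprintf("%g", record_s), 8L)
  wr(as.character(ns), 4L)
  labels <- c(sprintf("EEG %s", rec$channel_name), "EDF Annotations")
  for (s in labels) wr(s, 16L)
  for (s in c("AgAgCl cup electrode", "")) wr(s, 80L)
  for (s in c("uV", "")) wr(s, 8L)
  for (v in c(phys_min, -1)) wr(sprintf("%.7g", v), 8L)
  for (v in c(phys_max, 1)) wr(sprintf("%.7g", v), 8L)
  for (v in c(dig_min, -32768L)) wr(as.character(v), 8L)
  for (v in c(dig_max, 32767L)) wr(as.character(v), 8L)
  for (s in c("HP:0Hz LP:800Hz", "")) wr(s, 80L)
  for (v in c(spr, ann_spr)) wr(as.character(v), 8L)
  for (s in c("", "")) wr(s, 32L)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(dig[idx], con, size = 2L, endian = "little")
    writeBin(ann_records[[r]], con)
  }
  invisible(path)
}

parse_tals <- function(bytes) {
  # split the raw stream on NUL terminators, then each TAL on \x14
  zero <- which(bytes == as.raw(0))
  starts <- c(1L, zero + 1L)
  ends <- c(zero - 1L, length(bytes))
  tals <- character(0)
  for (k in seq_along(starts)) {
    if (starts[k] <= ends[k])
      tals <- c(tals, rawToChar(bytes[starts[k]:ends[k]]))
  }
  out_t <- numeric(0); out_s <- character(0)
  for (t in tals) {
    if (!nzchar(t)) next
    parts <- strsplit(t, "\x14", fixed = TRUE)[[1L]]
    onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1L])))
    if (is.na(onset)) next
    notes <- parts[-1L]
    notes <- notes[nzchar(notes)]
    for (s in notes) { out_t <- c(out_t, onset); out_s <- c(out_s, s) }
  }
  data.frame(time = out_t, text = out_s, stringsAsFactors = FALSE)
}

#' Read one channel of an EDF/EDF+ file
#'
#' Returns the named channel in microvolts with any annotations whose text
#' matches a stimulus label mapped to events; unmapped annotations are
#' skipped with a warning. Physical dimensions `uV`, `mV` and `V` are
#' converted on load.
#'
#' @param path EDF/EDF+ file.
#' @param channel Channel label to extract; matched against the EDF label
#'   with or without an `"EEG "` prefix. Default `"Cz"`.
#' @param infant_id,age_group Metadata to attach (EDF carries no age group).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, channel = "Cz", infant_id = "unknown",
                           age_group = "term") {
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    r <- readBin(con, "raw", w)
    trimws(rawToChar(r))
  }
  version <- rd(8L)
  if (version != "0") stop("read_recording: not an EDF file (bad version field)")
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L))
  rd(44L)
  n_rec <- as.integer(rd(8L))
  record_s <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("read_recording: malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  invisible(vapply(seq_len(ns), function(i) rd(80L), character(1)))
  dims <- vapply(seq_len(ns), function(i) rd(8L), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  invisible(vapply(seq_len(ns), function(i) rd(80L), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  invisible(vapply(seq_len(ns), function(i) rd(32L), character(1)))

  want <- which(labels == channel | labels == paste("EEG", channel))
  if (!length(want))
    stop("read_recording: channel '", channel, "' not found (available: ",
         paste(labels, collapse = ", "), ")")
  want <- want[1L]
  ann_idx <- which(labels == "EDF Annotations")

  sig <- vector("list", n_rec)
  ann_raw <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (s == want) {
        sig[[r]] <- readBin(con, "integer", spr[s], size = 2L,
                            signed = TRUE, endian = "little")
      } else if (length(ann_idx) && s == ann_idx[1L]) {
        ann_raw[[r]] <- readBin(con, "raw", spr[s] * 2L)
      } else {
        invisible(readBin(con, "raw", spr[s] * 2L))
      }
    }
  }
  dig <- unlist(sig)
  scale <- (pmax_[want] - pmin_[want]) / (dmax_[want] - dmin_[want])
  phys <- pmin_[want] + (dig - dmin_[want]) * scale
  unit_mult <- switch(tolower(dims[want]), "uv" = 1, "mv" = 1e3, "v" = 1e6, 1)
  phys <- phys * unit_mult
  fs <- spr[want] / record_s

  events <- data.frame(time = numeric(0), stimulus = character(0),
                       stringsAsFactors = FALSE)
  if (length(ann_idx)) {
    ann <- parse_tals(do.call(c, ann_raw))
    if (nrow(ann)) {
      known <- ann$text %in% STIMULUS_LEVELS
      if (any(!known))
        warning("read_recording: skipping unmapped annotation(s): ",
                paste(unique(ann$text[!known]), collapse = ", "))
      ann <- ann[known, , drop = FALSE]
      ann <- ann[order(ann$time), , drop = FALSE]
      events <- data.frame(time = ann$time, stimulus = ann$text,
                           stringsAsFactors = FALSE)
    }
  }
  eeg_recording(phys, fs, events, channel_name = channel,
                infant_id = infant_id, age_group = age_group)
}
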