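# Minimal EDF (16-bit) writer/reader and BDF (24-bit BioSemi) reader.
# Implemented here because no installed R package reads these formats; covers
# exactly the subset this package emits and ingests: continuous records, one
# sampling rate, EEG channels plus one GSR channel.

# Format a number into at most `width` ASCII characters (EDF header fields).
edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) return(s)
  }
  isa_stop("isa_invalid_spec", "cannot format %g into %d characters", x, width)
}

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space-padded
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records: EEG channels first, the GSR
#' channel last. Physical scaling per channel spans the data range, so values
#' round-trip within one 16-bit quantization step. A JSON sidecar
#' (`<path>.json`) carries participant metadata, and the montage can be saved
#' with [write_montage()].
#'
#' @param rec an `isa_recording` with integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "isa_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    isa_stop("isa_invalid_spec", "EDF export needs an integer sampling rate")
  fs <- round(fs)
  n <- ncol(rec$eeg)
  n_rec <- n %/% fs
  if (n_rec < 1)
    isa_stop("isa_insufficient_data", "recording shorter than one data record")
  keep <- seq_len(n_rec * fs)
  signals <- rbind(rec$eeg[, keep, drop = FALSE], rec$gsr[keep])
  labels <- c(rec$montage$name, "GSR")
  dims <- c(rep("uV", nrow(rec$eeg)), "uS")
  ns <- nrow(signals)

  pmin_ <- apply(signals, 1, min)
  pmax_ <- apply(signals, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  pmin_s <- vapply(pmin_, edf_num, "")
  pmax_s <- vapply(pmax_, edf_num, "")
  pmin_ <- as.numeric(pmin_s)   # use header-representable values for scaling
  pmax_ <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr(sprintf("%s %s %s", rec$participant$id %||% "X",
             rec$participant$sex %||% "X", rec$participant$group %||% ""), 80)
  wr(sprintf("session %d", rec$session %||% 1), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (lb in labels) wr(lb, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (dm in dims) wr(dm, 8)
  for (s in pmin_s) wr(s, 8)
  for (s in pmax_s) wr(s, 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((signals[i, cols] - pmin_[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  meta <- list(participant = rec$participant, session = rec$session, fs = fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an EDF or BDF file
#'
#' Parses the fixed-layout header and the continuous data records; BioSemi
#' BDF files (24-bit samples) are detected from the magic byte and scaled per
#' the header's physical/digital ranges, like EDF.
#'
#' @param path EDF/BDF file path.
#' @return list with `labels`, `data` (channels x samples, physical units),
#'   `fs` (per-channel sampling rate), `dims` (physical dimensions).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                       # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                       # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  data <- lapply(spr, function(k) matrix(0, nrow = k, ncol = n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_bdf) {
        b <- as.integer(readBin(con, "raw", 3 * spr[i]))
        v <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
          65536 * b[seq(3, length(b), 3)]
        v[v >= 2^23] <- v[v >= 2^23] - 2^24
      } else {
        v <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                     endian = "little")
      }
      data[[i]][, r] <- v
    }
  }
  phys <- lapply(seq_len(ns), function(i) {
    as.numeric(data[[i]]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
      pmin_[i] - dmin[i] * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
  })
  nmax <- max(vapply(phys, length, 1L))
  mat <- matrix(NA_real_, ns, nmax)
  for (i in seq_len(ns)) mat[i, seq_along(phys[[i]])] <- phys[[i]]
  list(labels = labels, data = mat, fs = spr / rec_dur, dims = dims)
}

#' Write a montage as a plain-text electrode table
#'
#' @param montage data.frame with columns name, x, y, z.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage[, c("name", "x", "y", "z")], path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text electrode table
#'
#' @param path file with header `name x y z` and one electrode per line.
#' @return montage data.frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(m)))
    isa_stop("isa_montage", "montage file must have columns name, x, y, z")
  m
}

#' Read an EDF/BDF recording plus montage into an `isa_recording`
#'
#' The channel whose label contains "GSR" or "EDA" (case-insensitive) becomes
#' the GSR channel; all others are EEG channels and must match the montage
#' names one-to-one. Participant metadata is taken from a `<path>.json`
#' sidecar when present.
#'
#' @param path EDF/BDF file.
#' @param montage_path plain-text electrode table (see [read_montage()]).
#' @return an `isa_recording`.
#' @export
read_recording <- function(path, montage_path) {
  raw <- read_edf(path)
  is_gsr <- grepl("GSR|EDA", raw$labels, ignore.case = TRUE)
  if (sum(is_gsr) != 1)
    isa_stop("isa_channel_map",
             "expected exactly one GSR/EDA channel, found %d", sum(is_gsr))
  if (sum(!is_gsr) < 2)
    isa_stop("isa_channel_map", "need at least 2 EEG channels")
  if (length(unique(raw$fs)) != 1)
    isa_stop("isa_channel_map", "mixed sampling rates are not supported")
  montage <- read_montage(montage_path)
  eeg_labels <- raw$labels[!is_gsr]
  if (!identical(sort(montage$name), sort(eeg_labels)))
    isa_stop("isa_montage", "montage names do not match EEG channel labels")
  montage <- montage[match(eeg_labels, montage$name), ]
  meta <- list(id = "unknown", group = NA_character_, sex = NA_character_,
               age = NA_real_)
  session <- 1L
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(js$participant)) meta <- utils::modifyList(meta, js$participant)
    session <- js$session %||% 1L
  }
  structure(list(
    eeg = raw$data[!is_gsr, , drop = FALSE],
    gsr = as.numeric(raw$data[is_gsr, ]),
    fs = raw$fs[1], montage = montage, participant = meta,
    session = as.integer(session)
  ), class = "isa_recording")
}
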