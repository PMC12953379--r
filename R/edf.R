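# Minimal EDF (European Data Format) reader/writer for waveform
# interchange. Implements the fixed-layout 16-bit EDF core: one header,
# per-signal subheaders, sequential data records. Sufficient for the
# channels this pipeline exchanges (ECG, ACC_X/Y/Z, RESP); EDF+
# annotations are out of scope.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write waveform channels to an EDF file
#'
#' @param path Output file path.
#' @param channels Named list; each element a list with `samples`
#'   (numeric vector) and `rate` (Hz). Each channel's `rate *
#'   record_sec` must be a whole number.
#' @param record_sec Data-record duration in seconds.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, channels, record_sec = 1,
                      patient = "X", recording = "synthetic") {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  ns <- length(channels)
  spr <- vapply(channels, function(ch) {
    s <- ch$rate * record_sec
    if (abs(s - round(s)) > 1e-9) {
      stop("channel rate times record_sec must be an integer sample count")
    }
    as.integer(round(s))
  }, integer(1))
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$rate, numeric(1))
  n_rec <- as.integer(ceiling(max(durs) / record_sec))

  pmin_ <- numeric(ns)
  pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]]$samples
    need <- n_rec * spr[i]
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    lo <- min(x)
    hi <- max(x)
    if (hi - lo < 1e-12) {
      lo <- lo - 1
      hi <- hi + 1
    }
    pmin_[i] <- lo
    pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_sec), 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    labels = vapply(names(channels), edf_pad, character(1), width = 16),
    transducer = rep(edf_pad("", 80), ns),
    dim = rep(edf_pad("", 8), ns),
    pmin = vapply(pmin_, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), character(1)),
    pmax = vapply(pmax_, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), character(1)),
    dmin = rep(edf_pad(-32768, 8), ns),
    dmax = rep(edf_pad(32767, 8), ns),
    prefilter = rep(edf_pad("", 80), ns),
    spr = vapply(spr, edf_pad, character(1), width = 8),
    reserved = rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  # interleave: record-major, signal order within each record
  rec_len <- sum(spr)
  sig_off <- cumsum(c(0, spr))[seq_len(ns)]
  all_vals <- integer(n_rec * rec_len)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + sig_off[i],
                           (seq_len(n_rec) - 1) * rec_len, `+`))
    all_vals[idx] <- dig[[i]]
  }
  writeBin(all_vals, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1):(off + width)]))
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to
#'   return; an absent requested channel is an error.
#' @return List with `channels` (named list of `samples` + `rate`),
#'   `record_sec` and `n_records`.
#' @export
read_edf <- function(path, channels = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256) stop("malformed EDF header: file shorter than 256 bytes")
  n_rec <- as.integer(read_edf_field(raw, 236, 8))
  rec_sec <- as.numeric(read_edf_field(raw, 244, 8))
  ns <- as.integer(read_edf_field(raw, 252, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header at byte offset 252: bad signal count")
  hoff <- 256
  gets <- function(width) {
    out <- vapply(seq_len(ns), function(i)
      read_edf_field(raw, hoff + (i - 1) * width, width), character(1))
    hoff <<- hoff + ns * width
    out
  }
  labels <- gets(16)
  gets(80); gets(8)
  pmin_ <- as.numeric(gets(8))
  pmax_ <- as.numeric(gets(8))
  dmin_ <- as.numeric(gets(8))
  dmax_ <- as.numeric(gets(8))
  gets(80)
  spr <- as.integer(gets(8))
  gets(32)
  data_off <- 256 * (1 + ns)
  rec_len <- sum(spr)
  vals <- readBin(raw[(data_off + 1):length(raw)], "integer",
                  n = n_rec * rec_len, size = 2, signed = TRUE,
                  endian = "little")
  out <- vector("list", ns)
  names(out) <- labels
  sig_off <- cumsum(c(0, spr))[seq_len(ns)]
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + sig_off[i],
                           (seq_len(n_rec) - 1) * rec_len, `+`))
    x <- vals[idx]
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    out[[i]] <- list(samples = (x - dmin_[i]) * scale + pmin_[i],
                     rate = spr[i] / rec_sec)
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing) > 0) {
      stop("channel(s) not present in EDF: ", paste(missing, collapse = ", "))
    }
    out <- out[channels]
  }
  list(channels = out, record_sec = rec_sec, n_records = n_rec)
}

#' Write a synthetic night as EDF + hypnogram CSV
#'
#' @param rec [night_record] with waveforms.
#' @param dir Output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_night <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("%s_%s", rec$participant_id, rec$night_label))
  edf <- paste0(stem, ".edf")
  csv <- paste0(stem, "_hypnogram.csv")
  write_edf(edf, list(
    ECG = list(samples = rec$ecg, rate = rec$ecg_rate),
    ACC_X = list(samples = rec$accel$samples[, 1], rate = rec$accel$rate),
    ACC_Y = list(samples = rec$accel$samples[, 2], rate = rec$accel$rate),
    ACC_Z = list(samples = rec$accel$samples[, 3], rate = rec$accel$rate)))
  write_hypnogram_csv(rec$hypnogram, csv,
                      participant_id = rec$participant_id,
                      night_label = rec$night_label)
  invisible(c(edf, csv))
}

#' Read a night written by [write_night()]
#' @param edf_path EDF file path.
#' @param csv_path Hypnogram CSV path.
#' @return [night_record].
#' @export
read_night <- function(edf_path, csv_path) {
  ed <- read_edf(edf_path, c("ECG", "ACC_X", "ACC_Y", "ACC_Z"))
  hyp <- read_hypnogram_csv(csv_path)
  night_record(participant_id = attr(hyp, "participant_id") %||% "unknown",
               night_label = attr(hyp, "night_label") %||% NA_character_,
               hypnogram = hyp,
               ecg = ed$channels$ECG$samples,
               ecg_rate = ed$channels$ECG$rate,
               accel = accel_trace(cbind(ed$channels$ACC_X$samples,
                                         ed$channels$ACC_Y$samples,
                                         ed$channels$ACC_Z$samples),
                                   rate = ed$channels$ACC_X$rate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
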