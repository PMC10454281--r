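#' Read a Biosemi BDF or EDF recording
#'
#' Minimal reader for continuous European Data Format (16-bit) and Biosemi
#' BDF (24-bit) files. Signal values are returned in microvolts using each
#' signal's physical/digital calibration. Trigger events are extracted from
#' the status channel (label containing "Status" or "Trigger"): every sample
#' where the status value changes to a nonzero code yields one event.
#'
#' @param path path to a .bdf/.edf file.
#' @param format "auto" (default; detected from the header magic), "BDF" or
#'   "EDF".
#' @param layout optional [eeg_layout]; if supplied, the number of data
#'   channels (excluding the status channel) must match.
#' @return An [eeg_raw] (status channel removed from the data matrix).
#' @export
read_raw_recording <- function(path, format = c("auto", "BDF", "EDF"),
                               layout = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", n = 8L)
  is_bdf <- magic[1] == as.raw(255L)
  if (format == "BDF" && !is_bdf) stop("not a BDF file (bad magic byte)")
  if (format == "EDF" && is_bdf) stop("not an EDF file (BDF magic found)")

  rd_str <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd_num <- function(n) as.numeric(rd_str(n))
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)        # ids, date, time
  header_bytes <- rd_num(8)
  rd_str(44)                                          # reserved
  n_records <- rd_num(8)
  record_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  if (!is.finite(ns) || ns < 1L || !is.finite(header_bytes) ||
      header_bytes != 256L * (ns + 1L))
    stop("corrupt EDF/BDF header")

  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), "")
  labels <- fld(16)
  fld(80); fld(8)                                     # transducer, unit
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                                             # prefiltering
  spr <- as.integer(fld(8))                           # samples per record
  fld(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("corrupt EDF/BDF signal headers")
  if (length(unique(spr)) != 1L)
    stop("signals with differing samples-per-record are not supported")
  spr <- spr[1]

  bps <- if (is_bdf) 3L else 2L
  rec_bytes <- ns * spr * bps
  payload <- readBin(con, "raw", n = n_records * rec_bytes)
  if (length(payload) < n_records * rec_bytes)
    stop("file truncated: fewer data records than the header declares")

  if (is_bdf) {
    b <- as.integer(payload)
    dig <- b[seq(1, length(b), 3)] +
      256L * b[seq(2, length(b), 3)] +
      65536L * b[seq(3, length(b), 3)]
    dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
  } else {
    dig <- readBin(payload, "integer", n = length(payload) / 2L,
                   size = 2L, signed = TRUE, endian = "little")
  }
  # records x (signal-major blocks of spr samples) -> channels x samples
  dig <- array(dig, dim = c(spr, ns, n_records))
  data <- matrix(0, ns, spr * n_records)
  for (s in seq_len(ns)) data[s, ] <- as.vector(dig[, s, ])

  scale <- (pmax - pmin) / (dmax - dmin)
  phys <- data * scale + (pmin - dmin * scale)

  srate <- spr / record_dur
  status_idx <- grep("status|trigger", labels, ignore.case = TRUE)
  if (length(status_idx) == 0L)
    stop("no events: recording has no status/trigger channel")
  status_idx <- status_idx[1]
  status <- round(data[status_idx, ])                 # digital trigger codes
  prev <- c(0, status[-length(status)])
  onsets <- which(status != prev & status != 0)
  if (length(onsets) == 0L)
    stop("no events: status channel contains no trigger pulses")
  events <- data.frame(sample = onsets, code = status[onsets])

  keep <- setdiff(seq_len(ns), status_idx)
  if (!is.null(layout) && length(layout$labels) != length(keep))
    stop("configuration error: layout has ", length(layout$labels),
         " channels but recording has ", length(keep), " data channels")
  eeg_raw(phys[keep, , drop = FALSE], srate = srate, events = events,
          labels = labels[keep])
}

#' Write an EDF or BDF file (round-trip fixture support)
#'
#' Serializes an [eeg_raw] plus a "Status" trigger channel holding the event
#' codes at their sample indices. Quantization follows the format's digital
#' range over a symmetric physical range covering the data.
#'
#' @param rec an [eeg_raw].
#' @param path output path.
#' @param format "BDF" (24-bit) or "EDF" (16-bit).
#' @param physical_max symmetric physical range bound in microvolts
#'   (default: data maximum absolute value, rounded up).
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path, format = c("BDF", "EDF"),
                                physical_max = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_raw"))
  is_bdf <- format == "BDF"
  dig_lim <- if (is_bdf) 8388607 else 32767
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  srate <- rec$srate
  if (srate != round(srate)) stop("integer sampling rates only")
  n_records <- ceiling(nsamp / srate)
  total <- n_records * srate
  if (is.null(physical_max))
    physical_max <- max(1, ceiling(max(abs(rec$data))))

  status <- numeric(total)
  if (nrow(rec$events) > 0) status[rec$events$sample] <- rec$events$code
  dat <- cbind(rec$data, matrix(0, nch, total - nsamp))
  ns <- nch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) {
    s <- substr(sprintf("%-*s", w, x), 1, w)
    writeChar(s, con, nchars = w, eos = NULL)
  }
  if (is_bdf) {
    writeBin(as.raw(255L), con)
    wr("BIOSEMI", 7)
  } else wr("0", 8)
  wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(format(256L * (ns + 1L)), 8)
  wr(if (is_bdf) "24BIT" else "", 44)
  wr(format(n_records), 8)
  wr("1", 8)
  wr(format(ns), 4)

  labs <- c(rec$labels, "Status")
  for (l in labs) wr(l, 16)
  for (l in labs) wr("", 80)
  for (l in labs) wr("uV", 8)
  pmins <- c(rep(-physical_max, nch), -dig_lim - 1)
  pmaxs <- c(rep(physical_max, nch), dig_lim)
  dmins <- rep(-dig_lim - 1, ns)
  dmaxs <- rep(dig_lim, ns)
  for (v in pmins) wr(format(v), 8)
  for (v in pmaxs) wr(format(v), 8)
  for (v in dmins) wr(format(v), 8)
  for (v in dmaxs) wr(format(v), 8)
  for (l in labs) wr("", 80)
  for (l in labs) wr(format(srate), 8)
  for (l in labs) wr("", 32)

  scale <- (pmaxs - pmins) / (dmaxs - dmins)
  dig <- matrix(0L, ns, total)
  for (s in seq_len(nch))
    dig[s, ] <- as.integer(round((dat[s, ] - pmins[s]) / scale[s] + dmins[s]))
  dig[ns, ] <- as.integer(round(status))
  storage.mode(dig) <- "integer"
  dig <- pmax(pmin(dig, as.integer(dig_lim)), as.integer(-dig_lim - 1))
  storage.mode(dig) <- "integer"

  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * srate + 1L):(r * srate)
    block <- t(dig[, idx, drop = FALSE])              # spr x ns, signal-major
    v <- as.vector(block)
    if (is_bdf) {
      u <- ifelse(v < 0, v + 16777216, v)
      bytes <- as.raw(rbind(u %% 256L, (u %/% 256L) %% 256L,
                            (u %/% 65536L) %% 256L))
      writeBin(bytes, con)
    } else {
      writeBin(v, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
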