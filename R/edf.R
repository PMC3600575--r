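# Minimal EDF (European Data Format) input/output for continuous EEG.
# 16-bit integer samples; one physical/digital scaling per channel. All
# channels must share one sampling rate. Enough of the format for storing and
# exchanging recordings produced or consumed by this package.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  vapply(x, function(xi) {
    s <- formatC(xi, format = "g", digits = 7)
    if (nchar(s) > width) s <- substr(s, 1, width)
    edf_pad(s, width)
  }, "")
}

#' Write a continuous recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's physical
#' range (taken from the data), the standard EDF scaling; round-trip error is
#' bounded by the quantization step. Data records are 1 s long when the total
#' sample count is a multiple of the sampling rate, otherwise a single record
#' holds the whole recording.
#'
#' @param raw an \code{eeg_raw} object.
#' @param path output file path.
#' @param physical_dim physical dimension label (default "uV").
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(raw, path, physical_dim = "uV") {
  stopifnot(inherits(raw, "eeg_raw"))
  x <- raw$values
  D <- nrow(x); S <- ncol(x)
  if (S %% raw$sfreq == 0 && raw$sfreq == round(raw$sfreq)) {
    spr <- as.integer(raw$sfreq)         # samples per record
    n_rec <- S %/% spr
    dur <- 1
  } else {
    spr <- S
    n_rec <- 1L
    dur <- S / raw$sfreq
  }
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  # 256-byte fixed header
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))                        # patient id
  wr(edf_pad("Startdate X X X X", 80))              # recording id
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (1 + D), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_num(dur, 8))
  wr(edf_pad(D, 4))
  # per-signal header blocks (each field for all signals in turn)
  for (ch in raw$channels) wr(edf_pad(ch, 16))
  for (i in seq_len(D)) wr(edf_pad("", 80))         # transducer
  for (i in seq_len(D)) wr(edf_pad(physical_dim, 8))
  for (s in edf_num(pmin, 8)) wr(s)
  for (s in edf_num(pmax, 8)) wr(s)
  for (i in seq_len(D)) wr(edf_pad(dmin, 8))
  for (i in seq_len(D)) wr(edf_pad(dmax, 8))
  for (i in seq_len(D)) wr(edf_pad("", 80))         # prefiltering
  for (i in seq_len(D)) wr(edf_pad(spr, 8))
  for (i in seq_len(D)) wr(edf_pad("", 32))
  # EDF stores physical min/max as parsed back from their ASCII fields; use
  # the parsed values for scaling so the file is self-consistent.
  pmin_s <- as.numeric(edf_num(pmin, 8)); pmax_s <- as.numeric(edf_num(pmax, 8))
  scale <- (pmax_s - pmin_s) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(D)) {
      dig <- round((x[i, cols] - pmin_s[i]) / scale[i]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an \code{eeg_raw} object
#'
#' Supports ordinary EDF/EDF+ continuous recordings in which all signals share
#' one sampling rate. Annotation channels ("EDF Annotations") are dropped.
#'
#' @param path EDF file path.
#' @return An \code{eeg_raw} object.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdn <- function(n) as.numeric(trimws(rd(n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rdn(8)                                        # header bytes
  rd(44)
  n_rec <- rdn(8)
  dur <- rdn(8)
  D_all <- as.integer(rdn(4))
  field <- function(w) vapply(seq_len(D_all), function(i) trimws(rd(w)), "")
  labels <- field(16)
  field(80)                                     # transducer
  field(8)                                      # physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                                     # prefiltering
  spr <- as.integer(field(8))
  field(32)
  keep <- !grepl("^EDF Annotations", labels)
  if (!any(keep)) stop("EDF file contains no signal channels", call. = FALSE)
  if (length(unique(spr[keep])) != 1L)
    stop("EDF signals with differing sampling rates are not supported",
         call. = FALSE)
  sfreq <- spr[keep][1] / dur
  scale <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, sum(keep), n_rec * spr[keep][1])
  for (r in seq_len(n_rec)) {
    ki <- 0L
    for (i in seq_len(D_all)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (keep[i]) {
        ki <- ki + 1L
        cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
        out[ki, cols] <- (dig - dmin[i]) * scale[i] + pmin[i]
      }
    }
  }
  eeg_raw(out, sfreq, labels[keep])
}
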