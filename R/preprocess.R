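#' Construct a continuous multichannel EEG recording
#'
#' Light container for raw (continuous, unepoched) EEG: a channels-by-samples
#' matrix plus sampling rate and channel names.
#'
#' @param values numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel names (default "ch1", ...).
#' @return An object of class \code{eeg_raw}.
#' @export
eeg_raw <- function(values, sfreq, channels = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), sfreq > 0)
  assert_finite(values, "raw EEG")
  channels <- channels %||% paste0("ch", seq_len(nrow(values)))
  stopifnot(length(channels) == nrow(values))
  structure(list(values = values, sfreq = sfreq,
                 channels = as.character(channels)),
            class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat("<eeg_raw> ", nrow(x$values), " channels x ", ncol(x$values),
      " samples @ ", x$sfreq, " Hz (",
      round(ncol(x$values) / x$sfreq, 2), " s)\n", sep = "")
  invisible(x)
}

#' Zero-phase high-pass and notch filtering of raw EEG
#'
#' Applies a forward-backward (zero-phase) Butterworth high-pass filter to
#' remove DC drifts, followed by zero-phase Butterworth band-stop (notch)
#' filters at the given power-line frequencies. Defaults: 1.5 Hz high-pass and
#' notches at 50 and 100 Hz.
#'
#' @param raw an \code{eeg_raw} object.
#' @param highpass high-pass cutoff in Hz, or \code{NULL} to skip.
#' @param notch numeric vector of notch center frequencies in Hz (possibly
#'   empty).
#' @param order Butterworth order for the high-pass stage (the notch stages use
#'   order 2 per side).
#' @param notch_width half-width of each stop band in Hz.
#' @return A filtered \code{eeg_raw}.
#' @export
filter_raw <- function(raw, highpass = 1.5, notch = c(50, 100),
                       order = 4, notch_width = 2) {
  stopifnot(inherits(raw, "eeg_raw"))
  nyq <- raw$sfreq / 2
  cutoffs <- c(highpass, if (length(notch)) notch + notch_width)
  if (any(cutoffs >= nyq))
    stop("filter cutoff at or above the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  x <- raw$values
  apply_filt <- function(filt, x) {
    t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
  }
  if (!is.null(highpass)) {
    # remove the per-channel mean first: the zero-phase IIR then only has to
    # handle drifts, not the full DC offset
    x <- x - rowMeans(x)
    hp <- signal::butter(order, highpass / nyq, type = "high")
    x <- apply_filt(hp, x)
  }
  for (f0 in notch) {
    bs <- signal::butter(2, c(f0 - notch_width, f0 + notch_width) / nyq,
                         type = "stop")
    x <- apply_filt(bs, x)
  }
  eeg_raw(x, raw$sfreq, raw$channels)
}

#' Read and write per-trial event tables (TSV)
#'
#' The event table carries one row per stimulus event: the onset sample in the
#' raw recording (1-based), a condition label, the behavioral response (e.g.,
#' reaction time in ms) and a stimulus type label. Onsets must be strictly
#' increasing and responses positive where present.
#'
#' @param path file path of a tab-separated table with columns
#'   \code{onset_sample}, \code{condition}, \code{rt_ms}, \code{stim_type}.
#' @return \code{read_events}: a validated data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_events(ev)
}

#' @rdname read_events
#' @param events an event data frame.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_events <- function(ev) {
  need <- c("onset_sample", "condition", "rt_ms", "stim_type")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols))
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(ev) > 1 && any(diff(ev$onset_sample) <= 0))
    stop("event onsets must be strictly increasing", call. = FALSE)
  rt <- ev$rt_ms[!is.na(ev$rt_ms)]
  if (any(rt <= 0)) stop("response values must be positive", call. = FALSE)
  ev
}

#' Epoch a continuous recording around stimulus events
#'
#' Extracts fixed windows around each event onset. Latency sample k (0 at the
#' event onset) belongs to the epoch iff \code{t0 <= 1000*k/sfreq < t1}
#' (half-open convention), so a (-700, 1000) ms window at 512 Hz yields 870
#' samples. Events whose window extends outside the recording are dropped with
#' a warning.
#'
#' @param raw an \code{eeg_raw} object.
#' @param events event data frame (see \code{\link{read_events}}).
#' @param window_ms length-2 numeric, epoch window in ms relative to onset.
#'   Default \code{c(-700, 1000)}.
#' @return An \code{eeg_epochs} object: \code{values} is a channels x latency
#'   x trials array; \code{times} the latency axis in ms; \code{events} the
#'   retained event rows.
#' @export
epoch_data <- function(raw, events, window_ms = c(-700, 1000)) {
  stopifnot(inherits(raw, "eeg_raw"), length(window_ms) == 2)
  events <- validate_events(events)
  rel <- sample_range(window_ms[1], window_ms[2], raw$sfreq)
  times <- 1000 * rel / raw$sfreq
  S <- ncol(raw$values)
  n_ev <- nrow(events)
  keep <- logical(n_ev)
  if (n_ev > 0) {
    first <- events$onset_sample + rel[1]
    last <- events$onset_sample + rel[length(rel)]
    keep <- first >= 1 & last <= S
  }
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(n_drop, " event(s) dropped: epoch window outside the recording",
            call. = FALSE)
  events <- events[keep, , drop = FALSE]
  N <- nrow(events)
  D <- nrow(raw$values)
  vals <- array(0, dim = c(D, length(rel), N))
  for (n in seq_len(N))
    vals[, , n] <- raw$values[, events$onset_sample[n] + rel, drop = FALSE]
  structure(list(values = vals, sfreq = raw$sfreq, times = times,
                 channels = raw$channels, events = events,
                 window_ms = window_ms,
                 log = character(0)),
            class = "eeg_epochs")
}

#' Construct an epoched EEG object from an array
#'
#' For data epoched elsewhere: wraps a channels x latency x trials array with
#' the package's epoch conventions. The latency axis is derived from
#' \code{window_ms} and \code{sfreq} using the half-open sample convention
#' and must match the array's second dimension.
#'
#' @param values channels x latency x trials numeric array.
#' @param sfreq sampling rate, Hz.
#' @param window_ms length-2 epoch window in ms relative to the event.
#' @param channels optional channel names.
#' @param events optional event data frame (one row per trial).
#' @return An \code{eeg_epochs} object.
#' @export
eeg_epochs <- function(values, sfreq, window_ms, channels = NULL,
                       events = NULL) {
  stopifnot(length(dim(values)) == 3, sfreq > 0, length(window_ms) == 2)
  assert_finite(values, "epochs")
  rel <- sample_range(window_ms[1], window_ms[2], sfreq)
  if (length(rel) != dim(values)[2])
    stop("window [", window_ms[1], ", ", window_ms[2], ") ms at ", sfreq,
         " Hz implies ", length(rel), " latency samples; array has ",
         dim(values)[2], call. = FALSE)
  channels <- channels %||% paste0("ch", seq_len(dim(values)[1]))
  stopifnot(length(channels) == dim(values)[1])
  structure(list(values = values, sfreq = sfreq,
                 times = 1000 * rel / sfreq,
                 channels = as.character(channels),
                 events = events, window_ms = window_ms,
                 log = character(0)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$values)
  cat("<eeg_epochs> ", d[1], " channels x ", d[2], " latencies x ", d[3],
      " trials @ ", x$sfreq, " Hz; window [", x$window_ms[1], ", ",
      x$window_ms[2], ") ms\n", sep = "")
  invisible(x)
}

#' Baseline correction of epoched EEG
#'
#' Subtracts, per channel and trial, the mean amplitude over the baseline
#' interval (default -300 to -100 ms, half-open). Idempotent.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param baseline_ms length-2 numeric baseline interval in ms.
#' @return The corrected \code{eeg_epochs}.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-300, -100)) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(baseline_ms) == 2)
  if (baseline_ms[1] < epochs$window_ms[1] - 1e-9 ||
      baseline_ms[2] > epochs$window_ms[2] + 1e-9)
    stop("baseline interval lies outside the epoch window", call. = FALSE)
  sel <- window_samples(epochs$times, baseline_ms[1],
                        baseline_ms[2] - baseline_ms[1])
  v <- epochs$values
  N <- dim(v)[3]
  for (n in seq_len(N)) {
    m <- rowMeans(matrix(v[, sel, n, drop = FALSE], nrow = dim(v)[1]))
    v[, , n] <- v[, , n] - m
  }
  epochs$values <- v
  epochs$log <- c(epochs$log,
                  sprintf("baseline_correct [%g, %g) ms", baseline_ms[1],
                          baseline_ms[2]))
  epochs
}

#' Average re-referencing
#'
#' Subtracts, at every latency (and trial), the instantaneous mean across
#' channels. Works on both continuous (\code{eeg_raw}) and epoched
#' (\code{eeg_epochs}) data; requires at least two channels. Idempotent.
#'
#' @param x an \code{eeg_raw} or \code{eeg_epochs} object.
#' @return The re-referenced object.
#' @export
rereference_average <- function(x) UseMethod("rereference_average")

#' @export
rereference_average.eeg_raw <- function(x) {
  if (nrow(x$values) < 2)
    stop("average re-reference requires at least 2 channels", call. = FALSE)
  x$values <- sweep(x$values, 2L, colMeans(x$values))
  x
}

#' @export
rereference_average.eeg_epochs <- function(x) {
  d <- dim(x$values)
  if (d[1] < 2)
    stop("average re-reference requires at least 2 channels", call. = FALSE)
  mu <- colMeans(x$values, dims = 1L)            # latency x trial
  x$values <- x$values - aperm(array(mu, c(d[2], d[3], d[1])), c(3, 1, 2))
  x$log <- c(x$log, "rereference_average")
  x
}

#' Deterministic preprocessing pipeline
#'
#' Runs the fixed stage order: zero-phase filtering, ocular-artifact hook,
#' average re-reference, epoching, trial-rejection hook, baseline correction.
#' The ocular and rejection stages are pluggable no-op hooks by default:
#' \code{ocular_hook(raw)} must return an \code{eeg_raw} and
#' \code{reject_hook(epochs)} an \code{eeg_epochs}. Each stage is logged in
#' the returned object's \code{log} field.
#'
#' @param raw an \code{eeg_raw} object.
#' @param events event data frame.
#' @param highpass,notch see \code{\link{filter_raw}}.
#' @param window_ms see \code{\link{epoch_data}}.
#' @param baseline_ms see \code{\link{baseline_correct}}.
#' @param ocular_hook,reject_hook optional stage functions (identity when
#'   \code{NULL}).
#' @return A preprocessed \code{eeg_epochs} with a stage log.
#' @export
preprocess_pipeline <- function(raw, events, highpass = 1.5,
                                notch = c(50, 100),
                                window_ms = c(-700, 1000),
                                baseline_ms = c(-300, -100),
                                ocular_hook = NULL, reject_hook = NULL) {
  log <- character(0)
  raw <- filter_raw(raw, highpass, notch)
  log <- c(log, sprintf("filter_raw highpass=%s notch=[%s]",
                        format(highpass), paste(notch, collapse = ",")))
  if (!is.null(ocular_hook)) {
    raw <- ocular_hook(raw)
    stopifnot(inherits(raw, "eeg_raw"))
    log <- c(log, "ocular_hook")
  } else log <- c(log, "ocular_hook (no-op)")
  raw <- rereference_average(raw)
  log <- c(log, "rereference_average")
  ep <- epoch_data(raw, events, window_ms)
  log <- c(log, sprintf("epoch_data [%g, %g) ms", window_ms[1], window_ms[2]))
  if (!is.null(reject_hook)) {
    ep <- reject_hook(ep)
    stopifnot(inherits(ep, "eeg_epochs"))
    log <- c(log, "reject_hook")
  } else log <- c(log, "reject_hook (no-op)")
  ep <- baseline_correct(ep, baseline_ms)
  ep$log <- c(log, sprintf("baseline_correct [%g, %g) ms",
                           baseline_ms[1], baseline_ms[2]))
  ep
}
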