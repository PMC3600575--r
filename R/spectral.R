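#' Morlet decomposition specification
#'
#' Defines the complex Morlet kernels used for time-frequency decomposition:
#' \code{phi(t) = alpha * exp(2*pi*i*f*t) * exp(-t^2 / (2*sigma^2))} with
#' \code{sigma = cycles / (2*pi*f)} and \code{alpha} fixed so each kernel has
#' unit L2 norm, making power comparable across frequencies.
#'
#' @param frequencies numeric vector of center frequencies in Hz; must be
#'   strictly positive and below Nyquist.
#' @param cycles positive real (>= 1) controlling the Gaussian envelope width.
#' @param sfreq sampling rate in Hz.
#' @return An object of class \code{morlet_spec}.
#' @export
morlet_spec <- function(frequencies, cycles = 3, sfreq) {
  stopifnot(length(frequencies) >= 1, sfreq > 0)
  if (any(frequencies <= 0))
    stop("frequencies must be strictly positive", call. = FALSE)
  if (any(frequencies >= sfreq / 2))
    stop("frequency at or above the Nyquist frequency (", sfreq / 2, " Hz)",
         call. = FALSE)
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  structure(list(frequencies = as.numeric(frequencies), cycles = cycles,
                 sfreq = sfreq),
            class = "morlet_spec")
}

#' Complex Morlet kernel at one frequency
#'
#' @param f center frequency, Hz.
#' @param cycles envelope width in cycles.
#' @param sfreq sampling rate, Hz.
#' @return List with the complex \code{kernel} (odd length, centered,
#'   unit L2 norm), the envelope standard deviation \code{sigma_ms}, and the
#'   kernel \code{length} in samples (support truncated at 3.5 sigma).
#' @export
morlet_kernel <- function(f, cycles, sfreq) {
  sigma <- cycles / (2 * pi * f)                  # seconds
  half <- ceiling(3.5 * sigma * sfreq)
  t <- (-half:half) / sfreq
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  k <- k / sqrt(sum(Mod(k)^2))
  list(kernel = k, sigma_ms = 1000 * sigma, length = length(k))
}

#' Morlet time-frequency power of epoched EEG
#'
#' Convolves every channel/trial signal with each complex Morlet kernel
#' (FFT-based, same-length output with zero padding) and returns the
#' instantaneous power \code{|F(c,t,f,n)|^2}. Latencies within two envelope
#' standard deviations of either epoch edge are flagged (not dropped) in the
#' \code{edge} metadata, per frequency.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param spec a \code{morlet_spec}.
#' @param latency_range optional length-2 ms interval (half-open): compute
#'   power only at these output latencies. The convolution always uses the
#'   full epoch, so restricting the output changes nothing numerically; for
#'   narrow ranges a direct (matrix) convolution over the requested rows is
#'   used instead of the FFT, which is substantially faster.
#' @return A \code{power_tensor}: \code{values} is channels x latency x
#'   frequency x trials (all nonnegative), plus axis metadata and the
#'   \code{edge} flag matrix (latency x frequency).
#' @export
morlet_power <- function(epochs, spec, latency_range = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "morlet_spec"))
  if (!isTRUE(all.equal(spec$sfreq, epochs$sfreq)))
    stop("sampling rate mismatch between epochs and spectral spec",
         call. = FALSE)
  d <- dim(epochs$values)
  D <- d[1]; T_ <- d[2]; N <- d[3]
  kernels <- lapply(spec$frequencies, morlet_kernel,
                    cycles = spec$cycles, sfreq = spec$sfreq)
  klen <- vapply(kernels, `[[`, 0, "length")
  if (max(klen) > T_)
    stop("epoch (", T_, " samples) shorter than the Morlet kernel support (",
         max(klen), " samples) at ",
         spec$frequencies[which.max(klen)], " Hz", call. = FALSE)
  nF <- length(kernels)
  if (is.null(latency_range)) {
    out_idx <- seq_len(T_)
  } else {
    stopifnot(length(latency_range) == 2)
    out_idx <- which(epochs$times >= latency_range[1] - 1e-9 &
                     epochs$times < latency_range[2] - 1e-9)
    if (length(out_idx) == 0)
      stop("latency_range contains no epoch sample", call. = FALSE)
  }
  To <- length(out_idx)
  # signals as columns: latency x (channel*trial)
  xm <- matrix(aperm(epochs$values, c(2, 1, 3)), nrow = T_)
  # direct (BLAS) convolution wins for short-to-moderate epochs; FFT for long
  use_fft <- To * as.numeric(T_) > 2e5
  if (use_fft) {
    L <- next_fast_len(T_ + max(klen) - 1L)
    Xf <- stats::mvfft(rbind(xm, matrix(0, L - T_, ncol(xm))))
  }
  pow <- array(0, dim = c(D, To, nF, N))
  edge <- matrix(FALSE, To, nF)
  t0 <- epochs$times[1]; t1 <- epochs$times[T_]
  for (fi in seq_len(nF)) {
    k <- kernels[[fi]]
    half <- (k$length - 1L) / 2L
    if (use_fft) {
      Kf <- stats::fft(c(k$kernel, rep(0, L - k$length)))
      conv <- stats::mvfft(Xf * Kf, inverse = TRUE) / L
      same <- conv[half + out_idx, , drop = FALSE]
      p <- Mod(same)^2                            # latency x (channel*trial)
    } else {
      # direct convolution, restricted to the requested output rows:
      # same[t] = sum_j kernel[j] * x[t + center - j]
      ind <- outer(out_idx, seq_len(T_),
                   function(t, s) half + 1L + t - s)
      valid <- ind >= 1L & ind <= k$length
      Kre <- matrix(0, To, T_); Kim <- matrix(0, To, T_)
      Kre[valid] <- Re(k$kernel[ind[valid]])
      Kim[valid] <- Im(k$kernel[ind[valid]])
      p <- (Kre %*% xm)^2 + (Kim %*% xm)^2
    }
    pow[, , fi, ] <- aperm(array(p, c(To, D, N)), c(2, 1, 3))
    edge[, fi] <- epochs$times[out_idx] < t0 + 2 * k$sigma_ms |
      epochs$times[out_idx] > t1 - 2 * k$sigma_ms
  }
  structure(list(values = pow, channels = epochs$channels,
                 times = epochs$times[out_idx],
                 frequencies = spec$frequencies,
                 trials = epochs$events, sfreq = epochs$sfreq,
                 cycles = spec$cycles, edge = edge),
            class = "power_tensor")
}

#' @export
print.power_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<power_tensor> ", d[1], " channels x ", d[2], " latencies x ", d[3],
      " frequencies x ", d[4], " trials; ",
      paste(range(x$frequencies), collapse = "-"), " Hz\n", sep = "")
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Default closed band intervals: theta 5-7, alpha 8-12, beta1 16-22,
#' beta2 23-30, gamma 31-40 Hz.
#'
#' @return Data frame with columns \code{band}, \code{lo}, \code{hi}.
#' @export
eeg_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta1", "beta2", "gamma"),
             lo = c(5, 8, 16, 23, 31),
             hi = c(7, 12, 22, 30, 40))
}

#' Read band definitions from a YAML config
#'
#' Expects a mapping \code{bands: {alpha: [8, 12], ...}}; returns the same
#' data frame layout as \code{\link{eeg_bands}}.
#'
#' @param path YAML file path.
#' @return Data frame with columns \code{band}, \code{lo}, \code{hi}.
#' @export
read_band_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- cfg$bands %||% cfg
  data.frame(band = names(b),
             lo = vapply(b, function(x) as.numeric(x[[1]]), 0),
             hi = vapply(b, function(x) as.numeric(x[[2]]), 0),
             row.names = NULL)
}

#' Collapse a power tensor over a frequency band
#'
#' For each (channel, latency, trial), takes the maximum instantaneous power
#' over the grid frequencies inside the closed band interval, then subtracts
#' the baseline mean \code{M} (per channel and latency), yielding the
#' band-power analysis dataset. \code{M} is computed from the collapsed tensor
#' over the baseline trial set; by default all trials of the dataset serve as
#' baseline.
#'
#' @param power a \code{power_tensor}.
#' @param band length-2 numeric closed interval in Hz, or a band name from
#'   \code{\link{eeg_bands}}.
#' @param baseline_trials integer indices of the trials defining the baseline
#'   mean \code{M} (default: all trials), or a precomputed channels x latency
#'   baseline matrix.
#' @param band_name optional label stored with the dataset.
#' @param subject,condition optional provenance labels.
#' @return A \code{band_power} object: \code{values} channels x latency x
#'   trials, the subtracted \code{baseline_mean}, band interval and
#'   provenance.
#' @export
band_collapse <- function(power, band, baseline_trials = NULL,
                          band_name = NULL, subject = NA, condition = NA) {
  stopifnot(inherits(power, "power_tensor"))
  if (is.character(band)) {
    tbl <- eeg_bands()
    row <- tbl[tbl$band == band, ]
    if (nrow(row) == 0) stop("unknown band name: ", band, call. = FALSE)
    band_name <- band_name %||% band
    band <- c(row$lo, row$hi)
  }
  stopifnot(length(band) == 2, band[2] >= band[1])
  sel <- which(power$frequencies >= band[1] - 1e-9 &
               power$frequencies <= band[2] + 1e-9)
  if (length(sel) == 0)
    stop("band [", band[1], ", ", band[2],
         "] Hz contains no grid frequency", call. = FALSE)
  d <- dim(power$values)
  collapsed <- power$values[, , sel[1], , drop = FALSE]
  dim(collapsed) <- d[c(1, 2, 4)]
  for (fi in sel[-1]) {
    slab <- power$values[, , fi, , drop = FALSE]
    dim(slab) <- d[c(1, 2, 4)]
    collapsed <- pmax(collapsed, slab)
  }
  N <- d[4]
  if (is.matrix(baseline_trials)) {
    M <- baseline_trials
    stopifnot(all(dim(M) == d[1:2]))
  } else {
    bl <- baseline_trials %||% seq_len(N)
    if (length(bl) == 0) stop("baseline trial set is empty", call. = FALSE)
    stopifnot(all(bl >= 1), all(bl <= N))
    M <- rowMeans(collapsed[, , bl, drop = FALSE], dims = 2L)
  }
  vals <- collapsed - array(M, d[c(1, 2, 4)])
  trials <- power$trials
  if (is.null(trials) || nrow(trials) != N)
    trials <- data.frame(trial = seq_len(N))
  trials$trial_id <- seq_len(N)
  trials$subject <- subject
  trials$condition <- condition
  structure(list(values = vals, channels = power$channels,
                 times = power$times, sfreq = power$sfreq,
                 band = band, band_name = band_name %||% "band",
                 baseline_mean = M,
                 edge = apply(power$edge[, sel, drop = FALSE], 1L, any),
                 trials = trials),
            class = "band_power")
}

#' Construct a band-power dataset directly from values
#'
#' Low-level constructor used by simulations and tests that work in
#' band-power space without a spectral decomposition.
#'
#' @param values channels x latency x trials array.
#' @param times latency axis, ms.
#' @param sfreq sampling rate, Hz.
#' @param channels channel names.
#' @param band band interval (Hz); informational.
#' @param band_name band label.
#' @param trials optional trial provenance data frame.
#' @return A \code{band_power} object.
#' @export
band_power <- function(values, times, sfreq, channels = NULL,
                       band = c(NA_real_, NA_real_), band_name = "band",
                       trials = NULL) {
  stopifnot(length(dim(values)) == 3, length(times) == dim(values)[2])
  channels <- channels %||% paste0("ch", seq_len(dim(values)[1]))
  N <- dim(values)[3]
  if (is.null(trials))
    trials <- data.frame(trial_id = seq_len(N), subject = NA, condition = NA)
  structure(list(values = values, channels = channels, times = times,
                 sfreq = sfreq, band = band, band_name = band_name,
                 baseline_mean = matrix(0, dim(values)[1], dim(values)[2]),
                 edge = rep(FALSE, length(times)), trials = trials),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  d <- dim(x$values)
  cat("<band_power> '", x$band_name, "' [",
      paste(x$band, collapse = ", "), "] Hz; ", d[1], " channels x ", d[2],
      " latencies x ", d[3], " trials\n", sep = "")
  invisible(x)
}

#' Aggregate band-power datasets across subjects
#'
#' Concatenates datasets along the trial axis (channel and latency axes must
#' be identical). Per-trial provenance records the source dataset and the
#' original trial index, so any trial is retrievable after aggregation.
#'
#' @param datasets list of \code{band_power} objects.
#' @return A single \code{band_power} with concatenated trials.
#' @export
aggregate_subjects <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  lapply(datasets, function(d) stopifnot(inherits(d, "band_power")))
  ref <- datasets[[1]]
  for (d in datasets[-1]) {
    if (!identical(d$channels, ref$channels) ||
        !isTRUE(all.equal(d$times, ref$times)))
      stop("channel/latency axes differ across datasets", call. = FALSE)
  }
  if (length(datasets) == 1L) return(ref)
  Ns <- vapply(datasets, function(d) dim(d$values)[3], 0L)
  vals <- array(0, dim = c(dim(ref$values)[1:2], sum(Ns)))
  off <- 0L
  prov <- vector("list", length(datasets))
  for (j in seq_along(datasets)) {
    vals[, , off + seq_len(Ns[j])] <- datasets[[j]]$values
    tj <- datasets[[j]]$trials
    tj$source_dataset <- j
    tj$source_trial <- seq_len(Ns[j])
    prov[[j]] <- tj
    off <- off + Ns[j]
  }
  cols <- Reduce(intersect, lapply(prov, names))
  trials <- do.call(rbind, lapply(prov, function(p) p[, cols, drop = FALSE]))
  trials$trial_id <- seq_len(nrow(trials))
  out <- ref
  out$values <- vals
  out$trials <- trials
  out$baseline_mean <- NULL
  out
}

#' Band power from epochs in one step
#'
#' Convenience wrapper: builds a 1 Hz frequency grid spanning the band, runs
#' \code{\link{morlet_power}} and \code{\link{band_collapse}}.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param band length-2 numeric interval (Hz) or band name.
#' @param cycles Morlet envelope width in cycles.
#' @param latency_range optional output latency restriction (ms), see
#'   \code{\link{morlet_power}}.
#' @param ... passed to \code{\link{band_collapse}}.
#' @return A \code{band_power} object.
#' @export
compute_band_power <- function(epochs, band = "alpha", cycles = 3,
                               latency_range = NULL, ...) {
  if (is.character(band)) {
    tbl <- eeg_bands()
    row <- tbl[tbl$band == band, ]
    if (nrow(row) == 0) stop("unknown band name: ", band, call. = FALSE)
    nm <- band
    band <- c(row$lo, row$hi)
  } else nm <- paste0(band[1], "-", band[2], "Hz")
  spec <- morlet_spec(seq(band[1], band[2], by = 1), cycles, epochs$sfreq)
  band_collapse(morlet_power(epochs, spec, latency_range), band,
                band_name = nm, ...)
}
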