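# Shared fixtures, built in code.

# random dataset directly in band-power (analysis) space
tiny_band <- function(D = 3, T_ = 10, N = 40, sfreq = 100, seed = 1,
                      values = NULL) {
  if (is.null(values)) {
    set.seed(seed)
    values <- array(stats::rnorm(D * T_ * N), c(D, T_, N))
  }
  band_power(values, times = 1000 * (seq_len(dim(values)[2]) - 1) / sfreq,
             sfreq = sfreq)
}

# sinusoidal epochs: one trial per phase, D channels scaled by `gains`
sine_epochs <- function(freq, sfreq = 128, n_sec = 2, n_trials = 3,
                        gains = 1, amplitude = 1) {
  T_ <- n_sec * sfreq
  tt <- (0:(T_ - 1)) / sfreq
  D <- length(gains)
  vals <- array(0, c(D, T_, n_trials))
  for (n in seq_len(n_trials))
    vals[, , n] <- outer(gains,
                         amplitude * sin(2 * pi * freq * tt + n))
  eeg_epochs(vals, sfreq, c(0, 1000 * n_sec))
}

# brute-force Benjamini-Hochberg step-up, written independently of p.adjust
brute_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  sel <- logical(m)
  if (length(below) > 0) sel[o[seq_len(max(below))]] <- TRUE
  sel
}

# direct time-domain complex convolution, same-length with zero padding
direct_morlet <- function(x, kernel) {
  T_ <- length(x)
  Lk <- length(kernel)
  half <- (Lk - 1) / 2
  out <- complex(T_)
  for (t in seq_len(T_)) {
    acc <- 0 + 0i
    for (j in seq_len(Lk)) {
      s <- t + half + 1 - j
      if (s >= 1 && s <= T_) acc <- acc + kernel[j] * x[s]
    }
    out[t] <- acc
  }
  out
}

# quick spatial filter object without fitting
raw_filter <- function(weights, channels = NULL, tau = 0, delta_t = 1,
                       lambda = 0, band = "band", achieved_r = NA_real_) {
  structure(list(weights = weights, lambda = lambda, tau = tau, band = band,
                 channels = channels %||% paste0("ch", seq_along(weights)),
                 delta_t = delta_t, achieved_r = achieved_r),
            class = "spatial_filter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
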