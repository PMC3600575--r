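# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's RNG
# stream. `seed` may be NULL, in which case the current stream is used as-is.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample indices k (relative to the alignment point, 0-based) covered by the
# half-open time interval [t0, t1) in ms at sampling rate sfreq. The epoch
# convention used throughout: sample k lies in the window iff
# t0 <= 1000 * k / sfreq < t1.
sample_range <- function(t0, t1, sfreq) {
  stopifnot(t1 > t0, sfreq > 0)
  eps <- 1e-9
  kmin <- ceiling(t0 * sfreq / 1000 - eps)
  kmax <- ceiling(t1 * sfreq / 1000 - eps) - 1
  if (kmax < kmin) stop("interval [", t0, ", ", t1, ") ms contains no sample at ",
                        sfreq, " Hz", call. = FALSE)
  as.integer(kmin:kmax)
}

# Indices into a latency axis `times` (ms) covered by the half-open window
# [start, start + duration).
window_samples <- function(times, start, duration) {
  idx <- which(times >= start - 1e-9 & times < start + duration - 1e-9)
  if (length(idx) == 0L)
    stop("window [", start, ", ", start + duration,
         ") ms contains no latency sample", call. = FALSE)
  idx
}

# FFT length with only small prime factors, >= n.
next_fast_len <- function(n) stats::nextn(n, c(2L, 3L, 5L))

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
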