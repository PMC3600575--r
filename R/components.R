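#' Single-trial correlated components (SCC)
#'
#' Projects the band-power dataset through a fitted spatial filter:
#' \code{z_n(t) = w' x_n(t)} for every trial and latency. The component
#' amplitude is the quantity that tracks the behavioral variable.
#'
#' @param filter a \code{spatial_filter}.
#' @param band_data a \code{band_power} dataset with matching channel axis.
#' @return A \code{component_ts}: \code{values} trials x latency, latency
#'   axis, trial provenance, and filter metadata.
#' @export
scc <- function(filter, band_data) {
  stopifnot(inherits(filter, "spatial_filter"),
            inherits(band_data, "band_power"))
  if (!identical(filter$channels, band_data$channels))
    stop("channel axes of filter and dataset do not match", call. = FALSE)
  d <- dim(band_data$values)
  xm <- matrix(band_data$values, nrow = d[1])        # D x (T*N)
  z <- matrix(as.numeric(crossprod(xm, filter$weights)), d[2], d[3])
  structure(list(values = t(z), times = band_data$times,
                 trials = band_data$trials, filter = filter),
            class = "component_ts")
}

#' @export
print.component_ts <- function(x, ...) {
  d <- dim(x$values)
  cat("<component_ts> ", d[1], " trials x ", d[2], " latencies; tau = ",
      x$filter$tau, " ms, band '", x$filter$band, "'\n", sep = "")
  invisible(x)
}

#' Component correlation trace (CCT)
#'
#' Across-trial Pearson correlation between the component amplitude and the
#' behavioral variable, at every latency of the epoch. Latencies with zero
#' component variance yield \code{NA} (an explicit undefined marker, never
#' silently zero).
#'
#' @param filter a \code{spatial_filter}.
#' @param band_data a \code{band_power} dataset.
#' @param response per-trial behavioral vector.
#' @param source label stored with the trace (e.g., "training" or "test").
#' @return A \code{correlation_trace}: per-latency r in [-1, 1] (or NA),
#'   latency axis, source label.
#' @export
cct <- function(filter, band_data, response, source = "training") {
  comp <- scc(filter, band_data)
  z <- comp$values                                   # N x T
  if (length(response) != nrow(z))
    stop("response length does not match trial count", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("undefined correlation: response has zero variance", call. = FALSE)
  sds <- apply(z, 2L, stats::sd)
  vals <- rep(NA_real_, ncol(z))
  ok <- sds > 0
  if (any(ok))
    vals[ok] <- as.numeric(stats::cor(z[, ok, drop = FALSE], response))
  structure(list(values = vals, times = band_data$times,
                 source = source, filter = filter),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  pk <- which.max(abs(x$values))
  cat("<correlation_trace> (", x$source, ") ", length(x$values),
      " latencies; peak |r| = ", round(abs(x$values[pk]), 4), " at ",
      round(x$times[pk], 1), " ms\n", sep = "")
  invisible(x)
}

#' Forward model (activation pattern) of a correlated component
#'
#' Recovers the per-channel coupling \code{a = X z / (z'z)} of the component
#' at a given latency: unlike the filter weights themselves, \code{a} is
#' interpretable as a scalp topography. Both channels and component are
#' centered across trials before the projection. By default the model is
#' evaluated at every sample of the filter's training window and the
#' per-sample vectors are averaged; the per-sample vectors are also returned.
#' The forward model is invariant to positive rescaling of the filter in the
#' sense that \code{a z'} is unchanged (z -> k z implies a -> a / k).
#'
#' @param band_data a \code{band_power} dataset.
#' @param component a \code{component_ts} from \code{\link{scc}}.
#' @param latency single latency in ms, vector of latencies, or \code{NULL}
#'   (default) for the filter's training window.
#' @return A \code{forward_model}: \code{coupling} (length-D average),
#'   \code{per_sample} (D x n_latency matrix), evaluated latencies.
#' @export
forward_model <- function(band_data, component, latency = NULL) {
  stopifnot(inherits(band_data, "band_power"),
            inherits(component, "component_ts"))
  if (is.null(latency)) {
    f <- component$filter
    idx <- window_samples(band_data$times, f$tau,
                          1000 * f$delta_t / band_data$sfreq)
  } else {
    idx <- vapply(latency, function(l) which.min(abs(band_data$times - l)), 0L)
  }
  d <- dim(band_data$values)
  per <- matrix(NA_real_, d[1], length(idx))
  for (j in seq_along(idx)) {
    t_ <- idx[j]
    X <- band_data$values[, t_, , drop = FALSE]
    dim(X) <- c(d[1], d[3])
    z <- component$values[, t_]
    Xc <- X - rowMeans(X)
    zc <- z - mean(z)
    denom <- sum(zc^2)
    if (denom == 0)
      stop("component has zero norm at latency ",
           round(band_data$times[t_], 1), " ms", call. = FALSE)
    per[, j] <- as.numeric(Xc %*% zc) / denom
  }
  structure(list(coupling = rowMeans(per), per_sample = per,
                 latency_ms = band_data$times[idx],
                 channels = band_data$channels),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model> ", length(x$coupling), " channels, evaluated at ",
      length(x$latency_ms), " latenc",
      if (length(x$latency_ms) == 1) "y" else "ies", " (",
      paste(round(range(x$latency_ms), 1), collapse = "-"), " ms)\n",
      sep = "")
  invisible(x)
}

#' Correlated component map (CCM)
#'
#' Trials x latency image of component amplitude with the trial axis sorted
#' by ascending response value (fast trials first), ties broken by original
#' trial index. The permutation is retained so the original order can be
#' restored.
#'
#' @param component a \code{component_ts}.
#' @param response per-trial behavioral vector.
#' @return A \code{component_map}: sorted \code{values}, \code{order} (the
#'   permutation applied), sorted \code{response}, latency axis.
#' @export
component_map <- function(component, response) {
  stopifnot(inherits(component, "component_ts"))
  z <- component$values
  if (length(response) != nrow(z))
    stop("response length does not match trial count", call. = FALSE)
  ord <- order(response, seq_along(response))
  structure(list(values = z[ord, , drop = FALSE], order = ord,
                 response = response[ord], times = component$times,
                 filter = component$filter),
            class = "component_map")
}

#' Plot a correlated component map
#'
#' Heatmap of sorted single-trial component amplitude (fast trials in the top
#' rows), with the filter's training window marked by vertical lines.
#'
#' @param x a \code{component_map}.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.component_map <- function(x, ...) {
  n <- nrow(x$values)
  graphics::image(x = x$times, y = seq_len(n),
                  z = t(x$values[rev(seq_len(n)), , drop = FALSE]),
                  xlab = "latency (ms)", ylab = "trial (sorted by response)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  f <- x$filter
  if (!is.null(f) && is.finite(f$tau)) {
    dt_ms <- stats::median(diff(x$times)) * f$delta_t
    graphics::abline(v = c(f$tau, f$tau + dt_ms), lty = 2)
  }
  invisible(x)
}

#' Write a correlation trace or forward model as TSV
#'
#' @param x a \code{correlation_trace} or \code{forward_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_tsv <- function(x, path) {
  stopifnot(inherits(x, "correlation_trace"))
  utils::write.table(data.frame(latency_ms = x$times, r = x$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
write_forward_tsv <- function(x, path) {
  stopifnot(inherits(x, "forward_model"))
  utils::write.table(data.frame(channel = x$channels, coupling = x$coupling),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
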