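#' Build the temporally augmented design for one analysis window
#'
#' Concatenates the per-sample trial matrices of every latency sample inside
#' the window, giving a channels x (N * delta_t) design whose response vector
#' replicates the per-trial behavioral values once per window sample (the
#' block structure makes all window samples contribute jointly to the fitted
#' correlation). Channels and response are mean-centered before the
#' covariance is estimated; the covariance is normalized by the augmented
#' column count N * delta_t.
#'
#' @param band_data a \code{band_power} dataset.
#' @param window length-2 numeric \code{c(start_ms, duration_ms)} (half-open,
#'   like epochs), or an integer vector of latency sample indices.
#' @param response numeric per-trial behavioral vector (length = trial
#'   count), e.g., reaction times in ms.
#' @return An \code{augmented_design}: \code{values} (D x N*delta_t, centered),
#'   \code{response} (centered, length N*delta_t), \code{covariance} (D x D),
#'   \code{delta_t}, channel means and response mean, window metadata.
#' @export
build_augmented <- function(band_data, window, response) {
  stopifnot(inherits(band_data, "band_power"))
  d <- dim(band_data$values)
  N <- d[3]
  if (length(response) != N)
    stop("response length (", length(response),
         ") does not match trial count (", N, ")", call. = FALSE)
  assert_finite(response, "response")
  if (N < 2) stop("need at least 2 trials", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("response has zero variance: correlation undefined", call. = FALSE)
  if (is.numeric(window) && length(window) == 2 && !is.integer(window)) {
    idx <- window_samples(band_data$times, window[1], window[2])
    win_ms <- window
  } else {
    idx <- as.integer(window)
    stopifnot(all(idx >= 1), all(idx <= d[2]))
    win_ms <- c(band_data$times[idx[1]], NA)
  }
  dt <- length(idx)
  if (dt < 1) stop("window must contain at least one sample", call. = FALSE)
  # column blocks: all trials at sample idx[1], then idx[2], ...
  X <- matrix(aperm(band_data$values[, idx, , drop = FALSE], c(1, 3, 2)),
              nrow = d[1])
  assert_finite(X, "design")
  mu <- rowMeans(X)
  Xc <- X - mu
  y <- rep(as.numeric(response), times = dt)
  ybar <- mean(y)
  yc <- y - ybar
  R <- tcrossprod(Xc) / ncol(Xc)
  structure(list(values = Xc, response = yc, covariance = R,
                 delta_t = dt, n_trials = N,
                 channel_means = mu, response_mean = ybar,
                 channels = band_data$channels,
                 window_ms = win_ms, sample_idx = idx,
                 band = band_data$band_name),
            class = "augmented_design")
}

#' @export
print.augmented_design <- function(x, ...) {
  cat("<augmented_design> ", nrow(x$values), " channels x ", x$n_trials,
      " trials x delta_t=", x$delta_t, "; window start ", x$window_ms[1],
      " ms\n", sep = "")
  invisible(x)
}

#' Correlation objective of a spatial filter on a design
#'
#' Pearson correlation between the projected design \code{X'w} and the
#' (replicated) response — the quantity the closed-form solver maximizes.
#' Undefined correlations (zero projection variance) are an error, never
#' silently zero.
#'
#' @param weights length-D numeric filter.
#' @param design an \code{augmented_design}.
#' @return The Pearson correlation, in [-1, 1].
#' @export
correlation_objective <- function(weights, design) {
  stopifnot(inherits(design, "augmented_design"),
            length(weights) == nrow(design$values))
  proj <- as.numeric(crossprod(design$values, weights))
  if (stats::sd(proj) == 0)
    stop("undefined correlation: projected component has zero variance",
         call. = FALSE)
  if (stats::sd(design$response) == 0)
    stop("undefined correlation: response has zero variance", call. = FALSE)
  stats::cor(proj, design$response)
}

#' Closed-form regularized spatial filter
#'
#' Solves \code{(R_xx + lambda * I) w = X y} for the filter maximizing the
#' Pearson correlation between the projected component and the response,
#' where \code{R_xx} is the (augmented, centered) channel covariance. The
#' system is solved by a symmetric positive-definite factorization, never an
#' explicit inverse; a singular system at \code{lambda = 0} falls back to the
#' Moore-Penrose pseudoinverse with a warning. The returned weights are
#' scaled to unit L2 norm (correlation is scale-free); the training objective
#' is recorded as \code{achieved_r} and is nonnegative by construction.
#'
#' @param design an \code{augmented_design}.
#' @param lambda nonnegative ridge strength. Larger values shrink the
#'   solution toward the cross-covariance direction (spatially smoother
#'   filters).
#' @return A \code{spatial_filter}: \code{weights}, \code{lambda},
#'   \code{tau} (window start, ms), \code{band}, \code{channels},
#'   \code{achieved_r}.
#' @export
solve_weights <- function(design, lambda = 0) {
  stopifnot(inherits(design, "augmented_design"), lambda >= 0)
  D <- nrow(design$values)
  b <- as.numeric(design$values %*% design$response) / ncol(design$values)
  A <- design$covariance + diag(lambda, D)
  w <- tryCatch({
    U <- chol(A)
    # a near-zero pivot signals (numerical) rank deficiency even when the
    # factorization formally succeeds
    if (min(diag(U))^2 < 1e-12 * mean(diag(A)))
      stop("rank deficient")
    backsolve(U, backsolve(U, b, transpose = TRUE))
  }, error = function(e) {
    warning("covariance + lambda*I is singular; using pseudoinverse",
            call. = FALSE)
    as.numeric(MASS::ginv(A) %*% b)
  })
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  r <- correlation_objective(w, design)
  structure(list(weights = as.numeric(w), lambda = lambda,
                 tau = design$window_ms[1], band = design$band,
                 channels = design$channels, delta_t = design$delta_t,
                 achieved_r = r),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat("<spatial_filter> band '", x$band, "', tau = ", x$tau,
      " ms, lambda = ", signif(x$lambda, 4), ", training r = ",
      round(x$achieved_r, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a spatial filter to JSON
#'
#' Deterministic round-trip of the fitted filter (weights, lambda, tau, band,
#' channel names, achieved r).
#'
#' @param filter a \code{spatial_filter}.
#' @param path output path.
#' @return \code{path} invisibly (\code{write_filter_json});
#'   a \code{spatial_filter} (\code{read_filter_json}).
#' @export
write_filter_json <- function(filter, path) {
  stopifnot(inherits(filter, "spatial_filter"))
  obj <- filter[c("weights", "lambda", "tau", "band", "channels",
                  "delta_t", "achieved_r")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_filter_json
#' @export
read_filter_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(obj$weights), lambda = obj$lambda,
                 tau = obj$tau, band = obj$band,
                 channels = as.character(obj$channels),
                 delta_t = obj$delta_t, achieved_r = obj$achieved_r),
            class = "spatial_filter")
}
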