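#' Sliding window grid
#'
#' All maximal windows of the stated duration and step that fit inside the
#' epoch range; a 0-1000 ms range with 60 ms windows in 10 ms increments
#' yields 95 windows (starts 0, 10, ..., 940).
#'
#' @param epoch_ms length-2 numeric epoch range in ms.
#' @param duration window duration in ms (> 0).
#' @param step window start increment in ms (> 0).
#' @return Data frame (class \code{window_grid}) with columns \code{start}
#'   and \code{end} (ms).
#' @export
window_grid <- function(epoch_ms = c(0, 1000), duration = 60, step = 10) {
  stopifnot(length(epoch_ms) == 2, duration > 0, step > 0)
  if (epoch_ms[1] + duration > epoch_ms[2] + 1e-9)
    stop("window duration exceeds the epoch range", call. = FALSE)
  starts <- seq(epoch_ms[1], epoch_ms[2] - duration, by = step)
  structure(data.frame(start = starts, end = starts + duration),
            class = c("window_grid", "data.frame"))
}

#' Subset trials of a band-power dataset
#'
#' @param band_data a \code{band_power}.
#' @param idx trial indices to keep.
#' @return The subsetted \code{band_power}.
#' @export
subset_trials <- function(band_data, idx) {
  stopifnot(inherits(band_data, "band_power"))
  out <- band_data
  out$values <- band_data$values[, , idx, drop = FALSE]
  out$trials <- band_data$trials[idx, , drop = FALSE]
  out
}

#' Random train/test split of trials
#'
#' Disjoint partition of trials, reproducible under \code{seed}.
#'
#' @param band_data a \code{band_power}.
#' @param response per-trial behavioral vector.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed RNG seed (the caller's RNG stream is left untouched).
#' @return List with \code{train}, \code{test} (\code{band_power}),
#'   \code{train_response}, \code{test_response}, and the index vectors
#'   \code{train_idx}, \code{test_idx}.
#' @export
split_train_test <- function(band_data, response, fraction = 0.8,
                             seed = NULL) {
  stopifnot(inherits(band_data, "band_power"),
            fraction > 0, fraction < 1)
  N <- dim(band_data$values)[3]
  if (length(response) != N)
    stop("response length does not match trial count", call. = FALSE)
  n_train <- round(fraction * N)
  if (n_train < 2 || N - n_train < 2)
    stop("too few trials for both a training and a test split", call. = FALSE)
  perm <- with_rng_seed(seed, sample.int(N))
  tr <- sort(perm[seq_len(n_train)])
  te <- sort(perm[(n_train + 1):N])
  list(train = subset_trials(band_data, tr),
       test = subset_trials(band_data, te),
       train_response = response[tr], test_response = response[te],
       train_idx = tr, test_idx = te)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up selection at level \code{q} over a vector of p-values.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return Logical significance mask (empty input gives an empty mask).
#' @export
fdr_select <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  out <- stats::p.adjust(p_values, method = "BH") <= q
  out[is.na(out)] <- FALSE
  out
}

# ---- internal cross-validation engine ------------------------------------
#
# Evaluates the held-out correlation of the closed-form filter for many
# response vectors at once (observed + permutations). The channel covariance
# and its Cholesky factors do not depend on the response, so all responses
# share one factorization per (fold, lambda); cross-covariances use the
# identity X_aug %*% rep(y, dt) = (sum over window samples of X) %*% y, which
# reduces every response evaluation to small matrix products.

make_folds <- function(N, k, seed = NULL) {
  stopifnot(k >= 2)
  if (N < 2 * k)
    stop("need at least 2 trials per fold (", N, " trials, ", k, " folds)",
         call. = FALSE)
  perm <- with_rng_seed(seed, sample.int(N))
  unname(split(perm, rep_len(seq_len(k), N)))
}

default_lambda_grid <- function(band_data, window) {
  d <- dim(band_data$values)
  idx <- if (is.numeric(window) && length(window) == 2 && !is.integer(window))
    window_samples(band_data$times, window[1], window[2]) else as.integer(window)
  xs <- matrix(band_data$values[, idx, , drop = FALSE], nrow = d[1])
  mean_eig <- mean(rowMeans(xs^2) - rowMeans(xs)^2)  # trace/D of covariance
  if (mean_eig <= 0) mean_eig <- 1
  mean_eig * 10^seq(-3, 1, by = 1)
}

ridge_solve_mat <- function(R, lambda, B) {
  A <- R + diag(lambda, nrow(R))
  tryCatch({
    U <- chol(A)
    backsolve(U, backsolve(U, B, transpose = TRUE))
  }, error = function(e) MASS::ginv(A) %*% B)
}

# Paired correlations: column c of Z (n x m) against column c of Y (n x m).
paired_cor <- function(Z, Y) {
  n <- nrow(Z)
  Yc <- Y - rep(colMeans(Y), each = n)
  paired_cor_pc(Z, Yc, colSums(Yc^2))
}

# fast path: Yc already column-centered, ycss = colSums(Yc^2); Z need not be
# centered (the cross term vanishes against a centered Yc)
paired_cor_pc <- function(Z, Yc, ycss) {
  n <- nrow(Z)
  num <- colSums(Z * Yc)
  zss <- colSums(Z^2) - colSums(Z)^2 / n
  zss[zss < 0] <- 0
  den <- sqrt(zss * ycss)
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

cv_engine <- function(x, Y, idx, lambda_grid, folds, reselect = TRUE) {
  d <- dim(x)
  D <- d[1]; N <- d[3]
  dt <- length(idx)
  m <- ncol(Y)
  k <- length(folds)
  nl <- length(lambda_grid)
  # per-sample channel slices and the window sum
  Xs <- lapply(idx, function(j) matrix(x[, j, , drop = FALSE], D, N))
  Xsum <- Reduce(`+`, Xs)
  # fold-level caches: any training set is a union of folds, so all second
  # moments and cross-products assemble from per-fold pieces
  S2f <- lapply(folds, function(f) {
    S <- matrix(0, D, D)
    for (Xj in Xs) S <- S + tcrossprod(Xj[, f, drop = FALSE])
    S
  })
  sumf <- lapply(folds, function(f) rowSums(Xsum[, f, drop = FALSE]))
  Gf <- lapply(folds, function(f)
    Xsum[, f, drop = FALSE] %*% Y[f, , drop = FALSE])              # D x m
  ysumf <- lapply(folds, function(f) colSums(Y[f, , drop = FALSE]))
  Qf <- lapply(folds, function(f)
    tcrossprod(Xsum[, f, drop = FALSE]))         # window-sum second moments
  nf <- lengths(folds)

  fold_proj <- function(J, te) {                 # J: training fold indices
    ntr <- sum(nf[J])
    M <- ntr * dt
    S2 <- Reduce(`+`, S2f[J])
    musum <- Reduce(`+`, sumf[J])
    mu <- musum / M
    R <- S2 / M - tcrossprod(mu)
    ybar <- Reduce(`+`, ysumf[J]) / ntr                            # length m
    # cross-covariance with both sides centered; the response centering term
    # couples through the training channel sums
    B <- (Reduce(`+`, Gf[J]) - outer(musum, ybar)) / M             # D x m
    Xte <- Xsum[, te, drop = FALSE] / dt - mu                      # D x nte
    # covariance of the window-averaged training data: used to scale each
    # component to unit *training* variance. Folds fit with different ridge
    # strengths project onto directions of very different data variance;
    # without a common scale, pooling held-out components across folds
    # corrupts the pooled correlation. Training-based scaling never touches
    # the held-out trials. (The training mean of the projection is exactly
    # zero by construction, so no location term is needed.)
    S_avg <- Reduce(`+`, Qf[J]) / (ntr * dt^2) - tcrossprod(mu)
    lapply(lambda_grid, function(l) {
      W <- ridge_solve_mat(R, l, B)
      s <- sqrt(pmax(colSums(W * (S_avg %*% W)), 0))
      s[s == 0] <- NA_real_
      crossprod(Xte, W) * rep(1 / s, each = length(te))            # nte x m
    })
  }

  zhat <- array(NA_real_, c(N, m, nl))
  for (i in seq_len(k)) {
    te <- folds[[i]]
    Z <- fold_proj(setdiff(seq_len(k), i), te)
    for (l in seq_len(nl)) zhat[te, , l] <- Z[[l]]
  }

  if (nl == 1L) {
    pick <- matrix(1L, k, m)
  } else if (!reselect) {
    stop("reselect = FALSE requires precomputed lambda choice")  # internal
  } else {
    # nested selection: within each outer-training set, leave one of the
    # remaining folds out in turn and pool its projections
    pick <- matrix(NA_integer_, k, m)
    for (i in seq_len(k)) {
      zin <- array(NA_real_, c(N, m, nl))
      for (j in seq_len(k)) {
        if (j == i) next
        te <- folds[[j]]
        Z <- fold_proj(setdiff(seq_len(k), c(i, j)), te)
        for (l in seq_len(nl)) zin[te, , l] <- Z[[l]]
      }
      inner_trials <- sort(unlist(folds[-i], use.names = FALSE))
      Yin <- Y[inner_trials, , drop = FALSE]
      Yin_c <- Yin - rep(colMeans(Yin), each = nrow(Yin))
      ycss <- colSums(Yin_c^2)
      r_in <- vapply(seq_len(nl), function(l) {
        paired_cor_pc(matrix(zin[inner_trials, , l], ncol = m), Yin_c, ycss)
      }, numeric(m))
      r_in <- matrix(r_in, nrow = m)
      r_in[is.na(r_in)] <- -Inf
      pick[i, ] <- max.col(r_in, ties.method = "first")
    }
  }

  # assemble pooled held-out projections at the per-fold chosen lambda
  zsel <- matrix(NA_real_, N, m)
  for (i in seq_len(k)) {
    te <- folds[[i]]
    for (l in unique(pick[i, ])) {
      cols <- which(pick[i, ] == l)
      zsel[te, cols] <- zhat[te, cols, l]
    }
  }
  dropped <- 0L
  for (i in seq_len(k)) {
    te <- folds[[i]]
    if (!all(is.finite(zsel[te, 1L]))) {
      zsel[te, ] <- NA_real_
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L)
    warning(dropped, " fold(s) skipped: degenerate held-out component variance",
            call. = FALSE)
  keep <- which(!is.na(zsel[, 1L]))
  if (length(keep) < 3L)
    stop("all cross-validation folds degenerate", call. = FALSE)
  r <- paired_cor(zsel[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  list(r = r, lambda_idx = pick, zhat = zsel)
}

# mode (most frequent value) of the per-fold lambda choices, observed column
modal_lambda <- function(lambda_grid, pick_col) {
  tab <- table(pick_col)
  lambda_grid[as.integer(names(tab)[which.max(tab)])]
}

#' Cross-validated correlation of the fitted component at one window
#'
#' K-fold cross-validation: on each fold, the filter is fit on the remaining
#' folds (with the ridge strength lambda chosen by nested selection on those
#' training folds only), held-out trials are projected at the window, the
#' per-trial component amplitude is averaged over the window samples, and the
#' pooled held-out (amplitude, response) pairs across folds give the reported
#' Pearson correlation.
#'
#' @param band_data a \code{band_power} training dataset.
#' @param response per-trial behavioral vector.
#' @param window \code{c(start_ms, duration_ms)} window.
#' @param lambda_grid ridge strengths to select among; default logarithmic,
#'   scaled by the mean covariance eigenvalue of the windowed data.
#' @param k_folds number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return List with \code{r_cv} (pooled held-out correlation),
#'   \code{lambda} (modal chosen strength), \code{lambda_folds} (per-fold
#'   choice), \code{folds}, \code{zhat} (pooled held-out amplitudes).
#' @export
cv_correlation <- function(band_data, response, window, lambda_grid = NULL,
                           k_folds = 5, seed = NULL) {
  stopifnot(inherits(band_data, "band_power"))
  N <- dim(band_data$values)[3]
  if (length(response) != N)
    stop("response length does not match trial count", call. = FALSE)
  idx <- window_samples(band_data$times, window[1], window[2])
  lambda_grid <- lambda_grid %||% default_lambda_grid(band_data, idx)
  folds <- make_folds(N, k_folds, seed)
  fit <- cv_engine(band_data$values, matrix(response, ncol = 1), idx,
                   lambda_grid, folds)
  list(r_cv = fit$r[1],
       lambda = modal_lambda(lambda_grid, fit$lambda_idx[, 1]),
       lambda_folds = lambda_grid[fit$lambda_idx[, 1]],
       folds = folds, zhat = fit$zhat[, 1])
}

#' Permutation null distribution of the cross-validated correlation
#'
#' Repeatedly shuffles the response across trials, reruns the full
#' cross-validation (by default including the nested lambda selection) and
#' records the held-out correlation. The p-value uses the add-one estimator
#' \code{(1 + #\{null >= observed\}) / (1 + n_perm)}, so it can never be
#' exactly zero.
#'
#' @inheritParams cv_correlation
#' @param n_perm number of permutations (default 1000).
#' @param reselect_lambda rerun the nested lambda selection for every
#'   permutation (default TRUE, conservative); when FALSE, permutations reuse
#'   the per-fold lambda chosen on the observed response.
#' @return A \code{null_distribution}: \code{values} (permuted r_cv),
#'   \code{observed}, \code{p_value}, \code{n_perm}, \code{seed},
#'   \code{lambda} (modal observed choice).
#' @export
permutation_null <- function(band_data, response, window, n_perm = 1000,
                             seed = NULL, k_folds = 5, lambda_grid = NULL,
                             reselect_lambda = TRUE) {
  stopifnot(n_perm >= 1)
  N <- dim(band_data$values)[3]
  if (length(response) != N)
    stop("response length does not match trial count", call. = FALSE)
  idx <- window_samples(band_data$times, window[1], window[2])
  lambda_grid <- lambda_grid %||% default_lambda_grid(band_data, idx)
  setup <- with_rng_seed(seed, {
    folds <- make_folds(N, k_folds)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(N), integer(N))
    list(folds = folds, perms = perms)
  })
  Y <- cbind(response, matrix(response[setup$perms], N, n_perm))
  fit <- run_engine_with_reselect(band_data$values, Y, idx, lambda_grid,
                                  setup$folds, reselect_lambda)
  obs <- fit$r[1]
  null <- fit$r[-1]
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + n_perm)
  structure(list(values = null, observed = obs, p_value = p,
                 n_perm = n_perm, seed = seed,
                 lambda = modal_lambda(lambda_grid, fit$lambda_idx[, 1])),
            class = "null_distribution")
}

# Run the engine; when reselect is FALSE, permutations reuse the per-fold
# lambda selected for the observed response (column 1).
run_engine_with_reselect <- function(x, Y, idx, lambda_grid, folds,
                                     reselect) {
  if (reselect || length(lambda_grid) == 1L)
    return(cv_engine(x, Y, idx, lambda_grid, folds))
  obs <- cv_engine(x, Y[, 1, drop = FALSE], idx, lambda_grid, folds)
  pick <- obs$lambda_idx[, 1]
  # evaluate all columns at the observed per-fold choice: run the engine per
  # distinct lambda and stitch folds together
  N <- nrow(Y); m <- ncol(Y); k <- length(folds)
  zsel <- matrix(NA_real_, N, m)
  for (l in unique(pick)) {
    fit_l <- cv_engine(x, Y, idx, lambda_grid[l], folds)
    for (i in which(pick == l)) zsel[folds[[i]], ] <- fit_l$zhat[folds[[i]], ]
  }
  keep <- which(!is.na(zsel[, 1L]))
  r <- paired_cor(zsel[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  list(r = r, lambda_idx = matrix(rep(pick, m), k, m), zhat = zsel)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_perm, " permutations; observed r_cv = ",
      round(x$observed, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Sliding-window scan with permutation significance and FDR control
#'
#' For every window of the grid, computes the cross-validated correlation and
#' its permutation p-value (fold assignment and the permutation set are fixed
#' across windows, so windows are comparable), applies Benjamini-Hochberg
#' selection across windows, and selects the optimal window offset tau among
#' the significant local maxima of the correlation profile. The whole scan is
#' reproducible bit-for-bit given (seed, config).
#'
#' @inheritParams cv_correlation
#' @param epoch_ms scan range in ms (default 0-1000, post-stimulus).
#' @param duration,step window grid parameters in ms (defaults 60 and 10).
#' @param n_perm permutations per window (default 1000).
#' @param q FDR level (default 0.05).
#' @param reselect_lambda see \code{\link{permutation_null}}.
#' @return A \code{scan_result}: \code{windows} data frame (start, end, r_cv,
#'   lambda, p, significant), \code{tau} (selected window row or NULL),
#'   \code{null} matrix of permuted r_cv (windows x n_perm), config and seed.
#' @export
scan_windows <- function(band_data, response, epoch_ms = c(0, 1000),
                         duration = 60, step = 10, lambda_grid = NULL,
                         k_folds = 5, n_perm = 1000, q = 0.05, seed = NULL,
                         reselect_lambda = TRUE) {
  stopifnot(inherits(band_data, "band_power"))
  N <- dim(band_data$values)[3]
  grid <- window_grid(epoch_ms, duration, step)
  setup <- with_rng_seed(seed, {
    folds <- make_folds(N, k_folds)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(N), integer(N))
    list(folds = folds, perms = perms)
  })
  Y <- cbind(response, matrix(response[setup$perms], N, n_perm))
  nw <- nrow(grid)
  r_cv <- numeric(nw); lambda <- numeric(nw); p <- numeric(nw)
  null <- matrix(NA_real_, nw, n_perm)
  for (wi in seq_len(nw)) {
    idx <- window_samples(band_data$times, grid$start[wi], duration)
    lg <- lambda_grid %||% default_lambda_grid(band_data, idx)
    fit <- run_engine_with_reselect(band_data$values, Y, idx, lg,
                                    setup$folds, reselect_lambda)
    r_cv[wi] <- fit$r[1]
    null[wi, ] <- fit$r[-1]
    lambda[wi] <- modal_lambda(lg, fit$lambda_idx[, 1])
    p[wi] <- (1 + sum(fit$r[-1] >= fit$r[1], na.rm = TRUE)) / (1 + n_perm)
  }
  windows <- data.frame(start = grid$start, end = grid$end, r_cv = r_cv,
                        lambda = lambda, p = p,
                        significant = fdr_select(p, q))
  out <- structure(list(windows = windows, null = null,
                        config = list(epoch_ms = epoch_ms,
                                      duration = duration, step = step,
                                      k_folds = k_folds, n_perm = n_perm,
                                      q = q,
                                      reselect_lambda = reselect_lambda),
                        seed = seed, tau = NULL),
                   class = "scan_result")
  out$tau <- select_tau(out)
  out
}

#' @export
print.scan_result <- function(x, ...) {
  w <- x$windows
  cat("<scan_result> ", nrow(w), " windows of ", x$config$duration,
      " ms (step ", x$config$step, " ms); ", sum(w$significant),
      " FDR-significant\n", sep = "")
  if (!is.null(x$tau))
    cat("  tau = [", x$tau$start, ", ", x$tau$end, ") ms, r_cv = ",
        round(x$tau$r_cv, 4), ", p = ", signif(x$tau$p, 3), "\n", sep = "")
  else cat("  no significant window\n")
  invisible(x)
}

# earliest index of each strict local maximum (plateaus count once, at their
# earliest window)
local_max_idx <- function(r) {
  n <- length(r)
  r[is.na(r)] <- -Inf
  if (n == 1L) return(if (is.finite(r[1])) 1L else integer(0))
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && r[j + 1L] == r[i]) j <- j + 1L
    left_ok <- i == 1L || r[i - 1L] < r[i]
    right_ok <- j == n || r[j + 1L] < r[i]
    if (left_ok && right_ok && is.finite(r[i])) out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' Select the optimal window offset tau from a scan
#'
#' Among the FDR-significant windows, returns the one whose cross-validated
#' correlation is the global maximum among local maxima of the correlation
#' profile over the window-start grid (plateau ties broken toward the
#' earliest window). Returns \code{NULL} when no window qualifies — absence
#' is a valid outcome.
#'
#' @param scan a \code{scan_result}, or a data frame with columns
#'   \code{start}, \code{end}, \code{r_cv}, \code{significant}.
#' @return A one-row list (start, end, r_cv, p if present) or \code{NULL}.
#' @export
select_tau <- function(scan) {
  w <- if (inherits(scan, "scan_result")) scan$windows else scan
  stopifnot(all(c("start", "end", "r_cv", "significant") %in% names(w)))
  cand <- intersect(local_max_idx(w$r_cv), which(w$significant))
  if (length(cand) == 0) return(NULL)
  best <- cand[which.max(w$r_cv[cand])]
  as.list(w[best, , drop = FALSE])
}

#' Write scan results as TSV plus a JSON summary
#'
#' @param scan a \code{scan_result}.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_scan_result <- function(scan, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (!is.null(tsv_path))
    utils::write.table(scan$windows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(tau = scan$tau, seed = scan$seed, config = scan$config,
                    config_hash = substr(paste(
                      unlist(scan$config), collapse = "|"), 1, 200))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(c(tsv_path, json_path))
}
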