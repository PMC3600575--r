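test_that("temporal augmentation replicates trials and the response per window sample", {
  bp <- tiny_band(D = 2, T_ = 10, N = 4, sfreq = 100, seed = 31)
  y <- c(3, 1, 4, 2)
  des <- build_augmented(bp, c(0, 30), y)          # 3 samples at 100 Hz
  expect_equal(des$delta_t, 3)
  expect_equal(length(des$response), 12)
  counts <- table(round(des$response + des$response_mean, 10))
  expect_true(all(counts == 3))
  # delta_t = 1 reduces to the (centered) single-latency trial matrix
  des1 <- build_augmented(bp, c(40, 10), y)
  expect_equal(des1$delta_t, 1)
  X <- bp$values[, 5, ]
  expect_equal(des1$values, X - rowMeans(X), tolerance = 1e-12)
  expect_error(build_augmented(bp, c(200, 30), y), "no latency")
  expect_error(build_augmented(bp, c(0, 30), y[1:3]), "does not match")
})

test_that("augmented covariance equals the brute-force average of per-sample outer products", {
  bp <- tiny_band(D = 4, T_ = 12, N = 20, sfreq = 100, seed = 32)
  y <- rnorm(20)
  des <- build_augmented(bp, c(20, 40), y)         # 4 samples
  idx <- 3:6
  Xaug <- do.call(cbind, lapply(idx, function(j) bp$values[, j, ]))
  Xc <- Xaug - rowMeans(Xaug)
  brute <- matrix(0, 4, 4)
  for (b in seq_along(idx)) {
    blk <- Xc[, (b - 1) * 20 + 1:20]
    brute <- brute + tcrossprod(blk) / 20
  }
  brute <- brute / length(idx)
  expect_lt(max(abs(des$covariance - brute)), 1e-10)
})

test_that("a single channel equal to the response is recovered with perfect correlation", {
  y <- rnorm(30)
  vals <- array(rep(y, each = 5), c(1, 5, 30))
  bp <- tiny_band(values = vals, sfreq = 100)
  des <- build_augmented(bp, c(0, 10), y)
  flt <- solve_weights(des, 0)
  expect_equal(flt$achieved_r, 1, tolerance = 1e-10)
})

test_that("at lambda = 0 the closed form attains the OLS multiple correlation", {
  set.seed(33)
  for (rep in 1:5) {
    D <- 3; N <- 60
    vals <- array(rnorm(D * 2 * N), c(D, 2, N))
    bp <- tiny_band(values = vals, sfreq = 100)
    y <- rnorm(N)
    des <- build_augmented(bp, c(0, 10), y)
    flt <- solve_weights(des, 0)
    fit <- stats::lm(y ~ t(vals[, 1, ]))
    expect_equal(flt$achieved_r, sqrt(summary(fit)$r.squared),
                 tolerance = 1e-8)
  }
})

test_that("large lambda shrinks the weight direction to the cross-covariance", {
  bp <- tiny_band(D = 5, T_ = 6, N = 80, sfreq = 100, seed = 34)
  y <- rnorm(80)
  des <- build_augmented(bp, c(0, 20), y)
  lam <- 1e6 * max(eigen(des$covariance, only.values = TRUE)$values)
  flt <- solve_weights(des, lam)
  b <- as.numeric(des$values %*% des$response)
  cs <- sum(flt$weights * b) / sqrt(sum(flt$weights^2) * sum(b^2))
  expect_gt(cs, 0.999)
})

test_that("the objective is scale-invariant and rejects degenerate projections", {
  bp <- tiny_band(D = 3, T_ = 6, N = 30, sfreq = 100, seed = 35)
  y <- rnorm(30)
  des <- build_augmented(bp, c(0, 20), y)
  w <- c(0.3, -1, 2)
  expect_equal(correlation_objective(w, des),
               correlation_objective(5 * w, des), tolerance = 1e-12)
  # filter orthogonal to every column: duplicate-channel dataset, w = (1,-1)
  one <- tiny_band(D = 1, T_ = 6, N = 30, sfreq = 100, seed = 36)
  dup <- one
  dup$values <- array(rep(one$values, each = 2), c(2, 6, 30))
  dup$channels <- c("a", "b")
  desd <- build_augmented(dup, c(0, 20), y)
  expect_error(correlation_objective(c(1, -1), desd), "zero variance")
  expect_error(build_augmented(bp, c(0, 20), rep(2, 30)), "zero variance")
})

test_that("the closed form beats 1000 random directions", {
  set.seed(37)
  bp <- tiny_band(D = 5, T_ = 4, N = 100, sfreq = 100, seed = 38)
  y <- rnorm(100)
  des <- build_augmented(bp, c(0, 20), y)
  flt <- solve_weights(des, 0)
  Wr <- matrix(rnorm(5 * 1000), 5)
  rs <- apply(Wr, 2, correlation_objective, design = des)
  expect_true(all(flt$achieved_r >= rs))
})

test_that("training correlation is non-increasing in lambda and nonnegative", {
  bp <- tiny_band(D = 6, T_ = 5, N = 50, sfreq = 100, seed = 39)
  y <- rnorm(50)
  des <- build_augmented(bp, c(0, 30), y)
  lams <- c(0, 10^seq(-4, 2, length.out = 12)) * mean(diag(des$covariance))
  rs <- vapply(lams, function(l) solve_weights(des, l)$achieved_r, 0)
  expect_true(all(diff(rs) <= 1e-10))
  expect_true(all(rs >= 0))
})

test_that("negating the response flips the weights but not the achieved correlation", {
  bp <- tiny_band(D = 4, T_ = 5, N = 40, sfreq = 100, seed = 40)
  y <- rnorm(40)
  des <- build_augmented(bp, c(0, 20), y)
  desn <- build_augmented(bp, c(0, 20), -y)
  f1 <- solve_weights(des, 0.1)
  f2 <- solve_weights(desn, 0.1)
  expect_equal(f1$weights, -f2$weights, tolerance = 1e-10)
  expect_equal(f1$achieved_r, f2$achieved_r, tolerance = 1e-12)
})

test_that("the solution is equivariant under invertible channel transforms at lambda 0", {
  set.seed(41)
  bp <- tiny_band(D = 3, T_ = 4, N = 80, sfreq = 100, seed = 42)
  y <- rnorm(80)
  des <- build_augmented(bp, c(0, 10), y)
  f0 <- solve_weights(des, 0)
  A <- matrix(rnorm(9), 3) + diag(3)
  tb <- bp
  for (t_ in 1:4) tb$values[, t_, ] <- A %*% bp$values[, t_, ]
  desA <- build_augmented(tb, c(0, 10), y)
  fA <- solve_weights(desA, 0)
  expect_equal(fA$achieved_r, f0$achieved_r, tolerance = 1e-8)
  mapped <- solve(t(A), f0$weights)
  cs <- abs(sum(mapped * fA$weights)) /
    sqrt(sum(mapped^2) * sum(fA$weights^2))
  expect_equal(cs, 1, tolerance = 1e-8)
})

test_that("no numerical maximizer beats the closed form at lambda 0", {
  set.seed(43)
  for (rep in 1:3) {
    bp <- tiny_band(D = 3, T_ = 3, N = 50, sfreq = 100,
                    seed = 43 + rep)
    y <- rnorm(50)
    des <- build_augmented(bp, c(0, 10), y)
    f0 <- solve_weights(des, 0)
    best <- -Inf
    for (s in 1:5) {
      res <- stats::optim(rnorm(3), function(w) {
        if (sum(w^2) < 1e-12) return(1)
        -correlation_objective(w, des)
      }, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12))
      best <- max(best, -res$value)
    }
    expect_lt(best - f0$achieved_r, 1e-6)
  }
})

test_that("a singular system at lambda 0 falls back to the pseudoinverse with a warning", {
  one <- tiny_band(D = 1, T_ = 4, N = 30, sfreq = 100, seed = 45)
  dup <- one
  dup$values <- array(rep(one$values, each = 2), c(2, 4, 30))
  dup$channels <- c("a", "b")
  y <- rnorm(30)
  des <- build_augmented(dup, c(0, 20), y)
  expect_warning(flt <- solve_weights(des, 0), "pseudoinverse")
  expect_true(all(is.finite(flt$weights)))
  expect_gte(flt$achieved_r, 0)
})

test_that("spatial filters round-trip deterministically through JSON", {
  bp <- tiny_band(D = 4, T_ = 5, N = 40, sfreq = 100, seed = 46)
  y <- rnorm(40)
  flt <- solve_weights(build_augmented(bp, c(0, 20), y), 0.5)
  path <- tempfile(fileext = ".json")
  write_filter_json(flt, path)
  back <- read_filter_json(path)
  expect_equal(back$weights, flt$weights)
  expect_equal(back$lambda, flt$lambda)
  expect_equal(back$tau, flt$tau)
  expect_equal(back$channels, flt$channels)
  expect_equal(back$achieved_r, flt$achieved_r)
})
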