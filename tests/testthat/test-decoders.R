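test_that("lagged design matches a brute-force constructor", {
  ev <- rand_evoked(n = 3, ns = 2, Tn = c(6, 8, 5), pad = 6, onset = 4)
  for (lag in list(c(0, 0), c(10, 30), c(0, 50))) {
    ld <- lagged_design(ev, lag)
    expect_equal(ld$blocks, brute_lagged(ev, lag))
  }
  # degenerate window: design equals the responses flattened per frame
  ld0 <- lagged_design(ev, c(0, 0))
  expect_equal(ld0$blocks[[2]],
               t(ev$data[2, , ev$onset:(ev$onset + 7)]))
  # overview window at 100 Hz has 41 lag samples per sensor
  ev2 <- rand_evoked(n = 1, ns = 1, Tn = 5, pad = 45)
  expect_length(lagged_design(ev2, c(20, 420))$lags, 41L)
  expect_error(lagged_design(ev, c(30, 10)), "exceeds")
  expect_error(lagged_design(ev, c(-10, 10)), "non-negative")
})

test_that("dual and primal ridge agree to 1e-8 on random instances", {
  set.seed(11)
  for (dims in list(c(8, 5), c(5, 8), c(12, 12))) {
    X <- matrix(rnorm(prod(dims)), dims[1])
    Y <- matrix(rnorm(dims[1] * 2), dims[1])
    for (lam in c(1e-2, 1, 1e3)) {
      expect_lt(max(abs(ridge_dual(X, Y, lam) - ridge_primal(X, Y, lam))),
                1e-8)
    }
  }
})

test_that("convolution fit recovers a planted response function", {
  set.seed(21)
  ev <- rand_evoked(n = 6, ns = 3, Tn = rep(12, 6), pad = 8)
  design <- lagged_design(ev, c(0, 40))      # 5 lags x 3 sensors = 15 cols
  g0 <- rnorm(15)
  S <- lapply(design$blocks, function(X) drop(X %*% g0))
  fit <- fit_convolution(design, S, lambda = 1e-8)
  expect_equal(drop(fit$G), g0, tolerance = 1e-4)
  # near-zero training residual in the interpolating limit
  pred <- predict(fit, design)
  expect_lt(max(abs(unlist(pred) - unlist(S))), 1e-4)
})

test_that("efficient grouped LOO equals explicit refit-and-predict", {
  set.seed(31)
  ev <- rand_evoked(n = 5, ns = 2, Tn = rep(6, 5), pad = 6)
  design <- lagged_design(ev, c(0, 30))
  S <- lapply(design$blocks, function(X)
    rbind(drop(X %*% rnorm(8)) + rnorm(6, sd = 0.3),
          drop(X %*% rnorm(8)) + rnorm(6, sd = 0.3)))
  grid <- 10^(-2:3)
  ss <- cortrack:::conv_suffstats(design$blocks, S)
  eff <- cortrack:::conv_loo_grid(ss, design$blocks, S, grid)
  expl <- explicit_conv_loo(design, S, grid)
  expect_equal(eff, expl, tolerance = 1e-7)
})

test_that("static ridge LOO shortcut equals explicit refit", {
  set.seed(41)
  X <- matrix(rnorm(9 * 30), 9)
  Y <- X %*% matrix(rnorm(30 * 3), 30) + rnorm(27, sd = 0.5)
  grid <- 10^(-1:3)
  fit <- fit_ridge_static(X, Y, grid)
  expl <- matrix(0, length(grid), ncol(Y))
  for (gi in seq_along(grid)) {
    for (i in 1:9) {
      f <- fit_ridge_static(X[-i, ], Y[-i, ], lambda = grid[gi])
      expl[gi, ] <- expl[gi, ] + (Y[i, ] - drop(predict(f, X[i, , drop = FALSE])))^2
    }
  }
  expect_equal(fit$loo_errors, expl, tolerance = 1e-7)
  # dual weights equal the primal solution
  W <- ridge_primal(X, Y, 10)
  expect_lt(max(abs(fit_ridge_static(X, Y, lambda = 10)$W - W)), 1e-8)
})

test_that("static ridge predicts a linear target nearly perfectly", {
  set.seed(51)
  X <- matrix(rnorm(20 * 15), 20)
  B <- matrix(rnorm(15 * 2), 15)
  Y <- X %*% B
  fit <- fit_ridge_static(X[1:19, ], Y[1:19, ], lambda = 1e-8)
  expect_equal(drop(predict(fit, X[20, , drop = FALSE])), Y[20, ],
               tolerance = 1e-3)
})

test_that("channels are fitted independently: permuting channels permutes G", {
  set.seed(61)
  ev <- rand_evoked(n = 4, ns = 2, Tn = rep(8, 4), pad = 6)
  design <- lagged_design(ev, c(0, 30))
  S <- lapply(design$blocks, function(X) matrix(rnorm(3 * 8), 3))
  fit <- fit_convolution(design, S, lambda = 1)
  fit_perm <- fit_convolution(design, lapply(S, function(m) m[c(3, 1, 2), ]),
                              lambda = 1)
  expect_equal(fit_perm$G, fit$G[, c(3, 1, 2)])
})

test_that("convolution predictions are linear and layout-checked", {
  set.seed(71)
  ev <- rand_evoked(n = 3, ns = 2, Tn = rep(6, 3), pad = 6)
  design <- lagged_design(ev, c(0, 20))
  S <- lapply(design$blocks, function(X) drop(X %*% rnorm(6)))
  fit <- fit_convolution(design, S, lambda = 1)
  zero <- design
  zero$blocks <- lapply(zero$blocks, function(X) X * 0)
  expect_true(all(unlist(predict(fit, zero)) == 0))
  scaled <- design
  scaled$blocks <- lapply(scaled$blocks, function(X) 3 * X)
  expect_equal(lapply(predict(fit, scaled), unname),
               lapply(predict(fit, design), function(p) unname(3 * p)))
  bad <- lagged_design(ev, c(0, 30))
  expect_error(predict(fit, bad), "layout")
})

test_that("penalty grid validation and singular-system handling", {
  ev <- rand_evoked(n = 3, ns = 1, Tn = rep(4, 3), pad = 6)
  design <- lagged_design(ev, c(0, 10))
  S <- lapply(design$blocks, function(X) drop(X[, 1]))
  expect_error(fit_convolution(design, S, grid = c(1, 2)), "grid")
  expect_error(fit_convolution(design, S, grid = c(3, 2, 1)), "grid")
})

test_that("logistic phoneme decoders learn separable data and handle edge cases", {
  set.seed(81)
  X <- cbind(rnorm(200), rnorm(200))
  s <- X[, 1] + 0.5 * X[, 2]
  X <- X[abs(s) > 0.3, ]              # separable with a clear margin
  y <- ifelse(s[abs(s) > 0.3] > 0, 1, -1)
  Y <- cbind(a = y, b = rep(-1, length(y)))
  expect_warning(fit <- fit_logistic_phonemes(X, Y, lambda = 1e-4,
                                              max_epochs = 100),
                 "single-class")
  expect_equal(fit$skipped, "b")
  pr <- predict(fit, X)
  expect_equal(unname(ifelse(pr$prob[, "a"] > 0.5, 1, -1)), y)  # 100% training acc
  expect_true(all(is.na(pr$prob[, "b"])))
  # zero model predicts exactly 0.5 -> inactive (strict inequality)
  fit$models[["a"]]$w <- c(0, 0); fit$models[["a"]]$b <- 0
  pr0 <- predict(fit, X)
  expect_true(all(pr0$prob[, "a"] == 0.5))
  expect_true(all(pr0$active[, "a"] == -1))
  # flipping the coefficients flips activity wherever p != 0.5
  fit$models[["a"]]$w <- c(1, -2); fit$models[["a"]]$b <- 0.3
  a1 <- predict(fit, X)$active[, "a"]
  fit$models[["a"]]$w <- -c(1, -2); fit$models[["a"]]$b <- -0.3
  a2 <- predict(fit, X)$active[, "a"]
  expect_true(all(a1 == -a2))
})
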