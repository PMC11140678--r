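test_that("leave-two-out split enumeration", {
  expect_equal(ncol(l2o_splits(44)), 946L)
  expect_equal(ncol(l2o_splits(8)), 28L)
  expect_equal(ncol(l2o_splits(3)), 3L)
  expect_error(l2o_splits(2), "at least 3")
})

test_that("pair length equalization truncates to the shorter feature", {
  f1 <- matrix(rnorm(2 * 81), 2); f2 <- matrix(rnorm(2 * 92), 2)
  eq <- equalize_pair_lengths(f1, f2)
  expect_equal(ncol(eq$f1), 81L)
  expect_equal(ncol(eq$f2), 81L)
  expect_identical(eq$f1, f1)                   # leading frames untouched
  expect_identical(eq$f2, f2[, 1:81])
  same <- equalize_pair_lengths(f1, f1)
  expect_identical(same$f1, f1)
  expect_error(equalize_pair_lengths(f1, matrix(0, 2, 0)), "zero-length")
})

test_that("pairwise criterion scores identity, swap, and the worked example", {
  s1 <- c(1, 2, 3); s2 <- c(3, 1, 2)
  expect_equal(classify_pair(s1, s2, s1, s2)$correct, 1)
  expect_equal(classify_pair(s1, s2, s2, s1)$correct, 0)
  p1 <- c(1, 2, 2.5); p2 <- c(2.5, 1, 2)
  out <- classify_pair(s1, s2, p1, p2)
  # oracle: the four Pearson correlations computed directly
  expect_equal(unname(out$sim),
               c(cor(s1, p1), cor(s2, p2), cor(s1, p2), cor(s2, p1)))
  expect_equal(out$correct,
               as.numeric(cor(s1, p1) + cor(s2, p2) > cor(s1, p2) + cor(s2, p1)))
  # invariant to exchanging the two items together with their reconstructions
  swapped <- classify_pair(s2, s1, p2, p1)
  expect_equal(swapped$correct, out$correct)
  # identical reconstructions give an exact tie, scored 0.5
  expect_equal(classify_pair(s1, s2, p1, p1)$correct, 0.5)
  # zero-variance vectors yield similarity 0 with a warning
  expect_warning(z <- pearson_sim(c(1, 1, 1), s1), "zero-variance")
  expect_equal(z, 0)
})

test_that("noise-free decoding is perfect and degrades gracefully", {
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 8, n_sensors = 6,
                    seed = 3, deficit = 1, noise = 0)
  ev <- co$participants[[1]]$evoked
  r <- loo_reconstruction(ev, co$drive, lag_ms = c(0, 420),
                          standardize = FALSE)
  expect_true(all(r > 0.99))
  expect_true(all(r >= -1 & r <= 1))
  res <- decode_cv(ev, co$drive, lag_ms = c(0, 420), standardize = FALSE)
  expect_equal(res$accuracy, 100)
  expect_equal(res$n_pairs, 28L)
})

test_that("pure-noise responses decode at chance and reconstruct near zero", {
  set.seed(17)
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 12, n_sensors = 4, seed = 19)
  noise_ev <- co$participants[[1]]$evoked
  noise_ev$data <- array(rnorm(length(noise_ev$data)), dim(noise_ev$data))
  accs <- vapply(1:8, function(b)
    decode_cv(noise_ev, co$drive, lambda = 100,
              pairing = sample(12))$accuracy, numeric(1))
  expect_lt(abs(mean(accs) - 50), 8)
  # raw responses: full-set standardization couples the held-out epoch to
  # the training epochs, so the pure-noise check bypasses it
  r <- loo_reconstruction(noise_ev, co$drive, lambda = 100,
                          standardize = FALSE)
  expect_lt(abs(mean(r)), 0.2)
  # accuracy lives on the 100 / n_pairs grid (ties add halves)
  res <- decode_cv(noise_ev, co$drive, lambda = 100)
  expect_equal(((res$accuracy / 100) * 66) %% 0.5, 0, tolerance = 1e-9)
})

test_that("evoked SNR estimate behaves like a calibrated power ratio", {
  set.seed(23)
  # pure noise: identical statistics in baseline and stimulus window -> ~1
  ev0 <- evoked_set(array(rnorm(4 * 3 * 120), c(4, 3, 120)), onset = 40,
                    lengths = rep(70, 4))
  expect_equal(estimate_snr(ev0), 1, tolerance = 0.15)
  # injecting evoked signal raises the SNR; doubling raises it further
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 6, n_sensors = 4,
                    seed = 29, noise = 10)
  ev1 <- co$participants[[1]]$evoked
  s1 <- estimate_snr(ev1)
  ev2 <- ev1
  post <- ev1$onset:dim(ev1$data)[3]
  ev2$data[, , post] <- 2 * ev1$data[, , post]
  expect_gt(s1, 1)
  expect_gt(estimate_snr(ev2), s1)
  expect_true(is.finite(s1) && s1 > 0)
  # constant baseline -> zero baseline variance error
  ev3 <- ev1
  ev3$data[, , 1:(ev1$onset - 1)] <- 0
  expect_error(estimate_snr(ev3), "baseline variance")
})

test_that("leave-two-out and leave-one-out rank participants consistently", {
  co <- tiny_cohort(n_per_group = 17, n_stimuli = 10, n_sensors = 4,
                    seed = 31, noise = 60)
  acc <- vapply(co$participants, function(p)
    decode_cv(p$evoked, co$drive, lambda = 100)$accuracy, numeric(1))
  loo <- vapply(co$participants, function(p)
    mean(loo_reconstruction(p$evoked, co$drive, lambda = 100)), numeric(1))
  expect_gt(cor(acc, loo, method = "spearman"), 0.8)
})

test_that("static ridge decoding identifies semantic-style vectors", {
  set.seed(91)
  Y <- synth_semantic(10, n_features = 20, seed = 91)
  expect_identical(Y, synth_semantic(10, n_features = 20, seed = 91))
  W <- matrix(rnorm(20 * 3 * 30), 20)
  arr <- array(0, c(10, 3, 40))
  arr[, , 11:40] <- array(Y %*% W, c(10, 3, 30))
  arr <- arr + rnorm(length(arr), sd = 0.1)
  ev <- evoked_set(arr, onset = 11, lengths = rep(30, 10))
  res <- decode_cv(ev, Y, model = "ridge", window_ms = c(0, 290))
  expect_gt(res$accuracy, 90)
  # shuffled pairing destroys the mapping
  null_acc <- decode_cv(ev, Y, model = "ridge", window_ms = c(0, 290),
                        pairing = sample(10))$accuracy
  expect_lt(null_acc, res$accuracy)
})

test_that("phoneme logistic decoding beats chance on aligned synthetic data", {
  set.seed(93)
  n <- 6; Tn <- rep(30, n)
  labels <- c("a", "t", "s")
  mats <- lapply(1:n, function(i) {
    M <- matrix(-1, 3, 30, dimnames = list(labels, NULL))
    for (t in seq(1, 30, 3)) M[sample(3, 1), t:min(t + 2, 30)] <- 1
    for (t in 1:30) if (sum(M[, t] == 1) > 1) M[sample(which(M[, t] == 1), 1), t] <- -1
    M
  })
  # responses: each phoneme drives its own sensor at a 2-sample delay
  arr <- array(rnorm(n * 3 * 45, sd = 0.3), c(n, 3, 45))
  for (i in 1:n) for (k in 1:3)
    arr[i, k, ] <- arr[i, k, ] + c(rep(0, 2), pmax(mats[[i]][k, ], 0), rep(0, 13))
  ev <- evoked_set(arr, onset = 1, lengths = Tn)
  res <- decode_cv(ev, mats, model = "logistic", lag_ms = c(0, 40),
                   max_epochs = 60, seed = 3)
  expect_gt(res$accuracy, 60)
})
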