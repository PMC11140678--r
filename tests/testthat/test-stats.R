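test_that("permutation null is centered at chance with a sensible threshold", {
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 10, n_sensors = 4, seed = 37)
  ev <- co$participants[[1]]$evoked
  pt <- permutation_test(ev, co$drive, n_permutations = 100, seed = 5,
                         lambda = 100)
  expect_length(pt$null, 100L)
  expect_lt(abs(mean(pt$null) - 50), 5)
  expect_true(pt$threshold95 > 50 && pt$threshold95 <= 100)
  expect_true(pt$p >= 0 && pt$p <= 1)
  # strict-inequality counting and the optional add-one convention
  expect_equal(pt$p, mean(pt$null > pt$observed))
  pt1 <- permutation_test(ev, co$drive, n_permutations = 100, seed = 5,
                          lambda = 100, add_one = TRUE)
  expect_equal(pt1$p, (sum(pt1$null > pt1$observed) + 1) / 101)
  expect_error(permutation_test(ev, co$drive, n_permutations = 50), "100")
})

test_that("class-restricted permutations stay within stimulus class", {
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 8, n_sensors = 4, seed = 41)
  classes <- rep(c("word", "sound"), each = 4)
  # degenerate classes of size 1 make permutation the identity
  single <- permutation_test(co$participants[[1]]$evoked, co$drive,
                             n_permutations = 100, classes = 1:8,
                             lambda = 100, seed = 2)
  expect_true(all(single$null == single$observed))
  mixed <- permutation_test(co$participants[[1]]$evoked, co$drive,
                            n_permutations = 100, classes = classes,
                            lambda = 100, seed = 2)
  expect_gt(stats::sd(mixed$null), 0)
})

test_that("lag sweep returns one accuracy per 20 ms window and localizes peaks", {
  co <- tiny_cohort(n_per_group = 1, n_stimuli = 10, n_sensors = 6, seed = 43)
  # early-only participant: curve must peak near the 100 ms component
  rf <- response_function(6, seed = 44, early_gain = 1, late_gain = 0)
  ev <- simulate_evoked(co$drive, rf, noise_sd = 60, trial_count = 20,
                        seed = 45)
  sw <- lag_sweep(ev, co$drive, lambda = 100)
  expect_equal(nrow(sw$windows), 20L)
  expect_equal(sw$windows$start_ms, seq(20, 400, 20))
  peak <- sw$windows$start_ms[which.max(sw$accuracy)]
  expect_true(peak >= 60 && peak <= 140)
})

test_that("group comparison matches closed-form t and d and is BH-monotone", {
  g <- factor(rep(c("TD", "DLD"), each = 4), levels = c("TD", "DLD"))
  x <- c(68, 70, 66, 68, 64, 66, 62, 64)
  out <- group_compare(x, g)
  sp <- sqrt((3 * var(x[1:4]) + 3 * var(x[5:8])) / 6)
  expect_equal(out$d, (mean(x[1:4]) - mean(x[5:8])) / sp)
  expect_equal(out$t, (mean(x[1:4]) - mean(x[5:8])) / (sp * sqrt(1 / 2)))
  expect_equal(out$df, 6)
  # identical groups: t = 0, d = 0
  same <- group_compare(rep(x[1:4], 2), g)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  # zero variance in both groups -> missing statistics
  degen <- group_compare(rep(c(70, 60), each = 4), g)
  expect_true(is.na(degen$t))
  # BH adjustment preserves the ordering of raw p-values
  set.seed(3)
  acc <- matrix(rnorm(8 * 6), 8) + outer(rep(c(1, 0), each = 4), c(2, 0, 1, 0, 0, 3))
  tab <- group_compare(acc, g)
  expect_true(all(diff(tab$p_adj[order(tab$p)]) >= -1e-12))
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("cluster permutation mass, invariances, and empty-cluster case", {
  set.seed(7)
  g <- factor(rep(c("TD", "DLD"), each = 8), levels = c("TD", "DLD"))
  base <- matrix(rnorm(16 * 20, sd = 2), 16)
  # single strongly different lag -> cluster mass equals that lag's t
  curves <- base
  curves[1:8, 9] <- curves[1:8, 9] + 15
  ct <- cluster_permutation(curves, g, n_permutations = 500, seed = 1)
  k <- which(ct$clusters$start == 9)
  expect_length(k, 1L)
  expect_equal(ct$clusters$end[k], 9L)               # single-lag cluster
  expect_equal(ct$clusters$mass[k], ct$t[9])         # mass = that lag's t
  expect_equal(ct$mass, ct$t[9])                     # and it is the largest
  expect_equal(ct$direction, "TD > DLD")
  # adding a group-common constant leaves t and mass unchanged
  ct2 <- cluster_permutation(curves + 7, g, n_permutations = 500, seed = 1)
  expect_equal(ct2$t, ct$t)
  expect_equal(ct2$mass, ct$mass)
  # flat curves: no supra-threshold cluster, p = 1, empty cluster table
  flat <- matrix(rep(rnorm(16, sd = 1e-3), 20), 16) + 50
  thr_high <- cluster_permutation(flat * 0 + matrix(rnorm(320, sd = .1), 16), g,
                                  alpha_cluster = 1e-6,
                                  n_permutations = 500, seed = 2)
  expect_equal(nrow(thr_high$clusters), 0L)
  expect_equal(thr_high$p, 1)
  expect_error(cluster_permutation(curves, g, n_permutations = 100), "500")
})

test_that("cluster permutation p-values are valid under the null", {
  set.seed(9)
  g <- factor(rep(c("A", "B"), each = 6))
  ps <- vapply(1:40, function(b) {
    curves <- matrix(rnorm(12 * 20), 12)
    cluster_permutation(curves, g, n_permutations = 500, seed = b)$p
  }, numeric(1))
  # validity: P(p <= alpha) <= alpha + 1/n_perm (with Monte Carlo slack)
  expect_lte(mean(ps <= 0.05), 0.05 + 1 / 500 + 0.075)
  expect_lte(mean(ps <= 0.2), 0.2 + 1 / 500 + 0.1)
})
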