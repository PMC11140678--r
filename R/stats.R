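#' Label-permutation significance test for one participant
#'
#' Builds the null distribution of decoding accuracy by randomly permuting
#' the stimulus labels of the averaged evoked responses (within stimulus
#' class, when classes are given) and re-running the full leave-two-out
#' evaluation for each permutation. The p-value counts how often a
#' permutation result was better than the observed accuracy,
#' `p = N(null > observed) / N(permutations)`; the 95th percentile of the
#' null is the per-participant significance threshold at alpha 0.05.
#'
#' @inheritParams decode_cv
#' @param n_permutations number of label permutations (>= 100; the
#'   reference protocol uses 200 for convolution models and 1000 for
#'   regression models).
#' @param classes optional factor/vector of stimulus classes; labels are
#'   permuted only within a class.
#' @param lambda_mode `"observed"` (default) reuses the penalty selected
#'   on the observed pairing for every permutation; `"refit"` re-selects
#'   it per permutation.
#' @param add_one use the (count + 1) / (n + 1) convention instead of the
#'   plain count ratio (default FALSE).
#' @param seed seed for the permutations.
#' @return object of class `ct_perm`: `observed` accuracy, `null`
#'   accuracies, `p`, `threshold95`, `n_permutations`.
#' @export
permutation_test <- function(evoked, features,
                             model = c("convolution", "ridge", "logistic"),
                             lag_ms = c(20, 420), window_ms = c(0, 1000),
                             grid = 10^(-3:6), lambda = NULL,
                             n_permutations = 200L, classes = NULL,
                             lambda_mode = c("observed", "refit"),
                             add_one = FALSE, seed = 1L, ...) {
  model <- match.arg(model)
  lambda_mode <- match.arg(lambda_mode)
  if (n_permutations < 100L)
    stop("need at least 100 permutations", call. = FALSE)
  if (!inherits(evoked, "ct_evoked")) evoked <- evoked_set(evoked)
  n <- dim(evoked$data)[1L]
  if (is.null(classes)) classes <- rep(1L, n)
  classes <- as.factor(classes)
  permute_within <- function() {
    p <- seq_len(n)
    for (lv in levels(classes)) {
      idx <- which(classes == lv)
      if (length(idx) > 1L) p[idx] <- idx[sample.int(length(idx))]
    }
    p
  }
  if (model == "convolution") {
    prep <- conv_prepare(evoked, features, lag_ms, standardize = TRUE)
    lam <- lambda
    if (is.null(lam)) lam <- conv_select_lambda(prep, seq_len(n), grid)
    observed <- conv_cv(prep, seq_len(n), lam, grid = grid)$accuracy
    set.seed(seed)
    null <- vapply(seq_len(n_permutations), function(b) {
      pairing <- permute_within()
      lb <- if (lambda_mode == "refit")
        conv_select_lambda(prep, pairing, grid) else lam
      conv_cv(prep, pairing, lb, grid = grid)$accuracy
    }, numeric(1L))
  } else {
    observed <- decode_cv(evoked, features, model = model, lag_ms = lag_ms,
                          window_ms = window_ms, grid = grid,
                          lambda = lambda, ...)$accuracy
    set.seed(seed)
    null <- vapply(seq_len(n_permutations), function(b) {
      decode_cv(evoked, features, model = model, lag_ms = lag_ms,
                window_ms = window_ms, grid = grid, lambda = lambda,
                pairing = permute_within(), ...)$accuracy
    }, numeric(1L))
  }
  cnt <- sum(null > observed)
  p <- if (add_one) (cnt + 1) / (n_permutations + 1) else cnt / n_permutations
  structure(list(observed = observed, null = null, p = p,
                 threshold95 = unname(stats::quantile(null, 0.95)),
                 n_permutations = n_permutations, model = model,
                 add_one = add_one),
            class = "ct_perm")
}

#' @export
print.ct_perm <- function(x, ...) {
  cat(sprintf(paste0("Label-permutation test (%s model, %d permutations)\n",
                     "  observed %.1f%%, null mean %.1f%%, 95th pct %.1f%%, p = %.4g\n"),
              x$model, x$n_permutations, x$observed, mean(x$null),
              x$threshold95, x$p))
  invisible(x)
}

#' Lag-resolved decoding curve
#'
#' Repeats the leave-two-out convolution-model evaluation in
#' non-overlapping 20-ms-wide lag windows (20-40, 40-60, ..., 400-420 ms
#' by default), yielding one accuracy per window: for how long the sound
#' features at each time point remain represented in the responses.
#'
#' @inheritParams decode_cv
#' @param starts_ms window start lags in ms (default `seq(20, 400, 20)`).
#' @param width_ms window width in ms (default 20).
#' @return object of class `ct_lagsweep`: `windows` (data frame with
#'   start/end ms), `accuracy` (one per window), `lambda` (per window).
#' @export
lag_sweep <- function(evoked, features, starts_ms = seq(20, 400, by = 20),
                      width_ms = 20, grid = 10^(-3:6), lambda = NULL,
                      standardize = TRUE, pairing = NULL) {
  if (!inherits(evoked, "ct_evoked")) evoked <- evoked_set(evoked)
  n <- dim(evoked$data)[1L]
  if (is.null(pairing)) pairing <- seq_len(n)
  acc <- numeric(length(starts_ms))
  lam_used <- vector("list", length(starts_ms))
  for (w in seq_along(starts_ms)) {
    lag_ms <- c(starts_ms[w], starts_ms[w] + width_ms)
    prep <- conv_prepare(evoked, features, lag_ms, standardize)
    lam <- lambda
    if (is.null(lam)) lam <- conv_select_lambda(prep, pairing, grid)
    acc[w] <- conv_cv(prep, pairing, lam, grid = grid)$accuracy
    lam_used[[w]] <- lam
  }
  structure(list(windows = data.frame(start_ms = starts_ms,
                                      end_ms = starts_ms + width_ms),
                 accuracy = acc, lambda = lam_used),
            class = "ct_lagsweep")
}

#' @export
print.ct_lagsweep <- function(x, ...) {
  best <- which.max(x$accuracy)
  cat(sprintf(paste0("Lag sweep: %d windows (%g-%g ms), peak %.1f%% at ",
                     "%g-%g ms\n"),
              nrow(x$windows), min(x$windows$start_ms), max(x$windows$end_ms),
              x$accuracy[best], x$windows$start_ms[best], x$windows$end_ms[best]))
  invisible(x)
}

#' @export
plot.ct_lagsweep <- function(x, ..., ylim = NULL) {
  mid <- (x$windows$start_ms + x$windows$end_ms) / 2
  if (is.null(ylim)) ylim <- range(c(45, x$accuracy + 2))
  graphics::plot(mid, x$accuracy, type = "b", pch = 16,
                 xlab = "lag (ms)", ylab = "decoding accuracy (%)",
                 ylim = ylim, ...)
  graphics::abline(h = 50, lty = 3, col = "grey40")
  invisible(x)
}

#' Group comparison of decoding accuracies with FDR correction
#'
#' Independent-samples t tests per comparison (pooled-variance Student t
#' by default, Welch optional), Benjamini-Hochberg adjustment across
#' comparisons, and Cohen's d with the pooled standard deviation.
#'
#' @param acc numeric matrix (participants x comparisons) or vector (one
#'   comparison) of accuracies.
#' @param groups two-level factor over participants; the difference is
#'   `level1 - level2`.
#' @param var_equal pooled-variance t (TRUE, default) or Welch.
#' @param fdr_level FDR level used for the `significant` flag
#'   (default 0.05).
#' @return data.frame with means, `t`, `df`, `p`, `p_adj`, `d`,
#'   `significant`. Comparisons with zero variance in both groups get
#'   `NA` statistics.
#' @export
group_compare <- function(acc, groups, var_equal = TRUE, fdr_level = 0.05) {
  acc <- as.matrix(acc)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  i1 <- groups == levels(groups)[1L]; i2 <- groups == levels(groups)[2L]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("need at least 2 participants per group", call. = FALSE)
  n1 <- sum(i1); n2 <- sum(i2)
  out <- do.call(rbind, lapply(seq_len(ncol(acc)), function(k) {
    x1 <- acc[i1, k]; x2 <- acc[i2, k]
    v1 <- stats::var(x1); v2 <- stats::var(x2)
    if (v1 == 0 && v2 == 0)
      return(data.frame(comparison = k, mean1 = mean(x1), mean2 = mean(x2),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        d = NA_real_))
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      tv <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se2 <- v1 / n1 + v2 / n2
      tv <- (mean(x1) - mean(x2)) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    data.frame(comparison = k, mean1 = mean(x1), mean2 = mean(x2),
               t = tv, df = df, p = 2 * stats::pt(-abs(tv), df),
               d = if (sp > 0) (mean(x1) - mean(x2)) / sp else 0)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_level
  rownames(out) <- colnames(acc)
  out
}

# per-lag two-sample t statistics (pooled variance); NA -> 0
two_sample_t <- function(curves, i1, i2) {
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(curves[i1, , drop = FALSE])
  m2 <- colMeans(curves[i2, , drop = FALSE])
  v1 <- apply(curves[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(curves[i2, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tv[!is.finite(tv)] <- 0
  tv
}

# contiguous supra-threshold clusters; returns data.frame or NULL
find_clusters <- function(tv, thr, alternative) {
  sign_vec <- integer(length(tv))
  sign_vec[tv > thr] <- 1L
  if (alternative == "two.sided") sign_vec[tv < -thr] <- -1L
  if (all(sign_vec == 0L)) return(NULL)
  r <- rle(sign_vec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(q)
               sum(tv[starts[q]:ends[q]]), numeric(1L)),
             sign = r$values[keep])
}

#' Cluster-based permutation test over lag windows
#'
#' Tests for group differences in lag-resolved decoding curves while
#' exploiting the dependence of neighboring lags: per-lag
#' independent-samples t statistics are thresholded at the cluster-forming
#' alpha, contiguous supra-threshold lags form clusters whose mass is the
#' sum of their t statistics, and the largest observed cluster mass is
#' compared against a null built by randomly reassigning participants to
#' two groups of the original sizes (same largest-cluster rule), with
#' `p = N(permutation mass > observed mass) / N(permutations)`.
#'
#' @param curves participants x lags accuracy matrix (e.g. rows of
#'   [lag_sweep()] accuracies).
#' @param groups two-level factor; per-lag t is `level1 - level2`.
#' @param alpha_cluster cluster-forming alpha for the t threshold
#'   (default 0.05).
#' @param n_permutations group relabelings (>= 500; default 1000).
#' @param alternative `"two.sided"` (default) forms clusters from both
#'   directions and compares absolute masses; `"greater"` only
#'   `level1 > level2` clusters.
#' @param windows optional data frame of lag window start/end ms,
#'   attached to the result for reporting.
#' @param add_one optional (count + 1)/(n + 1) p-value convention.
#' @param seed permutation seed.
#' @return object of class `ct_cluster`: `t` (per lag), `threshold`,
#'   `clusters` (data frame, possibly empty), `mass` (largest observed,
#'   signed), `null` (permutation masses), `p`, `direction`.
#'   With no observed cluster, `p = 1` and `clusters` is empty.
#' @export
cluster_permutation <- function(curves, groups, alpha_cluster = 0.05,
                                n_permutations = 1000L,
                                alternative = c("two.sided", "greater"),
                                windows = NULL, add_one = FALSE, seed = 1L) {
  alternative <- match.arg(alternative)
  curves <- as.matrix(curves)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  if (n_permutations < 500L)
    stop("need at least 500 permutations", call. = FALSE)
  i1 <- groups == levels(groups)[1L]
  i2 <- !i1
  n <- nrow(curves)
  df <- n - 2L
  thr <- if (alternative == "two.sided")
    stats::qt(1 - alpha_cluster / 2, df) else stats::qt(1 - alpha_cluster, df)
  tv <- two_sample_t(curves, i1, i2)
  cl <- find_clusters(tv, thr, alternative)
  max_mass <- function(cldf) {
    if (is.null(cldf)) return(0)
    cldf$mass[which.max(abs(cldf$mass))]
  }
  obs <- max_mass(cl)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(b) {
    pi1 <- logical(n)
    pi1[sample.int(n, sum(i1))] <- TRUE
    abs(max_mass(find_clusters(two_sample_t(curves, pi1, !pi1), thr,
                               alternative)))
  }, numeric(1L))
  if (is.null(cl)) {
    p <- 1
  } else {
    cnt <- sum(null > abs(obs))
    p <- if (add_one) (cnt + 1) / (n_permutations + 1) else cnt / n_permutations
  }
  direction <- if (is.null(cl)) NA_character_
    else if (obs > 0) sprintf("%s > %s", levels(groups)[1L], levels(groups)[2L])
    else sprintf("%s > %s", levels(groups)[2L], levels(groups)[1L])
  structure(list(t = tv, threshold = thr,
                 clusters = if (is.null(cl))
                   data.frame(start = integer(0), end = integer(0),
                              mass = numeric(0), sign = integer(0)) else cl,
                 mass = obs, null = null, p = p, direction = direction,
                 windows = windows, alternative = alternative,
                 n_permutations = n_permutations, groups = levels(groups)),
            class = "ct_cluster")
}

#' @export
print.ct_cluster <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %d permutations)\n",
              x$alternative, x$n_permutations))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold cluster; p = 1\n")
  } else {
    k <- which.max(abs(x$clusters$mass))
    loc <- if (!is.null(x$windows))
      sprintf("%g-%g ms", x$windows$start_ms[x$clusters$start[k]],
              x$windows$end_ms[x$clusters$end[k]])
      else sprintf("lags %d-%d", x$clusters$start[k], x$clusters$end[k])
    cat(sprintf("  largest cluster %s (%s), mass %.2f, p = %.4g\n",
                loc, x$direction, x$mass, x$p))
  }
  invisible(x)
}
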