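#' All leave-two-out splits
#'
#' @param n_stimuli number of stimuli (>= 3).
#' @return 2 x C(n, 2) integer matrix; each column is an unordered test
#'   pair, the training set being the remainder. 44 stimuli give 946
#'   pairwise tests.
#' @export
l2o_splits <- function(n_stimuli) {
  if (n_stimuli < 3L) stop("need at least 3 stimuli", call. = FALSE)
  utils::combn(n_stimuli, 2L)
}

#' Equalize the lengths of a test pair
#'
#' Truncates both time-varying features to the length of the shorter one,
#' keeping leading frames (from sound onset), so that differing feature
#' lengths cannot drive the pairwise decision.
#'
#' @param f1,f2 channels x frames matrices or per-frame vectors.
#' @return list with both features truncated to the common length.
#' @export
equalize_pair_lengths <- function(f1, f2) {
  f1 <- as_channel_matrix(f1); f2 <- as_channel_matrix(f2)
  if (ncol(f1) == 0L || ncol(f2) == 0L)
    stop("zero-length feature", call. = FALSE)
  L <- min(ncol(f1), ncol(f2))
  list(f1 = f1[, seq_len(L), drop = FALSE], f2 = f2[, seq_len(L), drop = FALSE])
}

# Pearson correlation over flattened cells; 0 (with warning) if either
# side has zero variance. Hand-rolled to keep the cross-validation inner
# loop lean.
pearson_sim <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a - mean(a); b <- b - mean(b)
  da <- sqrt(sum(a * a)); db <- sqrt(sum(b * b))
  if (da == 0 || db == 0) {
    warning("zero-variance vector in similarity; returning 0")
    return(0)
  }
  sum(a * b) / (da * db)
}

#' Pairwise classification of a leave-two-out test
#'
#' The decoding of a test pair is correct when the summed similarity of
#' each reconstruction to its own original exceeds the swapped labeling:
#' `sim(s1, p1) + sim(s2, p2) > sim(s1, p2) + sim(s2, p1)`, with
#' `sim` the Pearson correlation over all (channel, frame) cells. Exact
#' equality is scored as a tie (0.5 correct).
#'
#' @param s1,s2 original features of the two test stimuli (lengths already
#'   equalized).
#' @param p1,p2 the corresponding reconstructions.
#' @return object of class `ct_pair`: `correct` (1, 0, or 0.5 for a tie)
#'   and the four similarities.
#' @export
classify_pair <- function(s1, s2, p1, p2) {
  s11 <- pearson_sim(s1, p1); s22 <- pearson_sim(s2, p2)
  s12 <- pearson_sim(s1, p2); s21 <- pearson_sim(s2, p1)
  d <- (s11 + s22) - (s12 + s21)
  correct <- if (d > 0) 1 else if (d < 0) 0 else 0.5
  structure(list(correct = correct, sim = c(s11 = s11, s22 = s22,
                                            s12 = s12, s21 = s21)),
            class = "ct_pair")
}

# ---- convolution-model CV engine ------------------------------------------

# Standardize features/responses and precompute full-length design blocks.
conv_prepare <- function(evoked, features, lag_ms, standardize = TRUE) {
  if (!inherits(evoked, "ct_evoked")) evoked <- evoked_set(evoked)
  S <- lapply(features, as_channel_matrix)
  if (standardize) {
    if (nrow(S[[1L]]) == 1L) {
      S <- lapply(standardize_features(lapply(S, drop))$x, matrix, nrow = 1L)
    } else S <- standardize_features(S)$x
    evoked <- standardize_responses(evoked)$x
  }
  lengths <- vapply(S, ncol, 1L)
  design <- lagged_design(evoked, lag_ms,
                          lengths = rep(max(lengths), length(S)))
  list(blocks = design$blocks, S = S, lengths = lengths, design = design)
}

# Leave-two-out pairwise CV given a feature->response pairing.
# lambda: per-channel vector, or NULL for per-fold LOO selection on grid.
conv_cv <- function(prep, pairing, lambda, grid = NULL, splits = NULL) {
  n <- length(prep$S)
  nf <- nrow(prep$S[[1L]])
  X <- lapply(seq_len(n), function(i)
    prep$blocks[[pairing[i]]][seq_len(prep$lengths[i]), , drop = FALSE])
  ss <- conv_suffstats(X, prep$S)
  if (is.null(splits)) splits <- l2o_splits(n)
  m <- ncol(splits)
  correct <- numeric(m)
  sims <- matrix(0, m, 4L, dimnames = list(NULL, c("s11", "s22", "s12", "s21")))
  for (k in seq_len(m)) {
    i <- splits[1L, k]; j <- splits[2L, k]
    A0 <- ss$Ctot - ss$C[[i]] - ss$C[[j]]
    B <- ss$Vtot - ss$V[[i]] - ss$V[[j]]
    lam <- lambda
    if (is.null(lam)) {       # per-fold leave-one-stimulus-out selection
      tr <- setdiff(seq_len(n), c(i, j))
      err <- matrix(Inf, length(grid), nf)
      for (gi in seq_along(grid)) {
        tot <- rep(0, nf); bad <- FALSE
        for (g in tr) {
          A <- A0 - ss$C[[g]]
          diag(A) <- diag(A) + grid[gi]
          G <- sym_solve(A, B - ss$V[[g]], quiet = TRUE)
          if (is.null(G)) { bad <- TRUE; break }
          tot <- tot + colSums((t(prep$S[[g]]) - X[[g]] %*% G)^2)
        }
        if (!bad) err[gi, ] <- tot
      }
      lam <- grid[apply(err, 2L, which.min)]
    }
    lam <- rep_len(lam, nf)
    G <- matrix(0, ncol(A0), nf)
    for (lv in unique(lam)) {
      A <- A0
      diag(A) <- diag(A) + lv
      ch <- which(lam == lv)
      G[, ch] <- sym_solve(A, B[, ch, drop = FALSE])
    }
    L <- min(prep$lengths[i], prep$lengths[j])
    li <- seq_len(L)
    if (nf == 1L) {                 # single channel: plain vectors
      p1 <- X[[i]][li, , drop = FALSE] %*% G
      p2 <- X[[j]][li, , drop = FALSE] %*% G
      s1 <- prep$S[[i]][1L, li]
      s2 <- prep$S[[j]][1L, li]
    } else {                        # flatten channel-major on both sides
      p1 <- t(X[[i]][li, , drop = FALSE] %*% G)
      p2 <- t(X[[j]][li, , drop = FALSE] %*% G)
      s1 <- prep$S[[i]][, li, drop = FALSE]
      s2 <- prep$S[[j]][, li, drop = FALSE]
    }
    s11 <- pearson_sim(s1, p1); s22 <- pearson_sim(s2, p2)
    s12 <- pearson_sim(s1, p2); s21 <- pearson_sim(s2, p1)
    d <- (s11 + s22) - (s12 + s21)
    correct[k] <- if (d > 0) 1 else if (d < 0) 0 else 0.5
    sims[k, ] <- c(s11, s22, s12, s21)
  }
  list(accuracy = 100 * mean(correct),
       outcomes = data.frame(i = splits[1L, ], j = splits[2L, ],
                             correct = correct, sims))
}

# Global leave-one-stimulus-out lambda selection for a pairing.
conv_select_lambda <- function(prep, pairing, grid) {
  n <- length(prep$S)
  X <- lapply(seq_len(n), function(i)
    prep$blocks[[pairing[i]]][seq_len(prep$lengths[i]), , drop = FALSE])
  ss <- conv_suffstats(X, prep$S)
  err <- conv_loo_grid(ss, X, prep$S, grid)
  grid[apply(err, 2L, which.min)]
}

# ---- user-facing cross-validation ----------------------------------------

#' Leave-two-out decoding evaluation
#'
#' Runs the full leave-two-out cross-validation of a decoding model for
#' one participant: for every pair of stimuli the model is trained on the
#' remaining stimuli, the two held-out stimuli are reconstructed, test
#' pair lengths are equalized to the shorter one, and the pair is scored
#' with the summed-correlation criterion of [classify_pair()]. The final
#' accuracy is the percentage of pairs classified correctly.
#'
#' Standardization (features across stimuli, responses per sensor and
#' 10 ms window) is computed on the full stimulus set before
#' cross-validation, replicating the published protocol; `strict = TRUE`
#' restricts it to the training folds for leakage sensitivity checks.
#'
#' @param evoked a [evoked_set()] for one participant.
#' @param features model-dependent: for `"convolution"` a list of
#'   time-varying features (vectors or channels x frames matrices, one
#'   per stimulus); for `"ridge"` a stimuli x features matrix of static
#'   features; for `"logistic"` a `ct_phonemes` object or list of
#'   phoneme x frame +/-1 matrices.
#' @param model decoder type.
#' @param lag_ms lag window in ms for the time-resolved models
#'   (default `c(20, 420)`).
#' @param window_ms analysis window for the static ridge model
#'   (default `c(0, 1000)`).
#' @param grid penalty grid for leave-one-out selection.
#' @param lambda fixed penalty (scalar or per channel); overrides
#'   selection.
#' @param lambda_selection `"global"` (select once on all stimuli, the
#'   default) or `"per_fold"` (re-select within each training fold).
#' @param standardize standardize features and responses first
#'   (default TRUE).
#' @param strict restrict standardization to training folds
#'   (only with `lambda_selection = "per_fold"`; slow, default FALSE).
#' @param pairing optional permutation: feature i is paired with the
#'   response of stimulus `pairing[i]` (used for label-permutation nulls).
#' @param seed seed for the logistic decoder's SGD.
#' @param ... passed to [fit_logistic_phonemes()] for `model = "logistic"`.
#' @return object of class `ct_decoding`: `accuracy` (percent),
#'   `n_pairs`, `outcomes` (per-pair data frame), `lambda`, `model`.
#' @export
decode_cv <- function(evoked, features, model = c("convolution", "ridge", "logistic"),
                      lag_ms = c(20, 420), window_ms = c(0, 1000),
                      grid = 10^(-3:6), lambda = NULL,
                      lambda_selection = c("global", "per_fold"),
                      standardize = TRUE, strict = FALSE, pairing = NULL,
                      seed = 1L, ...) {
  model <- match.arg(model)
  lambda_selection <- match.arg(lambda_selection)
  if (!inherits(evoked, "ct_evoked")) evoked <- evoked_set(evoked)
  n <- dim(evoked$data)[1L]
  if (is.null(pairing)) pairing <- seq_len(n)
  res <- switch(model,
    convolution = {
      if (strict) {
        out <- conv_cv_strict(evoked, features, lag_ms, grid, lambda, pairing)
      } else {
        prep <- conv_prepare(evoked, features, lag_ms, standardize)
        lam <- lambda
        if (is.null(lam) && lambda_selection == "global")
          lam <- conv_select_lambda(prep, pairing, grid)
        out <- conv_cv(prep, pairing, lam, grid = grid)
        out$lambda <- if (is.null(lam)) NA_real_ else lam
      }
      out
    },
    ridge = ridge_cv(evoked, features, window_ms, grid, lambda,
                     lambda_selection, standardize, pairing),
    logistic = logit_cv(evoked, features, lag_ms, standardize, pairing,
                        seed = seed, ...))
  structure(list(accuracy = res$accuracy, n_pairs = nrow(res$outcomes),
                 outcomes = res$outcomes, lambda = res$lambda,
                 model = model, lag_ms = lag_ms),
            class = "ct_decoding")
}

#' @export
print.ct_decoding <- function(x, ...) {
  cat(sprintf("Leave-two-out decoding (%s model): %.1f%% correct over %d pairs\n",
              x$model, x$accuracy, x$n_pairs))
  invisible(x)
}

#' @export
summary.ct_decoding <- function(object, ...) {
  cat(sprintf("Model: %s decoder", object$model))
  if (object$model != "ridge")
    cat(sprintf(", lag window %g-%g ms", object$lag_ms[1L], object$lag_ms[2L]))
  cat("\n")
  cat(sprintf("Accuracy: %.2f%% over %d pairwise tests (chance 50%%)\n",
              object$accuracy, object$n_pairs))
  if (!all(is.na(object$lambda)))
    cat("Ridge penalty:", format(unique(object$lambda), digits = 3), "\n")
  invisible(object)
}

# Leakage-free variant: standardization states are estimated on each
# training fold only and applied to the held-out pair. Slow (refits the
# whole pipeline per split); intended for sensitivity checks at small n.
conv_cv_strict <- function(evoked, features, lag_ms, grid, lambda, pairing) {
  S0 <- lapply(features, as_channel_matrix)
  n <- length(S0)
  lengths <- vapply(S0, ncol, 1L)
  splits <- l2o_splits(n)
  m <- ncol(splits)
  correct <- numeric(m)
  sims <- matrix(0, m, 4L, dimnames = list(NULL, c("s11", "s22", "s12", "s21")))
  single <- nrow(S0[[1L]]) == 1L
  for (k in seq_len(m)) {
    te <- splits[, k]; tr <- setdiff(seq_len(n), te)
    fs <- if (single) standardize_features(lapply(S0[tr], drop))
          else standardize_features(S0[tr])
    S <- if (single)
      lapply(standardize_features(lapply(S0, drop), state = fs$state)$x,
             matrix, nrow = 1L)
    else standardize_features(S0, state = fs$state)$x
    rs <- standardize_responses(evoked$data[pairing[tr], , , drop = FALSE])
    ev <- evoked
    ev$data <- standardize_responses(evoked$data, state = rs$state)$x
    design <- lagged_design(ev, lag_ms, lengths = rep(max(lengths), n))
    X <- lapply(seq_len(n), function(i)
      design$blocks[[pairing[i]]][seq_len(lengths[i]), , drop = FALSE])
    dtr <- list(blocks = X[tr], lags = design$lags, lag_ms = lag_ms,
                n_sensors = design$n_sensors)
    class(dtr) <- "ct_lagged"
    fit <- fit_convolution(dtr, S[tr], grid = grid, lambda = lambda)
    L <- min(lengths[te])
    p1 <- t(X[[te[1L]]][seq_len(L), , drop = FALSE] %*% fit$G)
    p2 <- t(X[[te[2L]]][seq_len(L), , drop = FALSE] %*% fit$G)
    out <- classify_pair(S[[te[1L]]][, seq_len(L), drop = FALSE],
                         S[[te[2L]]][, seq_len(L), drop = FALSE], p1, p2)
    correct[k] <- out$correct
    sims[k, ] <- out$sim
  }
  list(accuracy = 100 * mean(correct),
       outcomes = data.frame(i = splits[1L, ], j = splits[2L, ],
                             correct = correct, sims),
       lambda = if (is.null(lambda)) NA_real_ else lambda)
}

ridge_cv <- function(evoked, features, window_ms, grid, lambda,
                     lambda_selection, standardize, pairing) {
  Y <- as.matrix(features)
  if (ncol(Y) < 2L)
    stop("static decoding needs at least 2 feature columns for the pairwise criterion", call. = FALSE)
  n <- nrow(Y)
  w0 <- evoked$onset + round(window_ms[1L] / 1000 * evoked$rate)
  w1 <- evoked$onset + round(window_ms[2L] / 1000 * evoked$rate)
  w1 <- min(w1, dim(evoked$data)[3L])
  r <- evoked$data[, , w0:w1, drop = FALSE]
  if (standardize) {
    r <- standardize_responses(r)$x
    Y <- standardize_features(Y)$x
  }
  X <- matrix(r, nrow = n)[pairing, , drop = FALSE]
  K <- tcrossprod(X)
  lam <- lambda
  if (is.null(lam) && lambda_selection == "global")
    lam <- fit_ridge_static(X, Y, grid)$lambda
  splits <- l2o_splits(n)
  m <- ncol(splits)
  correct <- numeric(m)
  sims <- matrix(0, m, 4L, dimnames = list(NULL, c("s11", "s22", "s12", "s21")))
  for (k in seq_len(m)) {
    te <- splits[, k]; tr <- setdiff(seq_len(n), te)
    lk <- lam
    if (is.null(lk))
      lk <- fit_ridge_static(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                             grid)$lambda
    lk <- rep_len(lk, ncol(Y))
    P <- matrix(0, 2L, ncol(Y))
    for (lv in unique(lk)) {
      A <- K[tr, tr]
      diag(A) <- diag(A) + lv
      ch <- which(lk == lv)
      alpha <- sym_solve(A, Y[tr, ch, drop = FALSE])
      P[, ch] <- K[te, tr] %*% alpha
    }
    out <- classify_pair(Y[te[1L], ], Y[te[2L], ], P[1L, ], P[2L, ])
    correct[k] <- out$correct
    sims[k, ] <- out$sim
  }
  list(accuracy = 100 * mean(correct),
       outcomes = data.frame(i = splits[1L, ], j = splits[2L, ],
                             correct = correct, sims),
       lambda = if (is.null(lam)) NA_real_ else lam)
}

logit_cv <- function(evoked, features, lag_ms, standardize, pairing,
                     seed = 1L, ...) {
  if (inherits(features, "ct_phonemes")) features <- features$matrices
  S <- lapply(features, as_channel_matrix)
  n <- length(S)
  if (standardize) evoked <- standardize_responses(evoked)$x
  lengths <- vapply(S, ncol, 1L)
  design <- lagged_design(evoked, lag_ms, lengths = rep(max(lengths), n))
  X <- lapply(seq_len(n), function(i)
    design$blocks[[pairing[i]]][seq_len(lengths[i]), , drop = FALSE])
  splits <- l2o_splits(n)
  m <- ncol(splits)
  correct <- numeric(m)
  sims <- matrix(0, m, 4L, dimnames = list(NULL, c("s11", "s22", "s12", "s21")))
  for (k in seq_len(m)) {
    te <- splits[, k]; tr <- setdiff(seq_len(n), te)
    Xtr <- do.call(rbind, X[tr])
    Ytr <- do.call(rbind, lapply(S[tr], t))
    fit <- suppressWarnings(
      fit_logistic_phonemes(Xtr, Ytr, seed = seed, ...))
    keep <- !vapply(fit$models, is.null, TRUE)
    L <- min(lengths[te])
    pr <- lapply(te, function(i)
      predict(fit, X[[i]][seq_len(L), , drop = FALSE])$prob[, keep, drop = FALSE])
    s1 <- t(S[[te[1L]]])[seq_len(L), keep, drop = FALSE]
    s2 <- t(S[[te[2L]]])[seq_len(L), keep, drop = FALSE]
    out <- classify_pair(s1, s2, pr[[1L]], pr[[2L]])
    correct[k] <- out$correct
    sims[k, ] <- out$sim
  }
  list(accuracy = 100 * mean(correct),
       outcomes = data.frame(i = splits[1L, ], j = splits[2L, ],
                             correct = correct, sims),
       lambda = NA_real_)
}

#' Leave-one-out reconstruction correlations
#'
#' Holds out each stimulus in turn, fits the convolution decoder on the
#' rest, reconstructs the held-out stimulus at full length and returns
#' the Pearson correlation between original and reconstructed features
#' (flattened over channels and frames), one value per stimulus.
#'
#' @inheritParams decode_cv
#' @return numeric vector of per-stimulus correlations in [-1, 1].
#' @export
loo_reconstruction <- function(evoked, features, lag_ms = c(20, 420),
                               grid = 10^(-3:6), lambda = NULL,
                               standardize = TRUE) {
  prep <- conv_prepare(evoked, features, lag_ms, standardize)
  n <- length(prep$S)
  X <- lapply(seq_len(n), function(i)
    prep$blocks[[i]][seq_len(prep$lengths[i]), , drop = FALSE])
  ss <- conv_suffstats(X, prep$S)
  if (is.null(lambda))
    lambda <- grid[apply(conv_loo_grid(ss, X, prep$S, grid), 2L, which.min)]
  nf <- nrow(prep$S[[1L]])
  lambda <- rep_len(lambda, nf)
  vapply(seq_len(n), function(g) {
    G <- matrix(0, ncol(ss$Ctot), nf)
    for (lv in unique(lambda)) {
      A <- ss$Ctot - ss$C[[g]]
      diag(A) <- diag(A) + lv
      ch <- which(lambda == lv)
      G[, ch] <- sym_solve(A, (ss$Vtot - ss$V[[g]])[, ch, drop = FALSE])
    }
    pearson_sim(prep$S[[g]], t(X[[g]] %*% G))
  }, numeric(1L))
}

#' Evoked signal-to-noise ratio
#'
#' Per participant: each sensor's epoch is z-scored with its pre-onset
#' baseline mean and sd; the SNR is the mean squared standardized signal
#' intensity during stimulus presentation divided by the baseline variance
#' of the z-scored signal, averaged over sensors and stimuli. Pure noise
#' gives values near 1.
#'
#' @param evoked a [evoked_set()] with a pre-onset baseline window.
#' @return scalar SNR (positive).
#' @export
estimate_snr <- function(evoked) {
  stopifnot(inherits(evoked, "ct_evoked"))
  if (evoked$onset < 3L) stop("no baseline window before onset", call. = FALSE)
  d <- dim(evoked$data)
  base_idx <- seq_len(evoked$onset - 1L)
  vals <- matrix(NA_real_, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    post_idx <- evoked$onset:min(evoked$onset + evoked$lengths[i] - 1L, d[3L])
    for (x in seq_len(d[2L])) {
      b <- evoked$data[i, x, base_idx]
      if (stats::sd(b) == 0) stop("zero baseline variance", call. = FALSE)
      z <- (evoked$data[i, x, ] - mean(b)) / stats::sd(b)
      vals[i, x] <- mean(z[post_idx]^2) / stats::var(z[base_idx])
    }
  }
  mean(vals)
}
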