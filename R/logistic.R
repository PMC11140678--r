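#' Binary logistic decoders for phoneme activity
#'
#' Trains, separately for each retained phoneme, a ridge-penalized binary
#' logistic regression predicting whether the phoneme is active (+1) or
#' inactive (-1) in each 10 ms frame, from the lagged sensor responses.
#' The loss is minimized by stochastic gradient descent with a decaying
#' learning rate and tail-averaged iterates; training stops when the full
#' epoch loss changes by less than `tol` or after `max_epochs` epochs.
#'
#' @param design a [lagged_design()] over the training stimuli, or an
#'   `NT x p` matrix of stacked lagged rows.
#' @param Y phoneme labels aligned with the design rows: an `NT x K`
#'   matrix of +/-1 (columns = phonemes), or a `ct_phonemes` object whose
#'   word matrices are stacked in stimulus order.
#' @param lambda ridge penalty on the coefficients (default 1e-3).
#' @param max_epochs,tol,learning_rate,batch SGD hyperparameters.
#' @param seed integer seed for the shuffling (logged in the fit).
#' @return object of class `ct_logit`: per-phoneme `models`
#'   (list of `w`, `b`, `converged`, `epochs`), `labels`, `skipped`
#'   (phonemes with single-class training labels, skipped with a warning).
#' @export
fit_logistic_phonemes <- function(design, Y, lambda = 1e-3, max_epochs = 200L,
                                  tol = 1e-6, learning_rate = 0.1,
                                  batch = 32L, seed = 1L) {
  X <- if (inherits(design, "ct_lagged")) do.call(rbind, design$blocks)
       else as.matrix(design)
  if (inherits(Y, "ct_phonemes")) Y <- do.call(rbind, lapply(Y$matrices, t))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stop("phoneme frames are not aligned with the design rows", call. = FALSE)
  labels <- colnames(Y)
  if (is.null(labels)) labels <- paste0("ph", seq_len(ncol(Y)))
  set.seed(seed)
  models <- vector("list", ncol(Y))
  names(models) <- labels
  skipped <- character(0)
  for (k in seq_len(ncol(Y))) {
    y <- Y[, k]
    if (length(unique(sign(y))) < 2L) {
      warning(sprintf("phoneme '%s' has single-class training labels; skipped",
                      labels[k]))
      skipped <- c(skipped, labels[k])
      next
    }
    models[[k]] <- sgd_logistic(X, y, lambda, max_epochs, tol,
                                learning_rate, batch)
  }
  structure(list(models = models, labels = labels, skipped = skipped,
                 lambda = lambda, p = ncol(X), seed = seed),
            class = "ct_logit")
}

sgd_logistic <- function(X, y, lambda, max_epochs, tol, lr0, batch) {
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  w_avg <- numeric(p); b_avg <- 0; n_avg <- 0L
  avg_from <- ceiling(max_epochs / 2)
  loss_prev <- Inf; converged <- FALSE; ep <- 0L
  # numerically stable logistic loss: log(1 + exp(-m)) = max(-m, 0) + log1p(exp(-|m|))
  logloss <- function(m) pmax(-m, 0) + log1p(exp(-abs(m)))
  for (ep in seq_len(max_epochs)) {
    lr <- lr0 / (1 + ep / 20)
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      z <- drop(X[idx, , drop = FALSE] %*% w) + b
      g <- -y[idx] * stats::plogis(-y[idx] * z)      # d loss / d z
      w <- w - lr * (drop(crossprod(X[idx, , drop = FALSE], g)) / length(idx) +
                       lambda * w)
      b <- b - lr * mean(g)
    }
    if (ep >= avg_from) {
      w_avg <- w_avg + w; b_avg <- b_avg + b; n_avg <- n_avg + 1L
    }
    z <- drop(X %*% w) + b
    loss <- mean(logloss(y * z)) + lambda / 2 * sum(w^2)
    if (abs(loss_prev - loss) < tol) { converged <- TRUE; break }
    loss_prev <- loss
  }
  if (n_avg > 0L) { w <- w_avg / n_avg; b <- b_avg / n_avg }
  list(w = w, b = b, converged = converged, epochs = ep)
}

#' @export
print.ct_logit <- function(x, ...) {
  cat(sprintf("Logistic phoneme decoders: %d phonemes (%d skipped), %d predictors\n",
              length(x$labels), length(x$skipped), x$p))
  invisible(x)
}

#' Predict phoneme activity from new responses
#'
#' A phoneme is scored active in a frame when its predicted probability
#' strictly exceeds 0.5 (a probability of exactly 0.5 is inactive);
#' probabilities are retained for similarity-based evaluation.
#'
#' @param object a `ct_logit` fit.
#' @param design a [lagged_design()] over the test stimuli (same layout as
#'   training) or a matrix of lagged rows.
#' @param ... unused.
#' @return list with `prob` (frames x phonemes probability matrix; `NA`
#'   columns for skipped phonemes) and `active` (same shape, +/-1).
#' @export
predict.ct_logit <- function(object, design, ...) {
  X <- if (inherits(design, "ct_lagged")) do.call(rbind, design$blocks)
       else as.matrix(design)
  if (ncol(X) != object$p)
    stop("design layout does not match the fitted model", call. = FALSE)
  prob <- matrix(NA_real_, nrow(X), length(object$labels),
                 dimnames = list(NULL, object$labels))
  for (k in seq_along(object$models)) {
    m <- object$models[[k]]
    if (is.null(m)) next
    prob[, k] <- stats::plogis(drop(X %*% m$w) + m$b)
  }
  active <- ifelse(prob > 0.5, 1, -1)
  list(prob = prob, active = active)
}
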