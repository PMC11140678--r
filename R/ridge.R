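# Linear ridge solvers, primal and dual (kernel) forms, plus efficient
# leave-one-stimulus-out penalty selection used by the decoders.

#' Ridge solutions in primal and dual form
#'
#' `ridge_primal()` computes `(X'X + lambda I)^-1 X'Y`; `ridge_dual()`
#' computes the equivalent kernel form `X'(XX' + lambda I)^-1 Y`, which is
#' cheaper when observations are far fewer than predictors (the usual
#' evoked-response regime). Both return the same p x F weight matrix for
#' any `lambda > 0`.
#'
#' @param X n x p design matrix.
#' @param Y n x F target matrix (or vector).
#' @param lambda non-negative ridge penalty.
#' @return p x F matrix of weights.
#' @export
ridge_primal <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda
  sym_solve(A, crossprod(X, Y))
}

#' @rdname ridge_primal
#' @export
ridge_dual <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  K <- tcrossprod(X)
  diag(K) <- diag(K) + lambda
  crossprod(X, sym_solve(K, Y))
}

# Cholesky solve for symmetric positive definite systems; NULL on failure.
sym_solve <- function(A, b, quiet = FALSE) {
  out <- tryCatch({
    ch <- chol(A)
    backsolve(ch, forwardsolve(t(ch), b))
  }, error = function(e) NULL)
  if (is.null(out)) out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out) && !quiet) warning("singular ridge system")
  out
}

# Per-stimulus sufficient statistics for the convolution decoder.
# blocks: list of T_n x p design matrices; S: list of F x T_n targets.
# Returns C (list of p x p), V (list of p x F), plus totals.
conv_suffstats <- function(blocks, S) {
  C <- lapply(blocks, crossprod)
  V <- mapply(function(X, s) crossprod(X, t(s)), blocks, S, SIMPLIFY = FALSE)
  list(C = C, V = V,
       Ctot = Reduce(`+`, C), Vtot = Reduce(`+`, V))
}

# Grouped (leave-one-stimulus-out) errors on a lambda grid, computed by
# downdating the pooled Gram matrices: for each held-out stimulus the
# pooled X'X and X'S lose that stimulus's contribution and the reduced
# system is re-solved. Returns a |grid| x F error matrix.
conv_loo_grid <- function(ss, blocks, S, grid) {
  nf <- ncol(ss$Vtot)
  err <- matrix(Inf, length(grid), nf)
  for (gi in seq_along(grid)) {
    lam <- grid[gi]
    tot <- rep(0, nf)
    bad <- FALSE
    for (g in seq_along(blocks)) {
      A <- ss$Ctot - ss$C[[g]]
      diag(A) <- diag(A) + lam
      G <- sym_solve(A, ss$Vtot - ss$V[[g]], quiet = TRUE)
      if (is.null(G)) { bad <- TRUE; break }
      res <- t(S[[g]]) - blocks[[g]] %*% G
      tot <- tot + colSums(res^2)
    }
    if (bad) {
      warning(sprintf("singular system at lambda = %g; grid point skipped", lam))
    } else err[gi, ] <- tot
  }
  err
}

#' Fit the kernel convolution decoder
#'
#' Learns, for each feature channel f independently, the spatiotemporal
#' response function G_f that reconstructs the time-varying stimulus
#' feature from lagged sensor responses, by ridge regression in the dual
#' (kernel) form `G_f = R'(RR' + lambda_f I)^-1 S_f`. The penalty
#' `lambda_f` is chosen per channel from a grid by minimizing the
#' leave-one-stimulus-out error within the training data.
#'
#' @param design a [lagged_design()] over the training stimuli.
#' @param S training features: a list (one element per stimulus) of
#'   channels x frames matrices, or numeric vectors for a single channel
#'   (e.g. the amplitude envelope). Frame counts must match the design.
#' @param grid ordered positive penalty grid (default `10^(-3:6)`).
#' @param lambda optional fixed penalty (scalar or one per channel); when
#'   supplied, grid selection is skipped.
#' @param method `"auto"` (dual when rows < columns, else the equivalent
#'   primal form), `"dual"` or `"primal"`.
#' @return object of class `ct_conv`, with methods [coef.ct_conv()],
#'   [predict.ct_conv()] and `print`.
#' @export
fit_convolution <- function(design, S, grid = 10^(-3:6), lambda = NULL,
                            method = c("auto", "dual", "primal")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "ct_lagged"))
  S <- lapply(S, as_channel_matrix)
  if (!all(vapply(S, ncol, 1L) == vapply(design$blocks, nrow, 1L)))
    stop("feature frame counts do not match design rows", call. = FALSE)
  nf <- nrow(S[[1L]])
  if (is.null(lambda)) {
    if (length(grid) < 3L || any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
      stop("penalty grid must be >= 3 strictly increasing positive values",
           call. = FALSE)
    ss <- conv_suffstats(design$blocks, S)
    err <- conv_loo_grid(ss, design$blocks, S, grid)
    lambda <- grid[apply(err, 2L, which.min)]
  } else {
    err <- NULL
    lambda <- rep_len(lambda, nf)
  }
  Xall <- do.call(rbind, design$blocks)
  Sall <- do.call(rbind, lapply(S, t))
  p <- ncol(Xall)
  use_dual <- switch(method, dual = TRUE, primal = FALSE,
                     auto = nrow(Xall) < p)
  G <- matrix(0, p, nf)
  for (lam in unique(lambda)) {
    ch <- which(lambda == lam)
    G[, ch] <- if (use_dual) ridge_dual(Xall, Sall[, ch, drop = FALSE], lam)
               else ridge_primal(Xall, Sall[, ch, drop = FALSE], lam)
  }
  structure(list(G = G, lambda = lambda, lag_ms = design$lag_ms,
                 lags = design$lags, n_sensors = design$n_sensors,
                 n_channels = nf, loo_errors = err, grid = grid),
            class = "ct_conv")
}

as_channel_matrix <- function(s) {
  if (inherits(s, "ct_envelope")) s <- s$values
  if (inherits(s, "ct_spectrogram")) s <- s$values
  if (is.matrix(s)) s else matrix(s, nrow = 1L)
}

#' @export
print.ct_conv <- function(x, ...) {
  cat(sprintf("Kernel convolution decoder: %d channel(s), lags %g-%g ms x %d sensors\n",
              x$n_channels, x$lag_ms[1L], x$lag_ms[2L], x$n_sensors))
  cat("  lambda:", format(unique(x$lambda), digits = 3), "\n")
  invisible(x)
}

#' Response-function weights of a convolution decoder
#'
#' @param object a `ct_conv` fit.
#' @param ... unused.
#' @return lag x sensor x channel array of weights g(tau, x) per channel;
#'   lag dimension named with lags in ms.
#' @export
coef.ct_conv <- function(object, ...) {
  out <- array(object$G,
               dim = c(object$n_sensors, length(object$lags), object$n_channels))
  out <- aperm(out, c(2L, 1L, 3L))
  dimnames(out)[[1L]] <- as.character(seq(object$lag_ms[1L], object$lag_ms[2L],
                                          length.out = length(object$lags)))
  out
}

#' Reconstruct time-varying features for new responses
#'
#' Applies the learned response functions to held-out evoked responses:
#' `s_hat_f(t) = sum_x sum_tau g_f(tau, x) r(t + tau, x)`, each stimulus
#' frame reconstructed from the response samples that followed it by
#' tau within the lag window.
#'
#' @param object a `ct_conv` fit.
#' @param design a [lagged_design()] over the test stimuli, built with the
#'   same lag window and sensor count as at training.
#' @param ... unused.
#' @return list of channels x frames reconstruction matrices, one per
#'   test stimulus.
#' @export
predict.ct_conv <- function(object, design, ...) {
  stopifnot(inherits(design, "ct_lagged"))
  if (design$n_sensors != object$n_sensors ||
      !identical(design$lags, object$lags))
    stop("design layout (sensors/lags) does not match the fitted model",
         call. = FALSE)
  lapply(design$blocks, function(X) t(X %*% object$G))
}

#' Fit the dual ridge decoder for static features
#'
#' Decodes non-time-varying stimulus features (frequency spectrum,
#' modulation power spectrum, semantic vectors) from the full analysis
#' window of the evoked response, one weight map w_f(t, x) per feature,
#' using kernel ridge regression with efficient leave-one-stimulus-out
#' penalty selection (the closed-form LOO residual `alpha_i / Q_ii` of
#' kernel ridge).
#'
#' @param X n_stimuli x p matrix of flattened (sensor x time) responses.
#' @param Y n_stimuli x F matrix of static features.
#' @param grid,lambda as in [fit_convolution()].
#' @return object of class `ct_ridge` with `W` (p x F weights), `lambda`
#'   (per feature) and `loo_errors`; has `predict` and `coef` methods.
#' @export
fit_ridge_static <- function(X, Y, grid = 10^(-3:6), lambda = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  K <- tcrossprod(X)
  nf <- ncol(Y)
  if (is.null(lambda)) {
    err <- matrix(Inf, length(grid), nf)
    for (gi in seq_along(grid)) {
      A <- K
      diag(A) <- diag(A) + grid[gi]
      Q <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
      if (is.null(Q)) {
        warning(sprintf("singular system at lambda = %g; grid point skipped",
                        grid[gi]))
        next
      }
      alpha <- Q %*% Y
      err[gi, ] <- colSums((alpha / diag(Q))^2)
    }
    lambda <- grid[apply(err, 2L, which.min)]
  } else {
    err <- NULL
    lambda <- rep_len(lambda, nf)
  }
  W <- matrix(0, ncol(X), nf)
  for (lam in unique(lambda)) {
    ch <- which(lambda == lam)
    W[, ch] <- ridge_dual(X, Y[, ch, drop = FALSE], lam)
  }
  structure(list(W = W, lambda = lambda, loo_errors = err, grid = grid,
                 p = ncol(X)),
            class = "ct_ridge")
}

#' @export
print.ct_ridge <- function(x, ...) {
  cat(sprintf("Dual ridge decoder: %d feature(s), %d predictors\n",
              ncol(x$W), x$p))
  invisible(x)
}

#' @export
coef.ct_ridge <- function(object, ...) object$W

#' @export
predict.ct_ridge <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("response layout does not match the fitted model", call. = FALSE)
  newdata %*% object$W
}
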