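# Directed spectral influence: bivariate Geweke Granger prediction and
# pairwise-conditional spectral Granger causality for three sites, with
# BIC model-order selection.
#
# Estimation is ordinary least squares on lag-stacked regressors. When a
# list of equal-length epochs is supplied, lag stacking is done per epoch
# and the normal equations pooled, so no regression ever crosses an epoch
# boundary.

# Coerce input to a list of demeaned n x m matrices (epochs).
as_epoch_list <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    eps <- lapply(x, function(e) as.matrix(e))
  } else {
    eps <- list(as.matrix(x))
  }
  lapply(eps, function(e) sweep(e, 2, colMeans(e)))
}

# Pooled OLS VAR(k) fit over epochs. Returns coefficient array A
# (m x m x k), residual covariance Sigma (ML, pooled), and n_eff.
var_fit_ols <- function(x, k) {
  eps <- as_epoch_list(x)
  m <- ncol(eps[[1]])
  XtX <- matrix(0, m * k, m * k)
  XtY <- matrix(0, m * k, m)
  YtY <- matrix(0, m, m)
  n_eff <- 0L
  for (e in eps) {
    n <- nrow(e)
    if (n <= k + 1L) stop("epoch too short for order ", k)
    Y <- e[(k + 1):n, , drop = FALSE]
    Z <- do.call(cbind, lapply(1:k, function(j) {
      e[(k + 1 - j):(n - j), , drop = FALSE]
    }))
    XtX <- XtX + crossprod(Z)
    XtY <- XtY + crossprod(Z, Y)
    YtY <- YtY + crossprod(Y)
    n_eff <- n_eff + nrow(Y)
  }
  if (min(diag(XtX)) <= 0 || any(!is.finite(XtX))) {
    stop("degenerate (constant) signal")
  }
  B <- solve(XtX, XtY)                      # (m*k) x m
  Sigma <- (YtY - crossprod(XtY, B)) / n_eff
  Sigma <- (Sigma + t(Sigma)) / 2
  A <- array(0, c(m, m, k))
  for (j in 1:k) A[, , j] <- t(B[((j - 1) * m + 1):(j * m), , drop = FALSE])
  list(A = A, Sigma = Sigma, n_eff = n_eff, m = m, k = k)
}

# Spectral radius of the VAR companion matrix.
var_spectral_radius <- function(A) {
  m <- dim(A)[1]; k <- dim(A)[3]
  comp <- matrix(0, m * k, m * k)
  for (j in 1:k) comp[1:m, ((j - 1) * m + 1):(j * m)] <- A[, , j]
  if (k > 1) comp[(m + 1):(m * k), 1:(m * (k - 1))] <- diag(m * (k - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

check_var_stable <- function(A, what = "VAR") {
  rho <- var_spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf("unstable %s fit: spectral radius %.4f >= 1", what, rho))
  }
  rho
}

# Transfer function H(f) = (I - sum_j A_j e^{-i 2 pi f j / fs})^{-1},
# returned as a list over frequencies of m x m complex matrices.
var_transfer <- function(A, freqs, sampling_rate) {
  m <- dim(A)[1]; k <- dim(A)[3]
  lapply(freqs, function(f) {
    z <- exp(-2i * pi * f * (1:k) / sampling_rate)
    Af <- matrix(0 + 0i, m, m)
    for (j in 1:k) Af <- Af + A[, , j] * z[j]
    solve(diag(m) - Af)
  })
}

#' Select VAR model order by BIC
#'
#' Fits univariate autoregressions of order 1..`max_order` to each signal
#' by OLS on a common estimation sample, scores each order by BIC, takes
#' each signal's argmin, and returns the median best order across signals
#' rounded half-away-from-zero — the shared order applied to every signal
#' in the Granger fits.
#'
#' @param signals A list of numeric vectors (one per signal), or a matrix
#'   with signals in columns. Each signal may itself be a list of epochs.
#' @param max_order Largest order tried (default 20).
#' @return The selected order (integer), with the per-signal best orders
#'   in attribute `per_signal`.
#' @export
select_order_bic <- function(signals, max_order = 20) {
  if (is.matrix(signals)) signals <- lapply(seq_len(ncol(signals)),
                                            function(j) signals[, j])
  best <- vapply(signals, function(s) {
    eps <- as_epoch_list(s)
    bics <- vapply(1:max_order, function(k) {
      fit <- var_fit_ols(eps, k)
      n <- fit$n_eff
      n * log(fit$Sigma[1, 1]) + k * log(n)
    }, numeric(1))
    which.min(bics)
  }, numeric(1))
  med <- stats::median(best)
  structure(round_half_away(med), per_signal = best)
}

# round half away from zero (the documented tie rule for the median order)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Bivariate Geweke Granger causality
#'
#' Fits univariate AR(k) models to each signal and a bivariate VAR(k) to
#' the pair, then reports the time-domain Granger prediction per direction
#' as `log(Var[e] / Var[eps])` (univariate over bivariate residual
#' variance) and the spectral decomposition per direction by Geweke's
#' method from the VAR transfer function and residual covariance. Both are
#' nonnegative; the average of the spectral measure over frequency
#' approaches the time-domain measure (Geweke's integral identity) on
#' stable simulations.
#'
#' @param x,y Numeric vectors, or lists of equal-length epochs.
#' @param k Model order (from [select_order_bic()]).
#' @param sampling_rate Hz.
#' @param freqs Frequency grid, Hz (default the streaming analysis grid,
#'   1--20 Hz at 0.5 Hz).
#' @return A list of class `granger_spectrum`: `freqs`, `gc` (matrix with
#'   rows `x->y` and `y->x`), `time_domain_gc` (named vector),
#'   `residual_variances`, `order`, `spectral_radius`.
#' @export
bivariate_gc <- function(x, y, k, sampling_rate,
                         freqs = seq(1, 20, by = 0.5)) {
  ex <- as_epoch_list(x); ey <- as_epoch_list(y)
  uni_x <- var_fit_ols(ex, k)
  uni_y <- var_fit_ols(ey, k)
  pair <- lapply(seq_along(ex), function(i) cbind(ex[[i]][, 1], ey[[i]][, 1]))
  biv <- var_fit_ols(pair, k)
  rho <- check_var_stable(biv$A)
  S <- biv$Sigma
  td <- c("x->y" = log(uni_y$Sigma[1, 1] / S[2, 2]),
          "y->x" = log(uni_x$Sigma[1, 1] / S[1, 1]))
  H <- var_transfer(biv$A, freqs, sampling_rate)
  spec <- vapply(H, function(Hf) {
    Sf <- Hf %*% S %*% Conj(t(Hf))
    # direction y->x: target x (index 1)
    Ht11 <- Hf[1, 1] + (S[1, 2] / S[1, 1]) * Hf[1, 2]
    f_yx <- log(Re(Sf[1, 1]) / (Mod(Ht11)^2 * S[1, 1]))
    # direction x->y: target y (index 2)
    Ht22 <- Hf[2, 2] + (S[1, 2] / S[2, 2]) * Hf[2, 1]
    f_xy <- log(Re(Sf[2, 2]) / (Mod(Ht22)^2 * S[2, 2]))
    c(f_xy, f_yx)
  }, numeric(2))
  gc <- pmax(spec, 0)
  rownames(gc) <- c("x->y", "y->x")
  structure(list(freqs = freqs, gc = gc, time_domain_gc = pmax(td, 0),
                 residual_variances = c(e_x = uni_x$Sigma[1, 1],
                                        e_y = uni_y$Sigma[1, 1],
                                        eps_x = S[1, 1], eps_y = S[2, 2]),
                 order = k, spectral_radius = rho),
            class = "granger_spectrum")
}

# Model-implied autocovariance sequence G(0..n_lags) from a stable VAR,
# via the companion-form discrete Lyapunov equation (doubling iteration)
# and forward propagation.
var_autocov <- function(A, Sigma, n_lags) {
  m <- dim(A)[1]; k <- dim(A)[3]
  comp <- matrix(0, m * k, m * k)
  for (j in 1:k) comp[1:m, ((j - 1) * m + 1):(j * m)] <- A[, , j]
  if (k > 1) comp[(m + 1):(m * k), 1:(m * (k - 1))] <- diag(m * (k - 1))
  Q <- matrix(0, m * k, m * k)
  Q[1:m, 1:m] <- Sigma
  P <- Q; Aj <- comp
  for (it in 1:60) {
    Pn <- P + Aj %*% P %*% t(Aj)
    Aj <- Aj %*% Aj
    if (max(abs(Pn - P)) < 1e-14 * max(abs(Pn))) { P <- Pn; break }
    P <- Pn
  }
  G <- vector("list", n_lags + 1L)
  # companion covariance holds G(0..k-1) in its first block row
  for (j in 0:(k - 1)) {
    if (j <= n_lags) G[[j + 1L]] <- P[1:m, (j * m + 1):((j + 1) * m)]
  }
  if (n_lags >= k) {
    for (l in k:n_lags) {
      Gl <- matrix(0, m, m)
      for (j in 1:k) {
        lag <- l - j
        Gj <- if (lag >= 0) G[[lag + 1L]] else t(G[[-lag + 1L]])
        Gl <- Gl + A[, , j] %*% Gj
      }
      G[[l + 1L]] <- Gl
    }
  }
  G
}

# Solve the block Yule-Walker equations for a VAR(p) model of the process
# with autocovariance list G (G[[l+1]] = Cov(X_t, X_{t-l})). Returns
# coefficients and residual covariance of the implied reduced regression.
autocov_to_var_yw <- function(G, p) {
  m <- nrow(G[[1]])
  R <- matrix(0, m * p, m * p)
  C <- matrix(0, m, m * p)
  for (i in 1:p) {
    C[, ((i - 1) * m + 1):(i * m)] <- G[[i + 1L]]
    for (j in 1:p) {
      lag <- j - i   # Cov(X_{t-i}, X_{t-j}) = G(j - i) for j >= i
      blk <- if (lag >= 0) G[[lag + 1L]] else t(G[[-lag + 1L]])
      R[((i - 1) * m + 1):(i * m), ((j - 1) * m + 1):(j * m)] <- blk
    }
  }
  Rs <- (R + t(R)) / 2
  ok <- tryCatch({ chol(Rs); TRUE }, error = function(e) FALSE)
  if (!ok) stop("autocovariance sequence not positive-definite")
  Astack <- C %*% solve(Rs)
  Sigma <- G[[1]]
  for (j in 1:p) {
    Aj <- Astack[, ((j - 1) * m + 1):(j * m), drop = FALSE]
    Sigma <- Sigma - Aj %*% t(G[[j + 1L]])
  }
  A <- array(0, c(m, m, p))
  for (j in 1:p) A[, , j] <- Astack[, ((j - 1) * m + 1):(j * m)]
  list(A = A, Sigma = (Sigma + t(Sigma)) / 2)
}

#' Pairwise-conditional spectral Granger causality for three sites
#'
#' Demeans the signals, fits a trivariate VAR(k) by OLS, verifies
#' stability, derives the model-implied autocovariance sequence, and for
#' each ordered pair computes Geweke's conditional spectral measure given
#' the remaining site. The reduced (target + conditioning) model is
#' obtained from the autocovariance sequence by solving the block
#' Yule-Walker equations at order `reduced_order`, so full and reduced
#' models describe the same process. Defaults are desk-scale
#' (`autocov_lags = 200`, `reduced_order = 20`); both are configurable.
#'
#' @param signals An n x 3 matrix (columns = sites), a list of 3 vectors,
#'   or a list of n x 3 epoch matrices.
#' @param k Full-model order.
#' @param sampling_rate Hz.
#' @param freqs Frequency grid, Hz.
#' @param autocov_lags Autocovariance sequence length.
#' @param reduced_order Order of the reduced Yule-Walker model.
#' @return A list of class `conditional_gc`: `freqs`, `gc` (6 x nf matrix,
#'   rownames like `"1->2|3"`), `order`, `spectral_radius`.
#' @export
multivariate_gc <- function(signals, k, sampling_rate,
                            freqs = seq(1, 20, by = 0.5),
                            autocov_lags = 200, reduced_order = 20) {
  if (is.list(signals) && !is.matrix(signals[[1]]) &&
      length(signals) == 3L && is.numeric(signals[[1]])) {
    signals <- do.call(cbind, signals)
  }
  fit <- var_fit_ols(signals, k)
  if (fit$m != 3L) stop("need exactly 3 aligned signals")
  rho <- check_var_stable(fit$A)
  n_lags <- max(autocov_lags, reduced_order, k)
  G <- var_autocov(fit$A, fit$Sigma, n_lags)
  nf <- length(freqs)
  out <- matrix(NA_real_, 6, nf)
  labels <- character(6)
  row <- 0L
  for (src in 1:3) for (tgt in 1:3) {
    if (src == tgt) next
    cond <- setdiff(1:3, c(src, tgt))
    row <- row + 1L
    labels[row] <- sprintf("%d->%d|%d", src, tgt, cond)
    perm <- c(tgt, src, cond)                 # target, source, conditioning
    Ap <- fit$A[perm, perm, , drop = FALSE]
    Sp <- fit$Sigma[perm, perm]
    H <- var_transfer(Ap, freqs, sampling_rate)
    L <- t(chol(Sp))                          # Sp = L L'
    # reduced model on (target, conditioning)
    Gr <- lapply(G, function(g) g[c(tgt, cond), c(tgt, cond), drop = FALSE])
    red <- autocov_to_var_yw(Gr, reduced_order)
    sig_r <- red$Sigma[1, 1]
    Hr <- var_transfer(red$A, freqs, sampling_rate)
    for (i in seq_len(nf)) {
      Hn <- H[[i]] %*% L
      Gf <- Hr[[i]]
      G3 <- matrix(0 + 0i, 3, 3)
      G3[1, 1] <- Gf[1, 1]; G3[1, 3] <- Gf[1, 2]
      G3[3, 1] <- Gf[2, 1]; G3[3, 3] <- Gf[2, 2]
      G3[2, 2] <- 1
      Q <- solve(G3, Hn)
      out[row, i] <- max(log(sig_r / Mod(Q[1, 1])^2), 0)
    }
  }
  rownames(out) <- labels
  structure(list(freqs = freqs, gc = out, order = k,
                 spectral_radius = rho),
            class = "conditional_gc")
}
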