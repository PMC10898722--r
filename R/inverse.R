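# eLORETA inverse: baseline noise covariance, weighted minimum-norm operator
# with the eLORETA fixed-point weights, and application to epochs.

#' Noise covariance from pre-wind baseline segments
#'
#' Empirical channel covariance pooled over the baseline windows of all
#' retained trials, then shrunk toward a scaled identity:
#' `(1 - lambda) C + lambda * (tr(C)/n) I`. Average-referenced EEG has a
#' rank-deficient covariance, so a positive shrinkage is required for a
#' positive-definite result.
#'
#' @param baseline An `epoch_segments` object (channels x samples x trials)
#'   or a plain matrix of channels x samples.
#' @param shrinkage Shrinkage weight `lambda` in \[0, 1\].
#' @return Object of class `noise_cov`: `matrix` (channels x channels),
#'   `n_samples`, `shrinkage`.
#' @export
compute_noise_covariance <- function(baseline, shrinkage = 0.1) {
  x <- if (inherits(baseline, "epoch_segments")) {
    d <- dim(baseline$data)
    if (d[3] < 2) stop_invalid("need at least 2 baseline segments")
    matrix(baseline$data, d[1])
  } else as.matrix(baseline)
  if (shrinkage < 0 || shrinkage > 1)
    stop_invalid("`shrinkage` must be in [0, 1]")
  n <- ncol(x)
  x <- x - rowMeans(x)
  C <- tcrossprod(x) / (n - 1)
  Cs <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / nrow(C)) * diag(nrow(C))
  if (shrinkage == 0) {
    ev <- eigen(Cs, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))
      stop_invalid("numerical error: covariance is rank deficient; ",
                   "use shrinkage > 0")
  }
  structure(list(matrix = Cs, n_samples = n, shrinkage = shrinkage),
            class = "noise_cov")
}

#' Compute the eLORETA inverse operator
#'
#' Fixed-orientation eLORETA: the lead field is whitened with the noise
#' covariance, and per-source weights `w_i` are iterated to the fixed point
#' `w_i = sqrt( l_i' (L W^-1 L' + alpha H)^+ l_i )` where `H` is the
#' average-reference projector, `^+` the Moore-Penrose pseudo-inverse, and
#' `alpha = tr(L W^-1 L') / (n_chan * alpha_snr^2)` (recomputed from the
#' current weights each iteration, so the operator is invariant to a joint
#' rescaling of data and noise covariance). The resulting kernel
#' `W^-1 L' (L W^-1 L' + alpha H)^+` maps whitened sensor data to source
#' amplitudes; the returned kernel includes the whitener, so it applies
#' directly to (average-referenced) channel data. This weighting gives exact
#' zero localization error for noiseless single point sources.
#'
#' @param forward A `forward_model`.
#' @param noise_cov A `noise_cov`, or `NULL` for an identity covariance
#'   (noiseless setting).
#' @param alpha_snr Regularization expressed as an assumed amplitude SNR;
#'   larger values mean less regularization.
#' @param tol Fixed-point stopping tolerance on the maximum relative weight
#'   change.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Object of class `inverse_operator`: `kernel` (sources x channels,
#'   applies to unwhitened data), `weights`, `alpha`, `iterations`,
#'   `residual`, `channel_names`.
#' @export
compute_eloreta_operator <- function(forward, noise_cov = NULL,
                                     alpha_snr = 3, tol = 1e-6,
                                     max_iter = 100) {
  L0 <- forward$lead_field
  nc <- nrow(L0)
  # sensor data entering the kernel are average-referenced; the model lead
  # field must live in the same subspace
  L0 <- L0 - matrix(colMeans(L0), nc, ncol(L0), byrow = TRUE)
  if (is.null(noise_cov)) {
    wh <- diag(nc)
  } else {
    e <- eigen(noise_cov$matrix, symmetric = TRUE)
    if (min(e$values) <= 0)
      stop_invalid("noise covariance must be positive definite (use shrinkage)")
    wh <- e$vectors %*% (1 / sqrt(e$values) * t(e$vectors))
  }
  L <- wh %*% L0
  H <- diag(nc) - matrix(1 / nc, nc, nc)

  ns <- ncol(L)
  w <- rep(1, ns)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Lw <- L * rep(1 / w, each = nc)          # L W^-1
    M <- tcrossprod(Lw, L)                   # L W^-1 L'
    alpha <- sum(diag(M)) / (nc * alpha_snr^2)
    Minv <- pinv(M + alpha * H)
    wnew <- sqrt(pmax(colSums(L * (Minv %*% L)), 0))
    if (any(wnew <= 0))
      stop_invalid("numerical error: a source weight collapsed to zero")
    res <- max(abs(wnew - w) / w)
    w <- wnew
    if (res < tol) break
  }
  if (res >= tol)
    stop_invalid(sprintf(
      "convergence error: eLORETA weights did not converge in %d iterations (residual %.2e)",
      max_iter, res))
  Lw <- L * rep(1 / w, each = nc)
  M <- tcrossprod(Lw, L)
  alpha <- sum(diag(M)) / (nc * alpha_snr^2)
  kernel <- t(Lw) %*% pinv(M + alpha * H) %*% wh
  structure(list(kernel = kernel, weights = w, alpha = alpha,
                 iterations = it, residual = res,
                 channel_names = forward$channel_names),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> eLORETA: %d sources x %d channels (converged in %d iterations)\n",
              nrow(x$kernel), ncol(x$kernel), x$iterations))
  invisible(x)
}

#' Apply an inverse operator to epochs
#'
#' Per trial, the channel mean over the baseline window is subtracted
#' (baseline correction of the channel EEG) before the kernel is applied.
#'
#' @param analysis `epoch_segments` with the analysis windows.
#' @param operator An `inverse_operator`.
#' @param baseline Matching `epoch_segments` with the baseline windows, or
#'   `NULL` to skip baseline correction.
#' @return Array sources x samples x trials of estimated source amplitudes.
#' @export
apply_inverse <- function(analysis, operator, baseline = NULL) {
  d <- dim(analysis$data)
  if (d[1] != ncol(operator$kernel))
    stop_invalid("channel dimension of epochs does not match the operator")
  if (!is.null(baseline) && dim(baseline$data)[3] != d[3])
    stop_invalid("baseline and analysis segments have different trial counts")
  out <- array(0, c(nrow(operator$kernel), d[2], d[3]))
  for (i in seq_len(d[3])) {
    x <- analysis$data[, , i]
    if (!is.null(baseline))
      x <- x - rowMeans(baseline$data[, , i])
    out[, , i] <- operator$kernel %*% x
  }
  out
}
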