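# Canonical analysis bands. Edges are half-open [lo, hi) so 4, 8, 12, 30 Hz
# are not double-counted; gamma is closed at 50 Hz.
FREQ_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                   beta = c(12, 30), gamma = c(30, 50))

band_members <- function(freqs) {
  lapply(seq_along(FREQ_BANDS), function(b) {
    lim <- FREQ_BANDS[[b]]
    if (names(FREQ_BANDS)[b] == "gamma") which(freqs >= lim[1] & freqs <= lim[2])
    else which(freqs >= lim[1] & freqs < lim[2])
  })
}

#' Fit a multivariate autoregressive model by least squares
#'
#' Channels are mean-centered, then each time point is regressed on the `p`
#' previous time points of all channels jointly (no intercept). The residual
#' covariance uses the bias-corrected divisor `n_obs - C * p`.
#'
#' @param epoch channels-by-samples numeric matrix.
#' @param p model order.
#' @return object of class `mvar_fit`: `order`, `coeffs` (p x C x C array),
#'   `residual_cov`, `n_obs`, `sbc`, `channels`.
#' @export
fit_mvar <- function(epoch, p) {
  x <- as.matrix(epoch)
  C <- nrow(x); N <- ncol(x)
  stopifnot(p >= 1)
  if (N <= p) stop("epoch too short: N must exceed the model order")
  n_obs <- N - p
  if (n_obs <= C * p)
    stop("too few observations to identify a VAR(", p, ") with ", C,
         " channels; use a smaller order")
  x <- x - rowMeans(x)
  # regressors: row t has [x(t-1); x(t-2); ... x(t-p)] stacked
  Y <- t(x[, (p + 1):N, drop = FALSE])               # n_obs x C
  Z <- matrix(0, n_obs, C * p)
  for (k in seq_len(p))
    Z[, (k - 1) * C + seq_len(C)] <- t(x[, (p + 1 - k):(N - k), drop = FALSE])
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("rank-deficient regressor matrix; try a smaller model order")
  B <- qr.coef(qrz, Y)                               # (C*p) x C
  E <- Y - Z %*% B
  sigma <- crossprod(E) / (n_obs - C * p)
  A <- array(0, dim = c(p, C, C))
  for (k in seq_len(p)) A[k, , ] <- t(B[(k - 1) * C + seq_len(C), , drop = FALSE])
  fit <- structure(list(order = p, n_channels = C, coeffs = A,
                        residual_cov = sigma, n_obs = n_obs,
                        channels = rownames(epoch) %||% paste0("ch", seq_len(C))),
                   class = "mvar_fit")
  fit$sbc <- sbc(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Schwarz Bayesian criterion of a fitted MVAR model
#'
#' `SBC(p) = ln det(Sigma_hat) + (ln n_obs / n_obs) * p * C^2`; additive
#' terms independent of the order are dropped (the argmin is unchanged).
#'
#' @param fit an `mvar_fit`.
#' @export
sbc <- function(fit) {
  S <- (fit$residual_cov + t(fit$residual_cov)) / 2
  ld <- tryCatch(2 * sum(log(diag(chol(S)))), error = function(e) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev <= 0)) stop("singular residual covariance; SBC undefined")
    sum(log(pmax(ev, max(ev) * 1e-12)))
  })
  ld + (log(fit$n_obs) / fit$n_obs) * fit$order * fit$n_channels^2
}

#' Select the MVAR order by minimum mean SBC across epochs
#'
#' Scans orders `1..p_max` and returns the minimizer of the mean Schwarz
#' criterion over epochs. The pipeline's default analysis order stays fixed
#' (12) regardless; this reports what the data prefer.
#'
#' @param epochs list of channels-by-samples matrices.
#' @param p_max largest order scanned.
#' @return integer order.
#' @export
select_order <- function(epochs, p_max = 30) {
  stopifnot(length(epochs) >= 1)
  mean_sbc <- vapply(seq_len(p_max), function(p)
    mean(vapply(epochs, function(e) fit_mvar(e, p)$sbc, numeric(1))),
    numeric(1))
  p_hat <- which.min(mean_sbc)
  if (p_hat == p_max)
    warning("selected order equals p_max; the true order may be larger")
  p_hat
}

#' Spectral transfer matrix of an MVAR model
#'
#' `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`.
#'
#' @param fit an `mvar_fit` or `var_model`.
#' @param f frequency in Hz, `0 <= f < fs/2`.
#' @param fs sampling rate.
#' @return C x C complex matrix.
#' @export
transfer_matrix <- function(fit, f, fs = EEG_FS) {
  stopifnot(f >= 0, f < fs / 2)
  C <- fit$n_channels; p <- fit$order
  Abar <- diag(1 + 0i, C)
  for (k in seq_len(p))
    Abar <- Abar - fit$coeffs[k, , ] * exp(-2i * pi * f * k / fs)
  Abar
}

gpdc_matrix <- function(Abar, sigma2) {
  s <- sqrt(sigma2)
  num <- abs(Abar) / s                    # row i scaled by 1/sigma_i
  den <- sqrt(colSums(num^2))             # per source column
  sweep(num, 2L, den, "/")
}

#' Generalized partial directed coherence of one fitted model
#'
#' `gpdc[i, j](f) = (|Abar_ij(f)| / sigma_i) / sqrt(sum_k |Abar_kj(f)|^2 /
#' sigma_k^2)` — the noise-variance-normalized variant of partial directed
#' coherence, invariant to per-channel amplitude scaling. Every source
#' column satisfies `sum_i gpdc[i, j](f)^2 = 1`.
#'
#' @param fit an `mvar_fit` (or a `var_model`, for closed-form ground truth).
#' @param freqs frequency grid in Hz (default 1..50).
#' @param fs sampling rate.
#' @return object of class `gpdc_result`: `freqs`, `values` (C x C x F array,
#'   entry (i, j, f) is the influence j -> i), `band_means` (C x C x 5),
#'   `n_epochs = 1`, `channels`.
#' @export
gpdc <- function(fit, freqs = 1:50, fs = EEG_FS) {
  C <- fit$n_channels
  sigma2 <- if (!is.null(fit$residual_cov)) diag(fit$residual_cov)
            else diag(fit$noise_cov)
  if (any(sigma2 <= 0)) stop("degenerate channel: zero residual variance")
  vals <- array(0, dim = c(C, C, length(freqs)))
  for (fi in seq_along(freqs))
    vals[, , fi] <- gpdc_matrix(transfer_matrix(fit, freqs[fi], fs), sigma2)
  new_gpdc_result(freqs, vals, n_epochs = 1L,
                  channels = fit$channels %||% paste0("ch", seq_len(C)))
}

new_gpdc_result <- function(freqs, values, n_epochs, channels) {
  C <- dim(values)[1]
  bm <- array(NA_real_, dim = c(C, C, length(FREQ_BANDS)),
              dimnames = list(channels, channels, names(FREQ_BANDS)))
  mem <- band_members(freqs)
  for (b in seq_along(mem))
    if (length(mem[[b]]))
      bm[, , b] <- apply(values[, , mem[[b]], drop = FALSE], c(1, 2), mean)
  dimnames(values) <- list(channels, channels, NULL)
  structure(list(freqs = freqs, values = values, band_means = bm,
                 n_epochs = n_epochs, channels = channels),
            class = "gpdc_result")
}

#' @export
print.gpdc_result <- function(x, ...) {
  cat(sprintf("<gpdc_result> %d x %d channels, %d frequencies, %d epoch(s)\n",
              dim(x$values)[1], dim(x$values)[2], length(x$freqs), x$n_epochs))
  print(round(x$band_means[, , "alpha"], 3))
  invisible(x)
}

#' Session-level gPDC from clean epochs
#'
#' Fits one MVAR per 6-s epoch (short-time stationary approach), computes
#' gPDC magnitudes per epoch, and averages them pointwise across epochs;
#' band means are taken over the averaged spectra.
#'
#' @param epochset a `clean_epoch_set` (or plain list of epoch matrices).
#' @param p MVAR order (default 12, about 54 ms of history at 220 Hz).
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate.
#' @return a `gpdc_result` with `n_epochs` the number averaged.
#' @export
session_gpdc <- function(epochset, p = 12, freqs = 1:50, fs = EEG_FS) {
  epochs <- if (inherits(epochset, "clean_epoch_set")) epochset$epochs else epochset
  if (length(epochs) == 0L) stop("no clean epochs to analyze")
  acc <- NULL; channels <- NULL
  for (e in epochs) {
    g <- gpdc(fit_mvar(e, p), freqs, fs)
    acc <- if (is.null(acc)) g$values else acc + g$values
    channels <- g$channels
  }
  new_gpdc_result(freqs, acc / length(epochs), n_epochs = length(epochs),
                  channels = channels)
}

#' Long-format band means of a gPDC result
#'
#' One row per directed pair and band (`source != target`).
#'
#' @param g a `gpdc_result`.
#' @export
gpdc_band_table <- function(g) {
  ch <- g$channels
  rows <- expand.grid(target = ch, source = ch, band = names(FREQ_BANDS),
                      stringsAsFactors = FALSE)
  rows <- rows[rows$target != rows$source, ]
  rows$gpdc_mean <- mapply(function(i, j, b) g$band_means[i, j, b],
                           match(rows$target, ch), match(rows$source, ch),
                           rows$band)
  rows$n_epochs <- g$n_epochs
  rows[c("source", "target", "band", "gpdc_mean", "n_epochs")]
}
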