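# cache for Slepian tapers keyed by (N, nw, k)
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classical symmetric tridiagonal eigenproblem whose top
#' eigenvectors are the Slepian sequences; tapers are unit-energy and
#' orthogonal. Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time half-bandwidth product.
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  stopifnot(n > 2 * k, nw > 0)
  W <- nw / n
  tt <- 0:(n - 1)
  M <- diag(((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W))
  off <- tt[-1] * (n - tt[-1]) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  V <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    # fix polarity: symmetric tapers positive mean, antisymmetric positive slope
    if (j %% 2 == 1 && sum(V[, j]) < 0) V[, j] <- -V[, j]
    if (j %% 2 == 0 && sum(tt * V[, j]) < 0) V[, j] <- -V[, j]
  }
  .taper_cache[[key]] <- V
  V
}

#' Thomson multitaper power spectral density of one epoch channel
#'
#' Averages the `2 * nw - 1` Slepian eigenspectra (unweighted) of the
#' zero-padded signal. The one-sided density integrates to the signal
#' variance over `[0, fs/2]` (Parseval); the returned grid is restricted to
#' `[fmin, fmax]`.
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate.
#' @param nw time half-bandwidth product.
#' @param nfft FFT length (zero-padded; must be >= `length(x)`).
#' @param fmin,fmax returned frequency range in Hz.
#' @return list with `freqs` (Hz) and `psd` (uV^2/Hz).
#' @export
multitaper_psd <- function(x, fs = EEG_FS, nw = 4, nfft = 4096,
                           fmin = 1, fmax = 50) {
  N <- length(x)
  k <- 2 * nw - 1
  if (N < 2 * nw) stop("signal shorter than 2 * nw samples")
  if (nfft < N) stop("nfft must be at least the signal length")
  V <- dpss_tapers(N, nw, k)
  S <- numeric(nfft)
  for (j in seq_len(k)) {
    X <- stats::fft(c(x * V[, j], numeric(nfft - N)))
    S <- S + Mod(X)^2 / fs
  }
  S <- S / k
  half <- S[1:(nfft %/% 2 + 1)]
  half[2:(nfft %/% 2)] <- 2 * half[2:(nfft %/% 2)]   # one-sided doubling
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  keep <- freqs >= fmin & freqs <= fmax
  list(freqs = freqs[keep], psd = half[keep])
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts ordered template pairs of
#' length `m` within Chebyshev distance `r` (self-matches excluded, both
#' template lengths counted over the same index range `i <= N - m`) and `A`
#' the same for length `m + 1`. The tolerance is `r_factor` standard
#' deviations of the window, so the measure is exactly invariant under
#' affine rescaling `a * x + b` (a > 0). Returns `NA` (undefined) for
#' constant signals or when no template pair matches.
#'
#' @param x numeric vector.
#' @param m template length.
#' @param r_factor tolerance as a multiple of `sd(x)`.
#' @return scalar sample entropy, or `NA_real_` when undefined.
#' @export
sampen <- function(x, m = 2, r_factor = 0.2) {
  N <- length(x)
  if (N < m + 2) stop("need at least m + 2 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r_factor * s)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Session-level spectral and entropy features
#'
#' Per-epoch multitaper PSD and per-channel sample entropy, averaged across
#' the session's clean epochs. Epochs whose sample entropy is undefined on a
#' channel are excluded from that channel's mean, with the exclusion count
#' reported (per-channel inclusion can therefore differ).
#'
#' @param epochset a `clean_epoch_set` (or plain list of epoch matrices).
#' @param fs sampling rate.
#' @param nw,nfft multitaper parameters.
#' @param m,r_factor sample-entropy parameters.
#' @return list with `psd` (`freqs`, `psd` 4 x F matrix, `n_epochs`) and
#'   `sampen` (`values` per channel, `n_used` per channel, `params`).
#' @export
session_features <- function(epochset, fs = EEG_FS, nw = 4, nfft = 4096,
                             m = 2, r_factor = 0.2) {
  epochs <- if (inherits(epochset, "clean_epoch_set")) epochset$epochs else epochset
  if (length(epochs) == 0L) stop("no clean epochs to analyze")
  C <- nrow(epochs[[1]])
  channels <- rownames(epochs[[1]]) %||% paste0("ch", seq_len(C))
  psd_acc <- NULL; freqs <- NULL
  se_sum <- numeric(C); se_n <- integer(C)
  for (e in epochs) {
    for (ch in seq_len(C)) {
      mt <- multitaper_psd(e[ch, ], fs = fs, nw = nw, nfft = nfft)
      if (is.null(psd_acc)) {
        freqs <- mt$freqs
        psd_acc <- matrix(0, C, length(freqs))
      }
      psd_acc[ch, ] <- psd_acc[ch, ] + mt$psd
      se <- sampen(e[ch, ], m = m, r_factor = r_factor)
      if (!is.na(se)) {
        se_sum[ch] <- se_sum[ch] + se
        se_n[ch] <- se_n[ch] + 1L
      }
    }
  }
  se_vals <- ifelse(se_n > 0, se_sum / pmax(se_n, 1L), NA_real_)
  names(se_vals) <- channels
  list(
    psd = list(freqs = freqs, psd = psd_acc / length(epochs),
               n_epochs = length(epochs), channels = channels),
    sampen = list(values = se_vals, n_used = stats::setNames(se_n, channels),
                  n_excluded = length(epochs) - se_n,
                  params = list(m = m, r_factor = r_factor,
                                N = ncol(epochs[[1]])))
  )
}
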