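#' Preprocessing configuration
#'
#' Collects every tunable of the cleaning chain with the defaults used for
#' mobile four-channel recordings: a 60 Hz notch, a zero-phase 4th-order
#' Butterworth band-pass at 1-100 Hz, artifact subspace reconstruction with a
#' 10-SD cutoff over 500 ms windows stepped by 250 ms, a 0.75 single-channel
#' loading threshold, a 100 microvolt sample-to-sample jump threshold, a
#' 1 m/s^2 dynamic-acceleration threshold, a one-continuous-minute usability
#' rule, and 6-s epochs with 50% overlap.
#'
#' @param notch_hz,notch_q mains frequency and notch quality factor.
#' @param bandpass band edges in Hz.
#' @param butterworth_order analog prototype order of the band-pass.
#' @param asr_cutoff_sd robust z cutoff for artifact components.
#' @param asr_window_ms,asr_step_ms ASR sliding-window geometry.
#' @param asr_loading_thresh single-channel loading above which the channel
#'   subwindow is masked rather than reconstructed.
#' @param jump_thresh_uv absolute first-difference rejection threshold.
#' @param accel_thresh_ms2 dynamic acceleration magnitude threshold.
#' @param min_good_contact_s minimum contiguous all-good run for a usable
#'   session.
#' @param epoch_s,epoch_overlap epoch length (s) and fractional overlap.
#' @export
preproc_config <- function(notch_hz = 60, notch_q = 30, bandpass = c(1, 100),
                           butterworth_order = 4, asr_cutoff_sd = 10,
                           asr_window_ms = 500, asr_step_ms = 250,
                           asr_loading_thresh = 0.75, jump_thresh_uv = 100,
                           accel_thresh_ms2 = 1.0, min_good_contact_s = 60,
                           epoch_s = 6, epoch_overlap = 0.5) {
  cfg <- list(notch_hz = notch_hz, notch_q = notch_q, bandpass = bandpass,
              butterworth_order = butterworth_order,
              asr_cutoff_sd = asr_cutoff_sd, asr_window_ms = asr_window_ms,
              asr_step_ms = asr_step_ms, asr_loading_thresh = asr_loading_thresh,
              jump_thresh_uv = jump_thresh_uv, accel_thresh_ms2 = accel_thresh_ms2,
              min_good_contact_s = min_good_contact_s, epoch_s = epoch_s,
              epoch_overlap = epoch_overlap)
  with(cfg, {
    stopifnot(notch_hz > 0, notch_q > 0, length(bandpass) == 2,
              bandpass[1] > 0, bandpass[1] < bandpass[2],
              butterworth_order >= 1, asr_cutoff_sd > 0, asr_window_ms > 0,
              asr_step_ms > 0, asr_loading_thresh > 0, jump_thresh_uv > 0,
              accel_thresh_ms2 > 0, min_good_contact_s > 0, epoch_s > 0,
              epoch_overlap >= 0, epoch_overlap < 1)
  })
  if (cfg$bandpass[2] >= EEG_FS / 2)
    stop("band-pass upper edge must be below the Nyquist frequency (110 Hz)")
  structure(cfg, class = "preproc_config")
}

as_eeg_matrix <- function(eeg) {
  if (is.vector(eeg)) matrix(eeg, nrow = 1) else as.matrix(eeg)
}

#' Notch filter (zero-phase biquad)
#'
#' Second-order IIR notch applied forward-backward to each channel.
#'
#' @param eeg channels-by-samples matrix (or a vector).
#' @param f0 notch frequency in Hz.
#' @param fs sampling rate.
#' @param Q quality factor (bandwidth f0/Q).
#' @export
notch_filter <- function(eeg, f0 = 60, fs = EEG_FS, Q = 30) {
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist")
  x <- as_eeg_matrix(eeg)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
  if (is.vector(eeg)) drop(out) else out
}

#' Band-pass filter (zero-phase Butterworth)
#'
#' Digital Butterworth band-pass applied forward-backward (zero phase), so
#' the effective magnitude response is the squared response of the designed
#' filter.
#'
#' @param eeg channels-by-samples matrix (or a vector).
#' @param lo,hi band edges in Hz.
#' @param order Butterworth prototype order.
#' @param fs sampling rate.
#' @export
bandpass_filter <- function(eeg, lo = 1, hi = 100, order = 4, fs = EEG_FS) {
  if (hi >= fs / 2) stop("upper band edge must be below Nyquist (", fs / 2, " Hz)")
  if (lo <= 0 || lo >= hi) stop("require 0 < lo < hi")
  x <- as_eeg_matrix(eeg)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
  if (is.vector(eeg)) drop(out) else out
}

asr_geometry <- function(n, fs, config) {
  win <- round(config$asr_window_ms / 1000 * fs)
  step <- round(config$asr_step_ms / 1000 * fs)
  starts <- seq(1L, n - win + 1L, by = step)
  list(win = win, step = step, starts = starts,
       n_sub = ceiling(n / step), sub_len = step)
}

#' Artifact subspace reconstruction
#'
#' Sliding-window PCA cleaning. Calibration uses the whole session: the
#' element-wise median of 500 ms window covariances is eigendecomposed to
#' give a calibration basis, and the per-component RMS across windows gives
#' robust location (median) and scale (MAD) statistics. Each processing
#' window is then eigendecomposed in calibration space; components whose RMS
#' exceeds `location + cutoff * scale` (threshold rotated into the window
#' basis) are zeroed and the window reconstructed from the retained
#' components with raised-cosine overlap-add. When a flagged component loads
#' almost entirely (|loading| > 0.75) on a single channel, that channel's
#' subwindows are marked bad in the returned mask instead of being
#' reconstructed.
#'
#' @param eeg filtered channels-by-samples matrix, at least 60 s.
#' @param config a [preproc_config()].
#' @param fs sampling rate.
#' @return list with `eeg` (cleaned matrix) and `mask` (channels x
#'   subwindows logical, `TRUE` = masked bad by the loading rule).
#' @export
asr_clean <- function(eeg, config = preproc_config(), fs = EEG_FS) {
  x <- as.matrix(eeg)
  C <- nrow(x); n <- ncol(x)
  if (n / fs < config$min_good_contact_s)
    stop("ASR calibration requires at least ", config$min_good_contact_s,
         " s of data")
  g <- asr_geometry(n, fs, config)
  win <- g$win; starts <- g$starts

  # calibration: median window covariance and per-component RMS statistics
  covs <- array(0, dim = c(C, C, length(starts)))
  for (w in seq_along(starts)) {
    seg <- x[, starts[w]:(starts[w] + win - 1L), drop = FALSE]
    covs[, , w] <- tcrossprod(seg) / win
  }
  C0 <- apply(covs, c(1, 2), stats::median)
  V <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)$vectors
  Y <- crossprod(V, x)                        # calibration component space
  rms_w <- sapply(seq_along(starts), function(w)
    sqrt(rowMeans(Y[, starts[w]:(starts[w] + win - 1L), drop = FALSE]^2)))
  mu <- apply(rms_w, 1L, stats::median)
  sc <- apply(rms_w, 1L, stats::mad)
  thresh_cal <- mu + config$asr_cutoff_sd * sc

  acc <- matrix(0, C, n)
  wsum <- numeric(n)
  taper <- sin(pi * (seq_len(win) - 0.5) / win)^2
  mask <- matrix(FALSE, C, g$n_sub)

  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + win - 1L)
    Yw <- Y[, idx, drop = FALSE]
    ew <- eigen(tcrossprod(Yw) / win, symmetric = TRUE)
    U <- ew$vectors
    r_k <- sqrt(pmax(ew$values, 0))
    t_k <- sqrt(colSums(U^2 * thresh_cal^2))  # calibration threshold rotated
    flagged <- which(r_k > t_k)
    sub_ids <- unique(pmin(((idx - 1L) %/% g$step) + 1L, g$n_sub))
    drop_comp <- integer(0)
    for (k in flagged) {
      load <- V %*% U[, k]                    # channel-space loading, unit norm
      ch <- which.max(abs(load))
      if (abs(load[ch]) > config$asr_loading_thresh) {
        mask[ch, sub_ids] <- TRUE             # mask instead of reconstructing
      } else {
        drop_comp <- c(drop_comp, k)
      }
    }
    if (length(drop_comp)) {
      Ud <- U[, drop_comp, drop = FALSE]
      Yw <- Yw - Ud %*% crossprod(Ud, Yw)
    }
    Xw <- V %*% Yw
    acc[, idx] <- acc[, idx] + Xw * rep(taper, each = C)
    wsum[idx] <- wsum[idx] + taper
  }
  covered <- wsum > 1e-12
  out <- x
  out[, covered] <- acc[, covered] / rep(wsum[covered], each = C)
  list(eeg = out, mask = mask)
}

zoh_upsample_index <- function(n_hi, fs_hi, fs_lo, n_lo) {
  pmin(floor((seq_len(n_hi) - 1L) * fs_lo / fs_hi) + 1L, n_lo)
}

#' Rule-based rejection mask
#'
#' Partitions the session into 250 ms subwindows and marks a subwindow bad
#' when (a) any electrode's zero-order-hold-upsampled contact indicator is
#' not 1 (`contact`), (b) any channel's maximum absolute sample-to-sample
#' difference exceeds the jump threshold (`jump`), or (c) the upsampled
#' dynamic-acceleration magnitude (per-axis session median removed) exceeds
#' the motion threshold (`accel`). The session is usable only if some
#' contiguous all-good run lasts at least `min_good_contact_s`.
#'
#' @param eeg channels-by-samples matrix at 220 Hz.
#' @param accel 3-by-samples matrix at 50 Hz.
#' @param contact 4-by-samples indicator matrix at 10 Hz.
#' @param config a [preproc_config()].
#' @param fs EEG sampling rate.
#' @return list with `bad` (logical per subwindow), `reasons` (3 x
#'   subwindows logical matrix, rows `contact`, `jump`, `accel`), `usable`,
#'   `sub_len` (samples per subwindow).
#' @export
rejection_mask <- function(eeg, accel, contact, config = preproc_config(),
                           fs = EEG_FS) {
  x <- as.matrix(eeg); n <- ncol(x)
  sub_len <- round(config$asr_step_ms / 1000 * fs)
  n_sub <- ceiling(n / sub_len)
  sub_of <- pmin(((seq_len(n) - 1L) %/% sub_len) + 1L, n_sub)

  ci <- zoh_upsample_index(n, fs, CONTACT_FS, ncol(contact))
  contact_bad_s <- colSums(as.matrix(contact)[, ci, drop = FALSE] != 1) > 0

  d <- abs(x[, -1L, drop = FALSE] - x[, -n, drop = FALSE])
  jump_bad_s <- c(FALSE, colSums(d > config$jump_thresh_uv) > 0)  # diff at later sample

  dyn <- as.matrix(accel) - apply(as.matrix(accel), 1L, stats::median)
  mag <- sqrt(colSums(dyn^2))
  ai <- zoh_upsample_index(n, fs, ACCEL_FS, length(mag))
  accel_bad_s <- mag[ai] > config$accel_thresh_ms2

  agg <- function(bad_s) as.logical(tapply(bad_s, sub_of, any))
  reasons <- rbind(contact = agg(contact_bad_s),
                   jump = agg(jump_bad_s),
                   accel = agg(accel_bad_s))
  bad <- colSums(reasons) > 0

  need <- ceiling(config$min_good_contact_s * fs / sub_len)
  runs <- rle(!bad)
  usable <- any(runs$values & runs$lengths >= need)
  list(bad = bad, reasons = reasons, usable = usable, sub_len = sub_len)
}

#' Cut clean 6-s epochs
#'
#' Extracts fixed-length epochs (default 6 s, hop 3 s) starting on a regular
#' grid, keeping only epochs whose every covered subwindow is good. Epochs
#' never span masked regions.
#'
#' @param eeg cleaned channels-by-samples matrix.
#' @param bad logical per-subwindow mask (combined across all rules and
#'   channels); `TRUE` = bad.
#' @param config a [preproc_config()].
#' @param fs sampling rate.
#' @return object of class `clean_epoch_set`: `epochs` (list of C x 1320
#'   matrices), `epoch_start_samples`, `rejection_mask`, `kept_fraction`.
#' @export
cut_epochs <- function(eeg, bad, config = preproc_config(), fs = EEG_FS) {
  x <- as.matrix(eeg); n <- ncol(x)
  sub_len <- round(config$asr_step_ms / 1000 * fs)
  epoch_len <- round(config$epoch_s * fs)
  hop <- round(epoch_len * (1 - config$epoch_overlap))
  starts <- if (n >= epoch_len) seq(1L, n - epoch_len + 1L, by = hop) else integer(0)
  epochs <- list(); kept_starts <- integer(0)
  for (s in starts) {
    subs <- (((s - 1L) %/% sub_len) + 1L):(((s + epoch_len - 2L) %/% sub_len) + 1L)
    subs <- subs[subs <= length(bad)]
    if (!any(bad[subs])) {
      epochs[[length(epochs) + 1L]] <- x[, s:(s + epoch_len - 1L), drop = FALSE]
      kept_starts <- c(kept_starts, s)
    }
  }
  good_samples <- sum(!bad[pmin(((seq_len(n) - 1L) %/% sub_len) + 1L, length(bad))])
  if (length(epochs) == 0L)
    warning("no clean epochs in session")
  structure(list(epochs = epochs, epoch_start_samples = kept_starts,
                 rejection_mask = bad, kept_fraction = good_samples / n,
                 epoch_len = epoch_len),
            class = "clean_epoch_set")
}

#' @export
print.clean_epoch_set <- function(x, ...) {
  cat(sprintf("<clean_epoch_set> %d epochs of %d samples, kept fraction %.3f\n",
              length(x$epochs), x$epoch_len, x$kept_fraction))
  invisible(x)
}

#' Full preprocessing chain for one session
#'
#' Applies, in order: notch filter, band-pass filter, artifact subspace
#' reconstruction, rule-based rejection, epoch cutting. The ASR channel mask
#' and the rejection reasons are combined into the final per-subwindow mask
#' (a subwindow is bad if any channel or rule marks it).
#'
#' @param rec a [session_recording()].
#' @param config a [preproc_config()].
#' @return list with `epochs` (a `clean_epoch_set`), `usable`, `mask`
#'   components, and a one-row `report` data frame.
#' @export
preprocess_session <- function(rec, config = preproc_config()) {
  x <- notch_filter(rec$eeg, f0 = config$notch_hz, Q = config$notch_q)
  x <- bandpass_filter(x, lo = config$bandpass[1], hi = config$bandpass[2],
                       order = config$butterworth_order)
  asr <- asr_clean(x, config)
  rej <- rejection_mask(asr$eeg, rec$accel, rec$contact, config)
  n_sub <- length(rej$bad)
  asr_any <- colSums(asr$mask) > 0
  length(asr_any) <- n_sub                   # pad with NA if geometry differs
  asr_any[is.na(asr_any)] <- FALSE
  bad <- rej$bad | asr_any
  es <- cut_epochs(asr$eeg, bad, config)
  report <- data.frame(
    session_id = rec$session_id, participant_id = rec$participant_id,
    stage = rec$stage, duration_s = session_duration(rec),
    usable = rej$usable, n_epochs = length(es$epochs),
    kept_fraction = es$kept_fraction,
    n_sub_contact = sum(rej$reasons["contact", ]),
    n_sub_jump = sum(rej$reasons["jump", ]),
    n_sub_accel = sum(rej$reasons["accel", ]),
    n_sub_asr = sum(asr_any))
  list(epochs = es, usable = rej$usable, bad = bad, reasons = rej$reasons,
       asr_mask = asr$mask, report = report)
}
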