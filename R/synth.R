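#' Construct a stable VAR model with planted directed coupling
#'
#' Builds a vector-autoregressive system whose lag-1 coefficient matrix has
#' `base_diag` on the diagonal (per-channel persistence) and one off-diagonal
#' entry per requested directed edge; higher lags are zero unless an edge
#' specifies `lag > 1`. Stability is verified through the companion-matrix
#' spectral radius.
#'
#' @param edges data frame with columns `source`, `target` (channel names or
#'   1-based indices), `strength`, and optional `lag` (default 1), or `NULL`
#'   for no coupling.
#' @param base_diag scalar self-coupling placed on the diagonal of the lag-1
#'   matrix.
#' @param order model order p.
#' @param noise_sd innovation standard deviation, recycled to `n_channels`.
#' @param n_channels number of channels (default 4, the headset montage).
#' @param channels channel names.
#' @return object of class `var_model` with fields `order`, `coeffs`
#'   (array p x C x C; `coeffs[k, i, j]` is the influence of channel j at lag
#'   k on channel i), `noise_cov`, `channels`.
#' @export
make_var_model <- function(edges = NULL, base_diag = 0.5, order = 1,
                           noise_sd = 1, n_channels = 4,
                           channels = EEG_CHANNELS[seq_len(n_channels)]) {
  C <- n_channels
  stopifnot(order >= 1, length(channels) == C)
  A <- array(0, dim = c(order, C, C))
  diag_idx <- cbind(rep(1L, C), seq_len(C), seq_len(C))
  A[diag_idx] <- base_diag
  if (!is.null(edges) && nrow(edges) > 0) {
    ix <- function(v) if (is.numeric(v)) as.integer(v) else match(v, channels)
    src <- ix(edges$source); tgt <- ix(edges$target)
    lag <- if ("lag" %in% names(edges)) as.integer(edges$lag) else rep(1L, nrow(edges))
    if (anyNA(src) || anyNA(tgt)) stop("unknown channel in edge spec")
    if (any(lag < 1 | lag > order)) stop("edge lag outside 1..order")
    A[cbind(lag, tgt, src)] <- edges$strength
  }
  noise_sd <- rep_len(noise_sd, C)
  model <- structure(list(order = order, n_channels = C,
                          coeffs = A, noise_cov = diag(noise_sd^2, C),
                          channels = channels),
                     class = "var_model")
  rho <- var_spectral_radius(model)
  if (rho >= 1)
    stop(sprintf("unstable VAR model: companion spectral radius %.4f >= 1", rho))
  model$spectral_radius <- rho
  model
}

#' Companion-matrix spectral radius of a VAR model
#' @param model a `var_model` (or any list with `order`, `n_channels`, `coeffs`).
#' @export
var_spectral_radius <- function(model) {
  p <- model$order; C <- model$n_channels
  comp <- matrix(0, C * p, C * p)
  for (k in seq_len(p)) comp[seq_len(C), (k - 1) * C + seq_len(C)] <- model$coeffs[k, , ]
  if (p > 1) comp[C + seq_len(C * (p - 1)), seq_len(C * (p - 1))] <- diag(C * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a VAR process
#'
#' Draws Gaussian innovations and iterates
#' `x(t) = sum_k A_k x(t-k) + eps(t)`; the first `10 * order` burn-in samples
#' are discarded so the returned series is (approximately) stationary.
#' Deterministic given `seed`.
#'
#' @param model a `var_model`.
#' @param n_samples samples to return (must exceed `10 * order`).
#' @param seed integer RNG seed.
#' @return numeric matrix C x n_samples.
#' @export
simulate_var <- function(model, n_samples, seed) {
  p <- model$order; C <- model$n_channels
  if (n_samples <= 10 * p) stop("n_samples must exceed 10 * order")
  burn <- 10L * p
  n_tot <- n_samples + burn
  L <- t(chol(model$noise_cov))
  set.seed(seed)
  eps <- L %*% matrix(stats::rnorm(C * n_tot), C, n_tot)
  A <- lapply(seq_len(p), function(k) model$coeffs[k, , , drop = TRUE])
  if (C == 1) A <- lapply(A, function(a) matrix(a, 1, 1))
  x <- simulate_var_cpp(A, eps, p)
  x[, (burn + 1):n_tot, drop = FALSE]
}

#' Describe the artifacts to plant in a synthetic session
#'
#' @param bursts data frame `start_s`, `dur_s` of high-amplitude motion
#'   bursts (EEG burst plus a co-occurring accelerometer spike), or `NULL`.
#' @param burst_amp_uv EEG burst scale in microvolts.
#' @param burst_accel_ms2 amplitude of the accompanying acceleration spike.
#' @param line_noise_uv amplitude of the 60 Hz mains sinusoid added to every
#'   channel.
#' @param dropouts data frame `electrode` (1..4), `start_s`, `dur_s` during
#'   which the contact indicator reads bad (3).
#' @export
artifact_plan <- function(bursts = NULL, burst_amp_uv = 500,
                          burst_accel_ms2 = 3, line_noise_uv = 0,
                          dropouts = NULL) {
  stopifnot(burst_amp_uv >= 0, burst_accel_ms2 >= 0, line_noise_uv >= 0)
  structure(list(bursts = bursts, burst_amp_uv = burst_amp_uv,
                 burst_accel_ms2 = burst_accel_ms2,
                 line_noise_uv = line_noise_uv, dropouts = dropouts),
            class = "artifact_plan")
}

check_intervals <- function(iv, duration_s, what) {
  if (is.null(iv) || nrow(iv) == 0) return(invisible())
  if (any(iv$start_s < 0) || any(iv$start_s + iv$dur_s > duration_s))
    stop(what, " interval outside session duration")
}

interval_samples <- function(start_s, dur_s, fs, n) {
  i0 <- floor(start_s * fs) + 1L
  i1 <- min(ceiling((start_s + dur_s) * fs), n)
  i0:i1
}

# Tukey envelope: raised-cosine on/off ramps over `alpha/2` of the length at
# each end, flat in between; motion bursts switch on and off quickly.
tukey_env <- function(nlen, alpha = 0.2) {
  u <- (seq_len(nlen) - 1) / (nlen - 1)
  env <- rep(1, nlen)
  lo <- u < alpha / 2
  hi <- u > 1 - alpha / 2
  env[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  env[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / alpha - 1)))
  env
}

#' Generate one synthetic session recording
#'
#' EEG is a simulated VAR process rescaled so each channel has the requested
#' root-mean-square amplitude, plus optional 60 Hz line noise and
#' amplitude-modulated broadband burst artifacts with a fixed (random but
#' seed-determined) spatial pattern. Acceleration is low-level Gaussian
#' jitter with spikes co-occurring with the bursts; gravity is excluded
#' (dynamic acceleration only). Contact reads 1 everywhere except planted
#' dropouts, where it reads 3.
#'
#' @param model a `var_model` (4 channels).
#' @param duration_s session length in seconds (>= 66 so at least one clean
#'   minute plus filter edges fits).
#' @param plan an [artifact_plan()].
#' @param stage `"Preparation"` or `"Generation"`.
#' @param seed integer RNG seed.
#' @param session_id,participant_id identifiers.
#' @param eeg_rms_uv per-channel RMS of the artifact-free EEG, in microvolts.
#' @return a [session_recording()].
#' @export
generate_session <- function(model, duration_s = 66, plan = artifact_plan(),
                             stage = "Preparation", seed = 1,
                             session_id = "S001", participant_id = "P001",
                             eeg_rms_uv = 20) {
  stopifnot(model$n_channels == 4)
  if (duration_s < 66) stop("duration_s must be >= 66 (one clean minute plus margins)")
  n_e <- round(duration_s * EEG_FS)
  n_a <- round(duration_s * ACCEL_FS)
  n_c <- round(duration_s * CONTACT_FS)
  check_intervals(plan$bursts, duration_s, "burst")
  check_intervals(plan$dropouts, duration_s, "dropout")

  x <- simulate_var(model, n_e, seed = seed)
  x <- x * (eeg_rms_uv / sqrt(rowMeans(x^2)))
  tt <- (seq_len(n_e) - 1) / EEG_FS
  if (plan$line_noise_uv > 0)
    x <- x + rep(plan$line_noise_uv * sin(2 * pi * 60 * tt), each = 4)

  set.seed(seed + 1L)
  accel <- matrix(stats::rnorm(3 * n_a, sd = 0.1 / sqrt(3)), 3, n_a)

  planted_bad <- rep(FALSE, n_e)
  if (!is.null(plan$bursts) && nrow(plan$bursts) > 0) {
    for (b in seq_len(nrow(plan$bursts))) {
      s0 <- plan$bursts$start_s[b]; d0 <- plan$bursts$dur_s[b]
      ie <- interval_samples(s0, d0, EEG_FS, n_e)
      env <- tukey_env(length(ie))
      pat <- stats::rnorm(4); pat <- pat / sqrt(sum(pat^2))
      x[, ie] <- x[, ie] + outer(pat, plan$burst_amp_uv * env * stats::rnorm(length(ie)))
      ia <- interval_samples(s0, d0, ACCEL_FS, n_a)
      accel[1, ia] <- accel[1, ia] + plan$burst_accel_ms2 * tukey_env(length(ia))
      planted_bad[ie] <- TRUE
    }
  }

  contact <- matrix(1L, 4, n_c)
  if (!is.null(plan$dropouts) && nrow(plan$dropouts) > 0) {
    for (d in seq_len(nrow(plan$dropouts))) {
      ic <- interval_samples(plan$dropouts$start_s[d], plan$dropouts$dur_s[d],
                             CONTACT_FS, n_c)
      contact[plan$dropouts$electrode[d], ic] <- 3L
      planted_bad[interval_samples(plan$dropouts$start_s[d],
                                   plan$dropouts$dur_s[d], EEG_FS, n_e)] <- TRUE
    }
  }

  rec <- session_recording(x, accel, contact, session_id, participant_id, stage,
                           start_time = "1970-01-01T00:00:00Z")
  # ground-truth sample mask of the planted artifacts (EEG-rate), for
  # recall/false-alarm evaluation of the cleaning chain
  rec$planted_bad <- planted_bad
  rec
}

#' Generate a two-stage cohort of synthetic sessions on disk
#'
#' Writes `n_sessions_per_stage` sessions per stage, each simulated from the
#' stage's VAR model with a per-session seed derived deterministically from
#' the master seed, plus a manifest CSV and a ground-truth CSV of the planted
#' directed edges (`stage,source,target,strength,lag`).
#'
#' @param n_sessions_per_stage sessions per stage.
#' @param prep_model,gen_model `var_model` for each stage.
#' @param dir output directory.
#' @param seed master seed.
#' @param duration_s session length (default 66 s).
#' @param plan an [artifact_plan()] applied to every session.
#' @param prep_edges,gen_edges edge data frames recorded as ground truth
#'   (what was planted in each model); may be `NULL`.
#' @return list with `manifest` (a `session_manifest`) and `ground_truth`.
#' @export
make_stage_cohort <- function(n_sessions_per_stage, prep_model, gen_model,
                              dir, seed = 1, duration_s = 66,
                              plan = artifact_plan(),
                              prep_edges = NULL, gen_edges = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); k <- 0L
  for (stage in STAGES) {
    model <- if (stage == "Preparation") prep_model else gen_model
    for (i in seq_len(n_sessions_per_stage)) {
      k <- k + 1L
      sid <- sprintf("%s%03d", substr(stage, 1, 1), i)
      rec <- generate_session(model, duration_s = duration_s, plan = plan,
                              stage = stage, seed = (seed + 7919L * k) %% .Machine$integer.max,
                              session_id = sid,
                              participant_id = sprintf("P%03d", i))
      paths <- write_session(rec, dir)
      rows[[k]] <- data.frame(session_id = sid, participant_id = rec$participant_id,
                              stage = stage,
                              eeg_file = basename(paths["eeg_file"]),
                              accel_file = basename(paths["accel_file"]),
                              contact_file = basename(paths["contact_file"]),
                              duration_s = duration_s)
    }
  }
  m <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(m, manifest_path)
  gt <- rbind(
    if (!is.null(prep_edges) && nrow(prep_edges))
      cbind(stage = "Preparation", normalize_edges(prep_edges)),
    if (!is.null(gen_edges) && nrow(gen_edges))
      cbind(stage = "Generation", normalize_edges(gen_edges))
  )
  if (!is.null(gt))
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  list(manifest = read_manifest(manifest_path), ground_truth = gt)
}

normalize_edges <- function(edges) {
  e <- as.data.frame(edges)
  if (!"lag" %in% names(e)) e$lag <- 1L
  e[c("source", "target", "strength", "lag")]
}
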