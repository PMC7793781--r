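#' @useDynLib gpdcpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Fixed acquisition constants of the four-channel headset data model.
EEG_FS <- 220
ACCEL_FS <- 50
CONTACT_FS <- 10
EEG_CHANNELS <- c("TP09", "AF07", "AF08", "TP10")
STAGES <- c("Preparation", "Generation")

#' Construct a session recording
#'
#' Bundles the three multirate streams of one recording session: four EEG
#' channels at 220 Hz (microvolts), triaxial head acceleration at 50 Hz
#' (m/s^2), and a per-electrode contact-quality indicator at 10 Hz
#' (1 = good, 2 = acceptable, >= 3 = bad). Streams are aligned by sample
#' index from a common session start; channel order is fixed as
#' TP09, AF07, AF08, TP10.
#'
#' @param eeg numeric matrix, 4 x T_e, microvolts at 220 Hz.
#' @param accel numeric matrix, 3 x T_a, m/s^2 at 50 Hz.
#' @param contact integer matrix, 4 x T_c, contact indicator at 10 Hz.
#' @param session_id,participant_id character identifiers.
#' @param stage `"Preparation"` or `"Generation"`.
#' @param start_time session start, any value printable by `format()`.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(eeg, accel, contact, session_id, participant_id,
                              stage, start_time = Sys.time()) {
  eeg <- as.matrix(eeg); accel <- as.matrix(accel); contact <- as.matrix(contact)
  if (nrow(eeg) != 4L) stop("eeg must have 4 rows (channels ",
                            paste(EEG_CHANNELS, collapse = ", "), ")")
  if (nrow(accel) != 3L) stop("accel must have 3 rows (ax, ay, az)")
  if (nrow(contact) != 4L) stop("contact must have 4 rows (one per electrode)")
  if (anyNA(eeg)) stop("eeg contains NA/NaN")
  if (anyNA(contact) || any(contact < 1) || any(contact != round(contact)))
    stop("contact values must be integers >= 1")
  stage <- match.arg(stage, STAGES)
  durs <- c(ncol(eeg) / EEG_FS, ncol(accel) / ACCEL_FS, ncol(contact) / CONTACT_FS)
  if (any(durs <= 0)) stop("zero-length recording rejected")
  # streams must agree on duration within one period of the coarsest stream
  if (max(durs) - min(durs) > 1 / CONTACT_FS + 1e-9)
    stop(sprintf("stream durations disagree: eeg %.3f s, accel %.3f s, contact %.3f s",
                 durs[1], durs[2], durs[3]))
  rownames(eeg) <- EEG_CHANNELS
  rownames(accel) <- c("ax", "ay", "az")
  rownames(contact) <- paste0("cq_", EEG_CHANNELS)
  structure(list(
    session_id = as.character(session_id),
    participant_id = as.character(participant_id),
    stage = stage,
    eeg = eeg, accel = accel, contact = contact,
    start_time = start_time
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s  participant %s  stage %s\n",
              x$session_id, x$participant_id, x$stage))
  cat(sprintf("  eeg %d samples (%.2f s @ %d Hz), accel %d @ %d Hz, contact %d @ %d Hz\n",
              ncol(x$eeg), ncol(x$eeg) / EEG_FS, EEG_FS,
              ncol(x$accel), ACCEL_FS, ncol(x$contact), CONTACT_FS))
  invisible(x)
}

#' Session duration in seconds
#' @param rec a `session_recording`.
#' @export
session_duration <- function(rec) ncol(rec$eeg) / EEG_FS

read_stream_csv <- function(path, expected_cols, fs) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  want <- c("time_s", expected_cols)
  if (!identical(names(df), want))
    stop(sprintf("%s: expected columns [%s], found [%s]",
                 path, paste(want, collapse = ","), paste(names(df), collapse = ",")))
  for (nm in want) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[nm]])))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, nm, if (is.na(bad)) NA_integer_ else bad))
    }
  }
  t(as.matrix(df[expected_cols]))
}

#' Read one session from its three stream files
#'
#' Files are plain CSV, one per stream, with a `time_s` column followed by the
#' stream's channels (`TP09,AF07,AF08,TP10` for EEG, `ax,ay,az` for
#' acceleration, `cq_TP09,...` for contact quality).
#'
#' @param eeg_file,accel_file,contact_file file paths.
#' @param session_id,participant_id,stage session metadata.
#' @return a [session_recording()].
#' @export
read_session <- function(eeg_file, accel_file, contact_file,
                         session_id, participant_id, stage) {
  eeg <- read_stream_csv(eeg_file, EEG_CHANNELS, EEG_FS)
  accel <- read_stream_csv(accel_file, c("ax", "ay", "az"), ACCEL_FS)
  contact <- read_stream_csv(contact_file, paste0("cq_", EEG_CHANNELS), CONTACT_FS)
  durs <- c(ncol(eeg) / EEG_FS, ncol(accel) / ACCEL_FS, ncol(contact) / CONTACT_FS)
  if (max(durs) - min(durs) > 1 / CONTACT_FS + 1e-9)
    stop(sprintf("stream sampling-rate mismatch across %s / %s / %s (durations %.3f/%.3f/%.3f s)",
                 eeg_file, accel_file, contact_file, durs[1], durs[2], durs[3]))
  session_recording(eeg, accel, contact, session_id, participant_id, stage)
}

write_stream_csv <- function(mat, fs, path, digits = 9) {
  tt <- (seq_len(ncol(mat)) - 1L) / fs
  df <- cbind(time_s = tt, t(mat))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- apply(df, 1L, function(r)
    paste(sprintf("%.*g", digits, r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Write a session to a directory as three CSV stream files
#'
#' Values are serialized with nine significant digits so a
#' write/read round trip is lossless at analysis precision.
#'
#' @param rec a `session_recording`.
#' @param dir output directory (created if absent).
#' @return named character vector with `eeg_file`, `accel_file`, `contact_file`.
#' @export
write_session <- function(rec, dir) {
  stopifnot(inherits(rec, "session_recording"))
  if (ncol(rec$eeg) == 0L) stop("zero-length recording rejected")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    eeg_file = file.path(dir, paste0(rec$session_id, "_eeg.csv")),
    accel_file = file.path(dir, paste0(rec$session_id, "_accel.csv")),
    contact_file = file.path(dir, paste0(rec$session_id, "_contact.csv"))
  )
  write_stream_csv(rec$eeg, EEG_FS, paths["eeg_file"])
  write_stream_csv(rec$accel, ACCEL_FS, paths["accel_file"])
  write_stream_csv(rec$contact, CONTACT_FS, paths["contact_file"])
  paths
}

MANIFEST_COLS <- c("session_id", "participant_id", "stage",
                   "eeg_file", "accel_file", "contact_file", "duration_s")

#' Read / write a session manifest
#'
#' The manifest is a CSV listing one row per session with its stream file
#' paths and duration. Relative file paths are resolved against the
#' manifest's own directory.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced stream files exist.
#' @return data frame with class `session_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!identical(names(m), MANIFEST_COLS))
    stop(sprintf("%s: expected columns [%s]", path, paste(MANIFEST_COLS, collapse = ",")))
  m$duration_s <- as.numeric(m$duration_s)
  bad_stage <- setdiff(unique(m$stage), STAGES)
  if (length(bad_stage))
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
         " (expected Preparation or Generation)")
  dup <- unique(m$session_id[duplicated(m$session_id)])
  if (length(dup)) stop("duplicate session_id(s): ", paste(dup, collapse = ", "))
  base <- dirname(normalizePath(path, mustWork = FALSE))
  for (col in c("eeg_file", "accel_file", "contact_file")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
    if (check_files && !all(file.exists(m[[col]])))
      stop("missing files referenced by manifest: ",
           paste(m[[col]][!file.exists(m[[col]])], collapse = ", "))
  }
  class(m) <- c("session_manifest", class(m))
  m
}

#' @rdname read_manifest
#' @param m a `session_manifest` data frame.
#' @export
write_manifest <- function(m, path) {
  stopifnot(all(MANIFEST_COLS %in% names(m)))
  out <- as.data.frame(m)[MANIFEST_COLS]
  out$duration_s <- sprintf("%.9g", out$duration_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one manifest row as a session recording
#' @param m a `session_manifest`.
#' @param i row index or session_id.
#' @export
load_manifest_session <- function(m, i) {
  if (is.character(i)) i <- match(i, m$session_id)
  read_session(m$eeg_file[i], m$accel_file[i], m$contact_file[i],
               m$session_id[i], m$participant_id[i], m$stage[i])
}
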