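#' Standard 10/20 montage used throughout the pipeline
#'
#' The fifteen electrode sites the study montage records, in recording order.
#'
#' @return Character vector of channel labels.
#' @export
standard_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7",
    "Cz", "T8", "P7", "Pz", "P8", "O1", "O2")
}

#' Channels carrying the emotion-related signal
#'
#' Electrode subset over frontal, temporal, central and occipital sites whose
#' features feed the emotion-trajectory construction.
#'
#' @return Character vector of channel labels.
#' @export
emotion_channels <- function() {
  c("Fp1", "F7", "T7", "Cz", "T8", "P8", "O2")
}

#' Construct an EEG recording object
#'
#' The basic container of the pipeline: a channels-by-samples signal matrix
#' with sampling rate and montage metadata.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param meta Free-form provenance list (condition, seed, latent state, ...).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("`fs` must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("row count of `data` must equal the number of channel labels")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$meta$condition)) cat("  condition:", x$meta$condition, "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write a recording to CSV with a JSON sidecar
#'
#' The CSV stores the signal with one column per channel (header row carries
#' the channel labels) and one row per sample; the sidecar records sampling
#' rate, condition, seed and any ground-truth metadata.
#'
#' @param rec An `eeg_recording`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.csv(m, path, row.names = FALSE)
  side <- rec$meta
  side$fs <- rec$fs
  side$channel_labels <- rec$channel_labels
  side$emotion_state <- NULL  # bulky; regenerable from the seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from CSV (+ optional JSON sidecar)
#'
#' @param path CSV path as written by [write_recording_csv()], or any CSV with
#'   a header row of channel labels and samples down the rows.
#' @param fs Sampling rate; taken from the sidecar when present.
#' @param montage Optional character vector; when given, the file's channels
#'   are checked and reordered against it.
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, fs = NULL, montage = NULL) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    meta$fs <- NULL
  }
  if (is.null(fs)) stop("`fs` not given and no JSON sidecar found")
  labels <- colnames(m)
  if (!is.null(montage)) {
    missing <- setdiff(montage, labels)
    if (length(missing))
      stop("montage channels missing from file: ", paste(missing, collapse = ", "))
    m <- m[, montage, drop = FALSE]
    labels <- montage
  }
  eeg_recording(t(m), fs = fs, channel_labels = labels, meta = meta)
}
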