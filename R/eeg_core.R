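#' @useDynLib fnnbci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Emotiv EPOC channel names
#'
#' Default names of the 14 scalp electrodes of the Emotiv EPOC consumer
#' headset, in its standard order.
#' @export
emotiv_channels <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                     "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Command class labels
#'
#' The command vocabulary of the wheelchair interface: four motion commands,
#' the two switch commands and the neutral (rest) command.
#' @export
command_classes <- c("forward", "backward", "left", "right",
                     "switch_on", "switch_off", "neutral")

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "fnnbci_error")))
}

#' Construct a multichannel EEG recording
#'
#' A recording is a samples-by-channels numeric matrix together with the
#' sampling rate and an optional class label. All samples must be finite.
#'
#' @param data numeric matrix, one column per channel.
#' @param channels character vector of channel names; defaults to the
#'   column names of `data`, or [emotiv_channels] when `data` has 14
#'   unnamed columns.
#' @param sample_rate samples per second (default 128, the Emotiv rate).
#' @param label optional class label (one of [command_classes] or any
#'   string).
#' @return an object of class `eeg_recording` with elements `data`,
#'   `channels`, `sample_rate`, `label`.
#' @export
recording <- function(data, channels = NULL, sample_rate = 128, label = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) {
    channels <- colnames(data)
    if (is.null(channels)) {
      channels <- if (ncol(data) == 14L) emotiv_channels
                  else paste0("ch", seq_len(ncol(data)))
    }
  }
  rec <- structure(
    list(data = data, channels = as.character(channels),
         sample_rate = sample_rate, label = label),
    class = "eeg_recording")
  validate_recording(rec)
}

#' Validate a recording
#'
#' Checks the recording invariants: at least one channel, channel names
#' matching the data columns, a positive sampling rate and finite samples.
#' @param rec an `eeg_recording`.
#' @return `rec`, invisibly unchanged, or a classed error.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording"))
    abort("not an eeg_recording", "fnnbci_type_error")
  if (ncol(rec$data) < 1L)
    abort("recording must have at least one channel", "fnnbci_no_channels")
  if (length(rec$channels) != ncol(rec$data))
    abort("channel names do not match data columns", "fnnbci_channel_mismatch")
  if (anyDuplicated(rec$channels))
    abort("duplicate channel names", "fnnbci_channel_mismatch")
  if (!is.numeric(rec$sample_rate) || length(rec$sample_rate) != 1L ||
      !is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    abort("sample_rate must be a positive number", "fnnbci_bad_sample_rate")
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    abort("recording contains NaN or infinite samples", "fnnbci_nonfinite")
  colnames(rec$data) <- rec$channels
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.2f s)%s\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sample_rate

#' Read a recording from a CSV file
#'
#' The file dialect is comma-separated UTF-8 with a header row naming the
#' channels and '.' as decimal mark. An optional leading column named
#' `time` is dropped. The sampling rate is metadata supplied by the
#' caller, not stored in the file.
#'
#' @param path path to the CSV file.
#' @param sample_rate samples per second (default 128).
#' @param label optional class label to attach.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, sample_rate = 128, label = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "fnnbci_missing_file")
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE),
    error = function(e)
      abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
            "fnnbci_ragged_rows"))
  if (ncol(df) >= 1L && tolower(names(df)[1]) == "time")
    df <- df[, -1, drop = FALSE]
  if (ncol(df) < 1L)
    abort("file has no channel columns", "fnnbci_no_channels")
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df))
  for (j in seq_len(ncol(df))) {
    raw <- df[[j]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & !(raw %in% c("NA", "NaN")))
    if (length(bad) > 0L)
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    raw[bad[1]], bad[1], names(df)[j], path),
            "fnnbci_nonnumeric")
    nav <- which(is.na(v) | !is.finite(v))
    if (length(nav) > 0L)
      abort(sprintf("missing/non-finite sample at row %d, column '%s' of %s",
                    nav[1], names(df)[j], path),
            "fnnbci_nonfinite")
    mat[, j] <- v
  }
  recording(mat, channels = names(df), sample_rate = sample_rate,
            label = label)
}

#' Write a recording to a CSV file
#'
#' Writes the header row of channel names and one row per sample, at full
#' double precision so that `read_recording(write_recording(x))` round
#' trips to below 1e-9 absolute difference.
#'
#' @param rec a validated `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- as.data.frame(rec$data)
  names(df) <- rec$channels
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    abort(sprintf("cannot write to %s", path), "fnnbci_unwritable")
  invisible(path)
}

#' Construct an analysis window
#'
#' One fixed-length multichannel segment of a recording, with provenance
#' (source id and 0-based start offset) and the inherited class label.
#'
#' @param data W-by-C numeric matrix.
#' @param source_id identifier of the source recording.
#' @param start_index 0-based sample offset within the source.
#' @param label optional class label.
#' @param sample_rate samples per second of the source.
#' @return an object of class `eeg_window`.
#' @export
eeg_window <- function(data, source_id = NA_character_, start_index = 0L,
                       label = NULL, sample_rate = 128) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  structure(list(data = data, source_id = source_id,
                 start_index = as.integer(start_index), label = label,
                 sample_rate = sample_rate),
            class = "eeg_window")
}

#' @export
print.eeg_window <- function(x, ...) {
  cat(sprintf("<eeg_window> %d samples x %d channels, start %d%s\n",
              nrow(x$data), ncol(x$data), x$start_index,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}
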