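#' Segment a recording into overlapping windows
#'
#' Divides a recording into fixed-length windows (default 2 s, i.e. 256
#' samples at 128 Hz) with fractional overlap (default 50%). The hop is
#' `round(W * (1 - overlap))` samples; a trailing partial window is
#' dropped. Each window inherits the recording's label.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length in seconds (default 2).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param source_id identifier recorded in each window's provenance.
#' @return list of `eeg_window` objects; starts at `0, H, 2H, ...`
#'   (0-based), count `floor((N - W)/H) + 1`.
#' @export
segment_windows <- function(rec, window_s = 2.0, overlap = 0.5,
                            source_id = NA_character_) {
  validate_recording(rec)
  if (overlap < 0 || overlap >= 1)
    abort("overlap must be in [0, 1)", "fnnbci_bad_overlap")
  w_exact <- window_s * rec$sample_rate
  W <- as.integer(round(w_exact))
  if (W < 1L || abs(w_exact - W) > 1e-9)
    abort("window_s * sample_rate must be a positive integer",
          "fnnbci_bad_window")
  N <- nrow(rec$data)
  if (N < W)
    abort(sprintf("recording shorter than window (%d < %d samples)", N, W),
          "fnnbci_short_recording")
  H <- max(1L, as.integer(round(W * (1 - overlap))))
  starts <- seq.int(0L, N - W, by = H)
  lapply(starts, function(s)
    eeg_window(rec$data[(s + 1L):(s + W), , drop = FALSE],
               source_id = source_id, start_index = s, label = rec$label,
               sample_rate = rec$sample_rate))
}

#' Centre each channel of a window on zero
#'
#' Subtracts the per-channel mean over the window, so every channel has
#' mean zero before spectral analysis.
#' @param win an `eeg_window`.
#' @return the centred window.
#' @export
center_channels <- function(win) {
  win$data <- sweep(win$data, 2L, colMeans(win$data))
  win
}

#' Hamming taper coefficients
#'
#' `h(t) = 0.54 - 0.46 cos(2 pi t / (W - 1))`, `t = 0, ..., W-1`,
#' delegated to [signal::hamming()].
#' @param W window length in samples (at least 2).
#' @return length-W numeric vector.
#' @export
hamming_coefficients <- function(W) {
  if (W < 2L) abort("window length must be >= 2", "fnnbci_bad_window")
  as.numeric(signal::hamming(W))
}

#' Apply a Hamming taper to each channel
#'
#' Multiplies sample `t` of every channel by the Hamming coefficient
#' `h(t)`, reducing the spectral leakage caused by treating a
#' non-periodic EEG segment as periodic.
#' @param win an `eeg_window`.
#' @return the tapered window.
#' @export
apply_hamming <- function(win) {
  win$data <- win$data * hamming_coefficients(nrow(win$data))
  win
}

#' FFT magnitude features for one window
#'
#' Per channel, the magnitude of the discrete Fourier transform at bins
#' `0 ... n_bins - 1` (bin spacing `sample_rate / W`; 0.5 Hz at the
#' defaults, so 64 bins cover 0–31.5 Hz). Channels are concatenated in
#' channel order into a single named feature row. The window is expected
#' to be centred and Hamming-tapered already.
#'
#' @param win an `eeg_window`.
#' @param n_bins number of retained frequency bins per channel
#'   (default 64; at most `W/2`).
#' @return named numeric vector of length `C * n_bins`; names are
#'   `"<channel>_<freq>Hz"`.
#' @export
spectral_features <- function(win, n_bins = 64L) {
  W <- nrow(win$data)
  if (n_bins > W / 2)
    abort(sprintf("n_bins (%d) exceeds W/2 (%g)", n_bins, W / 2),
          "fnnbci_too_many_bins")
  mags <- abs(stats::mvfft(win$data))[seq_len(n_bins), , drop = FALSE]
  freqs <- (seq_len(n_bins) - 1L) * win$sample_rate / W
  chans <- colnames(win$data)
  if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(win$data)))
  out <- as.numeric(mags)                       # column-major: channel blocks
  names(out) <- as.vector(outer(freqs, chans,
                                function(f, ch) sprintf("%s_%gHz", ch, f)))
  out
}

#' Construct a feature matrix
#'
#' Rows are windows, columns are named spectral features
#' (channel x frequency bin), with an optional label per row.
#'
#' @param values N-by-F numeric matrix.
#' @param feature_names length-F character vector of unique names.
#' @param labels optional length-N factor (or character) of class labels.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names = colnames(values),
                           labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(feature_names))
    abort("feature names must be unique", "fnnbci_duplicate_features")
  if (any(!is.finite(values)))
    abort("feature values must be finite", "fnnbci_nonfinite")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      abort("labels length must equal number of rows", "fnnbci_label_mismatch")
    labels <- as.factor(labels)
  }
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = as.character(feature_names),
                 labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) ""
              else sprintf(", %d classes", nlevels(x$labels))))
  invisible(x)
}

#' Run the full spectral feature pipeline over recordings
#'
#' For every recording: overlapped windowing, per-channel centring,
#' Hamming taper, FFT magnitude features; rows of all recordings are
#' stacked into one labelled feature matrix.
#'
#' @param recordings list of `eeg_recording` objects (labelled).
#' @param window_s,overlap,n_bins see [segment_windows()] and
#'   [spectral_features()].
#' @param spectral if `FALSE`, skip the Hamming/FFT stage and use the
#'   centred time-domain samples (flattened channel-major) as features.
#' @return a `feature_matrix`.
#' @export
extract_features <- function(recordings, window_s = 2.0, overlap = 0.5,
                             n_bins = 64L, spectral = TRUE) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- list(); labs <- character(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    wins <- segment_windows(rec, window_s, overlap,
                            source_id = sprintf("rec%03d", i))
    for (win in wins) {
      win <- center_channels(win)
      row <- if (spectral) spectral_features(apply_hamming(win), n_bins)
             else {
               v <- as.numeric(win$data)
               names(v) <- as.vector(outer(
                 seq_len(nrow(win$data)) - 1L, colnames(win$data),
                 function(t, ch) sprintf("%s_t%d", ch, t)))
               v
             }
      rows[[length(rows) + 1L]] <- row
      labs <- c(labs, if (is.null(win$label)) NA_character_ else win$label)
    }
  }
  values <- do.call(rbind, rows)
  feature_matrix(values, colnames(values),
                 labels = if (all(is.na(labs))) NULL else labs)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Equal-frequency binning by rank; ties share a rank so equal values can
# never be split across bins, and any strictly monotone transform of x
# leaves the binning unchanged.
discretise_quantile <- function(x, n_bins) {
  r <- rank(x, ties.method = "min")
  as.integer(ceiling(r * n_bins / length(x)))
}

#' Rank features by information gain
#'
#' Each continuous feature is discretised into equal-frequency (rank
#' quantile) bins and scored by the reduction in class entropy,
#' `InfoGain = H(class) - H(class | feature)`, in bits. Features are
#' ordered by decreasing score; ties break by ascending feature index so
#' the ranking is deterministic.
#'
#' @param fm a labelled `feature_matrix` with at least two classes.
#' @param n_disc_bins number of quantile bins (default 10).
#' @return an object of class `feature_ranking` with `scores` (bits,
#'   >= 0, in original feature order) and `order` (a permutation of
#'   feature indices, best first).
#' @export
info_gain_rank <- function(fm, n_disc_bins = 10L) {
  if (is.null(fm$labels))
    abort("feature matrix has no labels", "fnnbci_no_labels")
  y <- droplevels(fm$labels)
  if (nlevels(y) < 2L)
    abort("information gain needs at least two classes",
          "fnnbci_single_class")
  if (nrow(fm$values) < 2L)
    abort("need at least two windows", "fnnbci_too_few_rows")
  h_class <- entropy_bits(table(y))
  n <- nrow(fm$values)
  scores <- vapply(seq_len(ncol(fm$values)), function(j) {
    d <- discretise_quantile(fm$values[, j], n_disc_bins)
    tab <- table(d, y)
    h_cond <- sum(apply(tab, 1L, function(cnt)
      sum(cnt) / n * entropy_bits(cnt)))
    max(h_class - h_cond, 0)
  }, numeric(1))
  structure(list(scores = scores,
                 order = order(-scores, seq_along(scores))),
            class = "feature_ranking")
}

#' Keep the top-k ranked features
#'
#' Retains the `k` best-scored features, in ranked order (best first).
#' @param fm a `feature_matrix`.
#' @param ranking a `feature_ranking` from [info_gain_rank()].
#' @param k number of features to keep (default 100).
#' @return the reduced `feature_matrix`.
#' @export
select_top_k <- function(fm, ranking, k = 100L) {
  Fn <- ncol(fm$values)
  if (k < 1L || k > Fn)
    abort(sprintf("k (%d) must be in [1, %d]", k, Fn), "fnnbci_bad_k")
  keep <- ranking$order[seq_len(k)]
  feature_matrix(fm$values[, keep, drop = FALSE], fm$feature_names[keep],
                 fm$labels)
}

#' Min-max scaling bounds of a training feature matrix
#' @param train_fm the training `feature_matrix`.
#' @return list with `min` and `max` per feature.
#' @export
feature_bounds <- function(train_fm) {
  list(min = apply(train_fm$values, 2L, min),
       max = apply(train_fm$values, 2L, max),
       feature_names = train_fm$feature_names)
}

#' Min-max scale features to [0, 1]
#'
#' Scales each feature of `apply_fm` to `[0, 1]` using the per-feature
#' minimum and maximum of `train_fm` only; values outside the training
#' range are clipped. A zero-range (constant) training feature maps to
#' constant 0.
#'
#' @param train_fm training `feature_matrix` (or a precomputed
#'   [feature_bounds()] list).
#' @param apply_fm feature matrix to scale (default: `train_fm` itself).
#' @return scaled `feature_matrix` with attribute `"bounds"`.
#' @export
scale_features <- function(train_fm, apply_fm = train_fm) {
  b <- if (inherits(train_fm, "feature_matrix")) feature_bounds(train_fm)
       else train_fm
  if (!identical(b$feature_names, apply_fm$feature_names))
    abort("feature names of train and apply matrices differ",
          "fnnbci_feature_mismatch")
  rng <- b$max - b$min
  scaled <- sweep(apply_fm$values, 2L, b$min)
  scaled <- sweep(scaled, 2L, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  out <- feature_matrix(scaled, apply_fm$feature_names, apply_fm$labels)
  attr(out, "bounds") <- b
  out
}

#' Write a feature matrix to CSV
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values)
  names(df) <- fm$feature_names
  if (!is.null(fm$labels)) df$label <- as.character(fm$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#' @param path CSV written by [write_feature_matrix()].
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "fnnbci_missing_file")
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  feature_matrix(as.matrix(df), names(df), labels)
}
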