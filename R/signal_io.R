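# Data model and preprocessing for multi-channel sEMG recordings.
#
# A recording is a channels x samples matrix plus (participant, gesture,
# cycle) metadata. Recordings are band-pass filtered, then cut into
# fixed-length windows (151 samples @ 1 kHz by default, stride 51 = 100 ms
# overlap). Windows inherit their recording's metadata, and cycles define
# the train / validation / test split.

#' Construct an EMG recording
#'
#' @param signal numeric matrix, channels x samples.
#' @param participant participant identifier (integer).
#' @param gesture gesture class id, `0 .. n_classes - 1`.
#' @param cycle recording cycle id (1-based).
#' @param fs sampling rate in Hz.
#' @export
emg_recording <- function(signal, participant, gesture, cycle, fs = 1000) {
  .assert(is.matrix(signal) && is.numeric(signal), "signal must be a numeric matrix")
  .assert(all(is.finite(signal)), "signal must be finite")
  structure(list(signal = signal, fs = fs,
                 participant = as.integer(participant),
                 gesture = as.integer(gesture),
                 cycle = as.integer(cycle)),
            class = "emg_recording")
}

#' Segment a recording into fixed-length windows
#'
#' Produces `floor((S - window_len) / stride) + 1` windows (none if the
#' recording is shorter than one window). Window sample ranges are the
#' half-open 0-based intervals `[k * stride, k * stride + window_len)`.
#'
#' @param recording an [emg_recording()].
#' @param window_len window length in samples.
#' @param stride hop between window starts in samples.
#' @return list of windows; each has `data` (channels x window_len),
#'   `participant`, `gesture`, `cycle`.
#' @export
segment <- function(recording, window_len = 151, stride = 51) {
  s <- ncol(recording$signal)
  if (s < window_len) return(list())
  n <- floor((s - window_len) / stride) + 1
  lapply(seq_len(n) - 1L, function(k) {
    structure(list(data = recording$signal[, (k * stride + 1):(k * stride + window_len), drop = FALSE],
                   participant = recording$participant,
                   gesture = recording$gesture,
                   cycle = recording$cycle),
              class = "emg_window")
  })
}

#' Default cycle-based split
#'
#' Cycles 1-3 train, cycle 4 validation, cycles 5-8 test.
#' @export
default_split <- function() {
  list(train = 1:3, val = 4L, test = 5:8)
}

#' Assemble windows into a dataset
#'
#' @param windows list of windows as produced by [segment()].
#' @param split named list mapping `train` / `val` / `test` to cycle ids;
#'   the three sets must be disjoint.
#' @param fs sampling rate in Hz.
#' @export
windowed_dataset <- function(windows, split = default_split(), fs = 1000) {
  .assert(length(windows) > 0, "no windows")
  .assert(!anyDuplicated(unlist(split)), "split cycles must be disjoint")
  ch <- nrow(windows[[1]]$data)
  len <- ncol(windows[[1]]$data)
  arr <- array(0, dim = c(ch, len, length(windows)))
  for (i in seq_along(windows)) arr[, , i] <- windows[[i]]$data
  meta <- data.frame(
    participant = vapply(windows, `[[`, integer(1), "participant"),
    gesture = vapply(windows, `[[`, integer(1), "gesture"),
    cycle = vapply(windows, `[[`, integer(1), "cycle"))
  structure(list(windows = arr, meta = meta, split = split, fs = fs),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<emg_dataset> %d windows (%d x %d), %d participants, %d gestures\n",
              d[3], d[1], d[2], length(unique(x$meta$participant)),
              length(unique(x$meta$gesture))))
  invisible(x)
}

#' Number of windows in a dataset
#' @param dataset an `emg_dataset`.
#' @export
n_windows <- function(dataset) dim(dataset$windows)[3]

#' Indices of windows belonging to a split phase
#'
#' @param dataset an `emg_dataset`.
#' @param phase one of `"train"`, `"val"`, `"test"`.
#' @export
split_indices <- function(dataset, phase = c("train", "val", "test")) {
  phase <- match.arg(phase)
  which(dataset$meta$cycle %in% dataset$split[[phase]])
}

#' Subset a dataset by window indices
#' @param dataset an `emg_dataset`.
#' @param idx window indices to keep.
#' @export
subset_dataset <- function(dataset, idx) {
  dataset$windows <- dataset$windows[, , idx, drop = FALSE]
  dataset$meta <- dataset$meta[idx, , drop = FALSE]
  rownames(dataset$meta) <- NULL
  dataset
}

#' Build a windowed dataset from recordings
#'
#' Filtering is applied to the whole recording before segmentation by
#' default (avoiding 151-sample edge transients); set
#' `per_window_filter = TRUE` to filter each window independently instead.
#'
#' @param recordings list of [emg_recording()].
#' @param window_len,stride segmentation parameters in samples.
#' @param filter apply the Butterworth band-pass.
#' @param low,high,order band-pass configuration.
#' @param zero_phase forward-backward filtering instead of causal.
#' @param per_window_filter filter after segmentation, per window.
#' @param split cycle split, see [windowed_dataset()].
#' @export
preprocess_recordings <- function(recordings, window_len = 151, stride = 51,
                                  filter = TRUE, low = 20, high = 495,
                                  order = 4, zero_phase = FALSE,
                                  per_window_filter = FALSE,
                                  split = default_split()) {
  fs <- recordings[[1]]$fs
  filt <- if (filter) butter_bandpass(low, high, fs, order) else NULL
  windows <- list()
  for (rec in recordings) {
    if (filter && !per_window_filter) {
      rec$signal <- filter_signal(rec$signal, filt, zero_phase = zero_phase)
    }
    w <- segment(rec, window_len, stride)
    if (filter && per_window_filter) {
      w <- lapply(w, function(wi) {
        wi$data <- filter_signal(wi$data, filt, zero_phase = zero_phase)
        wi
      })
    }
    windows <- c(windows, w)
  }
  windowed_dataset(windows, split = split, fs = fs)
}

#' Load a dataset from a JSON manifest of delimited-text signal files
#'
#' The manifest is a JSON array of records with fields `file` (CSV path
#' relative to the manifest, one row per channel), `participant`,
#' `gesture`, `cycle`.
#'
#' @param manifest_path path to the manifest JSON.
#' @param n_channels expected channel count per file.
#' @param n_classes number of gesture classes (ids `0 .. n_classes - 1`).
#' @param ... passed to [preprocess_recordings()].
#' @export
load_dataset <- function(manifest_path, n_channels = 10, n_classes = 11, ...) {
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    sig <- as.matrix(utils::read.table(file.path(base, man$file[i]), sep = ","))
    dimnames(sig) <- NULL
    if (nrow(sig) != n_channels) {
      stop(sprintf("format error: %s has %d channels, expected %d",
                   man$file[i], nrow(sig), n_channels), call. = FALSE)
    }
    if (man$gesture[i] < 0 || man$gesture[i] >= n_classes) {
      stop(sprintf("format error: unknown gesture id %d", man$gesture[i]),
           call. = FALSE)
    }
    emg_recording(sig, man$participant[i], man$gesture[i], man$cycle[i])
  })
  preprocess_recordings(recs, ...)
}

#' Save a windowed dataset as plain text
#'
#' Writes `dataset.json` (metadata, split, shape) and `windows.csv`
#' (one row per (window, channel), values in sample order) under `path`.
#'
#' @param dataset an `emg_dataset`.
#' @param path output directory (created if missing).
#' @export
save_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$windows)
  jsonlite::write_json(
    list(fs = dataset$fs, n_channels = d[1], window_len = d[2],
         n_windows = d[3], split = dataset$split, meta = dataset$meta),
    file.path(path, "dataset.json"), auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(dataset$windows, c(2, 1, 3)), nrow = d[1] * d[3],
                 ncol = d[2], byrow = TRUE)
  utils::write.table(flat, file.path(path, "windows.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a dataset written by [save_dataset()]
#' @param path directory produced by [save_dataset()].
#' @export
load_saved_dataset <- function(path) {
  hdr <- jsonlite::fromJSON(file.path(path, "dataset.json"))
  flat <- as.matrix(utils::read.table(file.path(path, "windows.csv"), sep = ","))
  arr <- array(0, dim = c(hdr$n_channels, hdr$window_len, hdr$n_windows))
  for (i in seq_len(hdr$n_windows)) {
    arr[, , i] <- flat[((i - 1) * hdr$n_channels + 1):(i * hdr$n_channels), ]
  }
  meta <- as.data.frame(hdr$meta)
  structure(list(windows = arr, meta = meta,
                 split = lapply(hdr$split, as.integer), fs = hdr$fs),
            class = "emg_dataset")
}
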