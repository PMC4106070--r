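# Recording and segment containers, file I/O, segmentation, train/test split.

#' Construct a multichannel EEG recording
#'
#' A recording is an N x T numeric matrix (one channel per row, amplitudes in
#' microvolts) together with its sampling rate, channel labels and an ordered
#' list of annotated seizure intervals.  Intervals are half-open
#' `[start, end)` in seconds, must be sorted, non-overlapping and contained
#' in `[0, T/fs]`.
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels optional character vector of length `nrow(data)`.
#' @param seizure_intervals optional two-column matrix or data frame of
#'   `(start_s, end_s)` seizure annotations in seconds.
#' @return an object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels` and `seizure_intervals` (an m x 2 matrix).
#' @export
recording <- function(data, fs, channel_labels = NULL, seizure_intervals = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop_rsae("recording data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_rsae("fs must be a single positive number (Hz)")
  }
  n <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  if (length(channel_labels) != n) {
    stop_rsae("channel_labels must have one entry per channel")
  }
  duration <- ncol(data) / fs
  ints <- validate_intervals(seizure_intervals, duration)
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         seizure_intervals = ints),
    class = "eeg_recording"
  )
}

validate_intervals <- function(ints, duration) {
  if (is.null(ints) || (is.matrix(ints) && nrow(ints) == 0L)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  }
  ints <- as.matrix(ints)
  if (ncol(ints) != 2L) stop_rsae("seizure intervals must have two columns (start_s, end_s)")
  storage.mode(ints) <- "double"
  if (!all(is.finite(ints))) stop_rsae("seizure intervals must be finite")
  if (any(ints[, 1L] < 0) || any(ints[, 2L] > duration + 1e-9)) {
    stop_rsae("seizure intervals must lie within [0, duration] seconds")
  }
  if (any(ints[, 2L] <= ints[, 1L])) stop_rsae("seizure intervals must have end > start")
  o <- order(ints[, 1L])
  ints <- ints[o, , drop = FALSE]
  if (nrow(ints) > 1L && any(ints[-1L, 1L] < ints[-nrow(ints), 2L] - 1e-9)) {
    stop_rsae("seizure intervals must not overlap")
  }
  dimnames(ints) <- list(NULL, c("start_s", "end_s"))
  ints
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$seizure_intervals)))
  invisible(x)
}

new_segment <- function(data, label, start_s) {
  structure(list(data = data, label = label, start_s = start_s),
            class = "eeg_segment")
}

#' Labels of a list of segments
#' @param segments list of `eeg_segment` objects.
#' @return character vector of `"seizure"` / `"nonseizure"` labels.
#' @export
segment_labels <- function(segments) {
  vapply(segments, function(s) s$label, character(1L))
}

#' Read a multichannel recording from disk
#'
#' Supports two on-disk forms: a delimited numeric text matrix (one channel
#' per row, whitespace- or comma-separated columns of samples) and 16-bit
#' EDF (European Data Format).  Seizure annotations may be supplied as a
#' two-column text file of start/end seconds, or directly as a matrix.
#'
#' @param path path to the signal file.
#' @param format `"delimited"` or `"edf"`.
#' @param fs sampling rate in Hz; required for delimited input, ignored for
#'   EDF (taken from the header).
#' @param intervals seizure annotations: a path to a two-column text file,
#'   a two-column matrix/data frame, or `NULL` for none.
#' @param sep field separator for delimited input; `NULL` auto-detects
#'   comma versus whitespace.
#' @return an [recording()] object.
#' @export
read_recording <- function(path, format = c("delimited", "edf"), fs = NULL,
                           intervals = NULL, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_rsae("file not found: ", path)
  if (format == "delimited") {
    if (is.null(fs)) stop_rsae("fs is required for delimited input")
    if (is.null(sep)) {
      first <- readLines(path, n = 1L)
      sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    }
    nf <- count.fields(path, sep = sep)
    if (length(unique(nf)) != 1L) {
      stop_rsae("inconsistent row lengths in delimited file: ", path)
    }
    # scan(), not read.table(): recordings are very wide matrices and
    # read.table's one-column-per-sample representation does not scale
    vals <- scan(path, what = double(), sep = if (sep == "") "" else sep,
                 quiet = TRUE)
    data <- matrix(vals, nrow = length(nf), ncol = nf[1L], byrow = TRUE)
    rec <- list(data = data, fs = fs, labels = NULL)
  } else {
    rec <- read_edf_raw(path)
  }
  if (nrow(rec$data) < 2L) stop_rsae("recording must have at least 2 channels")
  ints <- intervals
  if (is.character(ints)) {
    ints <- as.matrix(read.table(ints, header = FALSE))
  }
  recording(rec$data, rec$fs, channel_labels = rec$labels,
            seizure_intervals = ints)
}

#' Write a recording to the delimited text dialect
#'
#' One channel per row, whitespace-separated samples; the optional
#' annotation file holds one `start_s end_s` pair per line.
#'
#' @param rec an [recording()] object.
#' @param path output path for the signal matrix.
#' @param intervals_path optional output path for the seizure annotations.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, intervals_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  write.table(format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(intervals_path)) {
    write.table(rec$seizure_intervals, intervals_path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# --- Minimal EDF (16-bit European Data Format) support -----------------------
# Fixed 256-byte header, then per-signal header fields, then contiguous
# little-endian int16 data records.  All channels must share one sampling
# rate; physical values are recovered by the standard linear calibration.

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fld <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  fld(8); fld(80); fld(80); fld(8); fld(8)           # version, ids, date, time
  fld(8); fld(44)                                    # header bytes, reserved
  n_rec <- as.integer(fld(8))
  rec_dur <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  if (!is_count(ns)) stop_rsae("unreadable EDF header: bad signal count")
  sfld <- function(w) vapply(seq_len(ns), function(i) {
    trimws(rawToChar(readBin(con, "raw", w)))
  }, character(1L))
  labels <- sfld(16); sfld(80); sfld(8)
  pmin <- as.numeric(sfld(8)); pmax <- as.numeric(sfld(8))
  dmin <- as.numeric(sfld(8)); dmax <- as.numeric(sfld(8))
  sfld(80)
  spr <- as.integer(sfld(8))
  sfld(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)) || n_rec < 1L || rec_dur <= 0) {
    stop_rsae("unreadable EDF header in ", path)
  }
  if (length(unique(spr)) != 1L) {
    stop_rsae("EDF channels disagree on samples per record (mixed sampling rates unsupported)")
  }
  m <- spr[1L]
  raw <- readBin(con, "integer", n = n_rec * ns * m, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != n_rec * ns * m) stop_rsae("truncated EDF data in ", path)
  # records are stored signal-major within each record
  arr <- array(raw, dim = c(m, ns, n_rec))
  data <- matrix(0, nrow = ns, ncol = n_rec * m)
  for (s in seq_len(ns)) {
    data[s, ] <- as.vector(arr[, s, ])
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- data * gain + (pmin - dmin * gain)
  list(data = data, fs = m / rec_dur, labels = labels)
}

pad_field <- function(x, w) {
  s <- as.character(x)
  if (nchar(s) > w) s <- substr(s, 1L, w)
  formatC(s, width = w, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Amplitudes are linearly quantised per channel to the int16 digital range.
#' The record duration is 1 second, so `fs` must be a whole number and any
#' trailing partial second of signal is dropped.
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param samples_per_record internal override of the per-channel samples
#'   per data record (defaults to `fs` for every channel).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, samples_per_record = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop_rsae("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  spr <- samples_per_record %||% rep(as.integer(fs), ns)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L) stop_rsae("recording shorter than one EDF record (1 s)")
  pmin <- apply(rec$data, 1L, min); pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(pad_field(x, w)), con)
  put("0", 8); put("synthetic", 80); put("rsae", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256L + ns * 256L, 8); put("", 44)
  put(n_rec, 8); put("1", 8); put(ns, 4)
  for (lab in rec$channel_labels) put(lab, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(formatC(pmin[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) put(formatC(pmax[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) put(dmin, 8)
  for (i in seq_len(ns)) put(dmax, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(spr[i], 8)
  for (i in seq_len(ns)) put("", 32)
  # re-read header-coded calibration so that read(write(x)) is exact up to
  # quantisation: quantise against the printed physical min/max
  pmin_h <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmax_h <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      x <- rec$data[s, idx]
      dig <- round((x - pmin_h[s]) / (pmax_h[s] - pmin_h[s]) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      dig <- as.integer(dig)
      length(dig) <- spr[s]          # internal override may truncate/pad
      dig[is.na(dig)] <- 0L
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Cut a recording into labelled fixed-length segments
#'
#' Non-seizure time is tiled with non-overlapping windows of `window_s`
#' seconds; seizure intervals are covered by a sliding window with stride
#' `window_s * (1 - seizure_overlap_frac)`.  A window is labelled seizure
#' only if it lies fully inside one seizure interval and nonseizure only if
#' it lies fully outside all intervals; windows straddling an interval
#' boundary are discarded.
#'
#' @param rec an [recording()] object.
#' @param window_s window length in seconds (default 5).
#' @param seizure_overlap_frac overlap fraction in `[0, 1)` between
#'   consecutive seizure windows (default 0.5).
#' @param max_per_class optional named vector/list with elements `seizure`
#'   and/or `nonseizure` capping the number of emitted segments per class;
#'   requesting more than are available is an error.
#' @return list of `eeg_segment` objects (fields `data`, `label`, `start_s`).
#' @export
segment_recording <- function(rec, window_s = 5,
                              seizure_overlap_frac = 0.5,
                              max_per_class = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  L <- round(window_s * fs)
  if (L < 2L) stop_rsae("window_s * fs must be at least 2 samples")
  total <- ncol(rec$data)
  duration <- total / fs
  if (window_s > duration + 1e-9) stop_rsae("window longer than recording")
  if (seizure_overlap_frac < 0 || seizure_overlap_frac >= 1) {
    stop_rsae("seizure_overlap_frac must lie in [0, 1)")
  }
  eps <- 1e-9
  ints <- rec$seizure_intervals
  grab <- function(start_s, label) {
    i0 <- floor(start_s * fs) + 1
    if (i0 + L - 1 > total) return(NULL)
    new_segment(rec$data[, i0:(i0 + L - 1L), drop = FALSE], label, start_s)
  }
  seiz <- list()
  stride <- window_s * (1 - seizure_overlap_frac)
  for (k in seq_len(nrow(ints))) {
    s0 <- ints[k, 1L]; s1 <- ints[k, 2L]
    t <- s0
    while (t + window_s <= s1 + eps) {
      seg <- grab(t, "seizure")
      if (!is.null(seg)) seiz[[length(seiz) + 1L]] <- seg
      t <- t + stride
    }
  }
  gaps_lo <- c(0, ints[, 2L])
  gaps_hi <- c(ints[, 1L], duration)
  nons <- list()
  for (k in seq_along(gaps_lo)) {
    g0 <- gaps_lo[k]; g1 <- gaps_hi[k]
    t <- g0
    while (t + window_s <= g1 + eps) {
      seg <- grab(t, "nonseizure")
      if (!is.null(seg)) nons[[length(nons) + 1L]] <- seg
      t <- t + window_s
    }
  }
  cap <- function(segs, class) {
    k <- max_per_class[[class]]
    if (is.null(k) || !is.finite(k)) return(segs)
    if (length(segs) < k) {
      stop_rsae("requested ", k, " ", class, " segments but only ",
                length(segs), " are available")
    }
    segs[seq_len(k)]
  }
  if (!is.null(max_per_class)) {
    seiz <- cap(seiz, "seizure")
    nons <- cap(nons, "nonseizure")
  }
  c(seiz, nons)
}

#' Split labelled segments into balanced train and held-out test sets
#'
#' Samples `n_train_per_class` segments per class without replacement by a
#' seeded shuffle; everything else becomes the test set.  The same seed on
#' the same input always yields the identical partition.
#'
#' @param segments list of labelled `eeg_segment` objects.
#' @param n_train_per_class training segments drawn per class (default 750).
#' @param seed integer seed controlling the draw.
#' @return list with elements `train` and `test` (lists of segments).
#' @export
split_train_test <- function(segments, n_train_per_class = 750, seed = 1L) {
  labels <- segment_labels(segments)
  classes <- c("seizure", "nonseizure")
  idx <- lapply(classes, function(cl) which(labels == cl))
  names(idx) <- classes
  for (cl in classes) {
    if (length(idx[[cl]]) < n_train_per_class) {
      stop_rsae("class '", cl, "' has ", length(idx[[cl]]),
                " segments, fewer than n_train_per_class = ", n_train_per_class)
    }
  }
  with_seed(seed, {
    picks <- unlist(lapply(classes, function(cl) {
      sample(idx[[cl]], n_train_per_class)
    }), use.names = FALSE)
    train_idx <- sample(picks)               # disorder the training set
    test_idx <- setdiff(seq_along(segments), picks)
    list(train = segments[train_idx], test = segments[test_idx])
  })
}
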