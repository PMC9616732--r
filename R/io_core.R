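# Shared data model and file formats.
#
# All pipeline computation assumes the fixed post-preprocessing sampling rate
# of 200 Hz; readers reject other rates rather than resampling. Time is in
# seconds, 0-based, and intervals are half-open [start, end).

PIPELINE_FS <- 200
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM")

#' Construct a continuous multichannel EEG recording
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (the pipeline requires 200).
#' @param channel_labels Character vector of 10-20 channel names, one per row
#'   of `signal`, in row order.
#' @param start_time Offset of the first sample in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_labels, start_time = 0) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(is.numeric(signal), fs > 0)
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match signal rows (", nrow(signal), ")")
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  structure(
    list(signal = signal, fs = fs,
         channel_labels = as.character(channel_labels),
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Construct a hypnogram
#'
#' @param stages Character vector of sleep-stage labels, one per scoring
#'   epoch, from `W`, `N1`, `N2`, `N3`, `REM`.
#' @param epoch_len Epoch length in seconds (default 30).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len = 30) {
  stopifnot(epoch_len > 0)
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(stages = stages, epoch_len = epoch_len), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %d x %gs epochs (%.1f min): %s\n",
              length(x$stages), x$epoch_len,
              length(x$stages) * x$epoch_len / 60,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Construct an artifact mask from time intervals
#'
#' Intervals are half-open `[start, end)` in recording time (seconds).
#' Overlapping or touching intervals are merged (with a warning when a true
#' overlap was present).
#'
#' @param intervals Two-column matrix or data frame of start and end times in
#'   seconds; may have zero rows.
#' @return An object of class `artifact_mask` with sorted, disjoint
#'   intervals.
#' @export
artifact_mask <- function(intervals = NULL) {
  if (is.null(intervals) || NROW(intervals) == 0) {
    m <- matrix(numeric(0), ncol = 2)
    colnames(m) <- c("start_s", "end_s")
    return(structure(list(intervals = m), class = "artifact_mask"))
  }
  m <- as.matrix(intervals)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative artifact times")
  if (any(m[, 2] <= m[, 1])) stop("artifact intervals must have end > start")
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  overlapped <- FALSE
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      last <- nrow(merged)
      if (m[i, 1] <= merged[last, 2]) {
        if (m[i, 1] < merged[last, 2]) overlapped <- TRUE
        merged[last, 2] <- max(merged[last, 2], m[i, 2])
      } else {
        merged <- rbind(merged, m[i, , drop = FALSE])
      }
    }
  }
  if (overlapped) warning("overlapping artifact intervals were merged")
  colnames(merged) <- c("start_s", "end_s")
  structure(list(intervals = merged), class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d interval(s), %.1f s total\n",
              nrow(x$intervals),
              sum(x$intervals[, 2] - x$intervals[, 1])))
  invisible(x)
}

#' Construct a montage (channel labels plus 2-D layout coordinates)
#'
#' @param channel_labels Character vector of unique channel names.
#' @param xy Two-column numeric matrix of layout coordinates (unitless layout
#'   space), rows ordered like `channel_labels`.
#' @return An object of class `montage`.
#' @export
montage <- function(channel_labels, xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) == length(channel_labels))
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  colnames(xy) <- c("x", "y")
  structure(list(channel_labels = as.character(channel_labels), xy = xy),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels\n", length(x$channel_labels)))
  invisible(x)
}

#' Built-in 58-channel 10-20/10-10 montage
#'
#' A schematic 58-channel layout of a 64-electrode cap after removing
#' reference, ground, mastoid and ocular electrodes. Coordinates are a
#' unitless anterior-posterior by left-right grid used for channel adjacency
#' in the cluster test; they are not digitized positions.
#'
#' @param n Optionally keep only the first `n` channels (useful for smaller
#'   synthetic cohorts).
#' @return A [montage()].
#' @export
builtin_montage <- function(n = NULL) {
  rows <- list(
    Fp = list(y = 4,  ch = c(Fp1 = -1, Fp2 = 1)),
    AF = list(y = 3,  ch = c(AF7 = -3, AF3 = -1, AF4 = 1, AF8 = 3)),
    F  = list(y = 2,  ch = c(F7 = -4, F5 = -3, F3 = -2, F1 = -1, Fz = 0,
                             F2 = 1, F4 = 2, F6 = 3, F8 = 4)),
    FC = list(y = 1,  ch = c(FT7 = -4, FC5 = -3, FC3 = -2, FC1 = -1,
                             FC2 = 1, FC4 = 2, FC6 = 3, FT8 = 4)),
    C  = list(y = 0,  ch = c(T7 = -4, C5 = -3, C3 = -2, C1 = -1, Cz = 0,
                             C2 = 1, C4 = 2, C6 = 3, T8 = 4)),
    CP = list(y = -1, ch = c(TP7 = -4, CP5 = -3, CP3 = -2, CP1 = -1, CPz = 0,
                             CP2 = 1, CP4 = 2, CP6 = 3, TP8 = 4)),
    P  = list(y = -2, ch = c(P7 = -4, P5 = -3, P3 = -2, P1 = -1, Pz = 0,
                             P2 = 1, P4 = 2, P6 = 3, P8 = 4)),
    PO = list(y = -3, ch = c(PO7 = -3, PO3 = -1, POz = 0, PO4 = 1, PO8 = 3)),
    O  = list(y = -4, ch = c(O1 = -1, Oz = 0, O2 = 1))
  )
  labels <- character(0); x <- numeric(0); y <- numeric(0)
  for (r in rows) {
    labels <- c(labels, names(r$ch))
    x <- c(x, unname(r$ch))
    y <- c(y, rep(r$y, length(r$ch)))
  }
  m <- montage(labels, cbind(x, y))
  if (!is.null(n)) m <- montage(m$channel_labels[seq_len(n)],
                                m$xy[seq_len(n), , drop = FALSE])
  m
}

# ---------------------------------------------------------------------------
# TSV / JSON readers and writers

#' Read a hypnogram from TSV
#'
#' Expected columns: `epoch_index` (0-based, consecutive) and `stage`.
#'
#' @param path Path to a TSV file.
#' @param epoch_len Epoch length in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len = 30) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(d))) {
    stop("hypnogram TSV must have columns epoch_index, stage")
  }
  d <- d[order(d$epoch_index), ]
  if (!identical(as.integer(d$epoch_index), seq_len(nrow(d)) - 1L)) {
    stop("epoch_index must be 0-based and consecutive")
  }
  hypnogram(d$stage, epoch_len = epoch_len)
}

#' Write a hypnogram to TSV
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read artifact intervals from TSV
#'
#' Expected columns: `start_s`, `end_s` (half-open intervals in seconds).
#' Overlapping intervals are merged with a warning.
#'
#' @param path Path to a TSV file.
#' @return An [artifact_mask()].
#' @export
read_artifacts <- function(path) {
  d <- utils::read.delim(path)
  if (!all(c("start_s", "end_s") %in% names(d))) {
    stop("artifact TSV must have columns start_s, end_s")
  }
  artifact_mask(d[, c("start_s", "end_s")])
}

#' Write artifact intervals to TSV
#' @param art An [artifact_mask()].
#' @param path Output path.
#' @export
write_artifacts <- function(art, path) {
  utils::write.table(as.data.frame(art$intervals), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a montage from TSV (columns: `channel`, `x`, `y`)
#' @param path Path to a TSV file.
#' @return A [montage()].
#' @export
read_montage <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "x", "y") %in% names(d))) {
    stop("montage TSV must have columns channel, x, y")
  }
  montage(d$channel, cbind(d$x, d$y))
}

#' Write a montage to TSV
#' @param mon A [montage()].
#' @param path Output path.
#' @export
write_montage <- function(mon, path) {
  utils::write.table(
    data.frame(channel = mon$channel_labels, x = mon$xy[, 1], y = mon$xy[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format) signal I/O. Continuous EDF with one fixed record
# duration of 1 s; 16-bit samples scaled per channel.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Standard continuous EDF: 1-second data records, per-channel physical
#' scaling over the 16-bit digital range. The recording is truncated to a
#' whole number of seconds (generator output always is one).
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$signal)
  spr <- as.integer(rec$fs)           # samples per 1-s record
  nrec <- ncol(rec$signal) %/% spr
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    m <- max(abs(rec$signal[i, ]), 1e-6)
    pmax_[i] <- m; pmin_[i] <- -m
  }
  fld <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                     collapse = "")
  writeChar(paste0(
    fld(rec$channel_labels, 16), fld(rep("", ns), 80),
    fld(rep("uV", ns), 8),
    fld(formatC(pmin_, format = "g", digits = 7), 8),
    fld(formatC(pmax_, format = "g", digits = 7), 8),
    fld(rep("-32768", ns), 8), fld(rep("32767", ns), 8),
    fld(rep("", ns), 80), fld(rep(spr, ns), 8), fld(rep("", ns), 32)),
    con, eos = NULL)
  # re-read the ascii physical bounds so scaling is exactly invertible
  pmin_r <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  scale <- (pmax_r - pmin_r) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      d <- round((rec$signal[i, idx] - pmin_r[i]) / scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(d, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path Path to an EDF file.
#' @return A [recording()] in microvolts.
#' @export
read_recording_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)               # transducer
  for (i in seq_len(ns)) rd(8)                # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)               # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("EDF with differing per-channel sampling rates is not supported")
  }
  fs <- spr[1] / recdur
  if (fs != PIPELINE_FS) {
    stop("recording sampled at ", fs, " Hz; the pipeline requires ",
         PIPELINE_FS, " Hz (resampling is out of scope)")
  }
  expected <- hbytes + nrec * sum(spr) * 2
  if (file.info(path)$size < expected) {
    stop("EDF data shorter than header declares (channel count mismatch?)")
  }
  sig <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      sig[i, idx] <- (d - dmin_[i]) * scale[i] + pmin_[i]
    }
  }
  recording(sig, fs, labs)
}

#' Read a recording (EDF or binary array + JSON header)
#'
#' `format = "edf"` reads standard 16-bit EDF (physical units converted to
#' microvolts). `format = "bin"` reads the package's lossless pair
#' `<stem>.json` (header: fs, channel labels, sample count) plus
#' `<stem>.dat` (float64 little-endian, channel-major).
#'
#' @param path File path (for `bin`, the `.json` header path or the stem).
#' @param format One of `"edf"`, `"bin"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("edf", "bin")) {
  format <- match.arg(format)
  if (format == "edf") return(read_recording_edf(path))
  stem <- sub("\\.json$", "", path)
  hdr_path <- paste0(stem, ".json")
  dat_path <- paste0(stem, ".dat")
  if (!file.exists(hdr_path) || !file.exists(dat_path)) {
    stop("missing header or data file for: ", stem)
  }
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (hdr$fs != PIPELINE_FS) {
    stop("recording sampled at ", hdr$fs, " Hz; the pipeline requires ",
         PIPELINE_FS, " Hz")
  }
  n <- hdr$n_samples * length(hdr$channel_labels)
  x <- readBin(dat_path, "double", n = n + 1, endian = "little")
  if (length(x) != n) stop("data length does not match header channel count")
  recording(matrix(x, nrow = length(hdr$channel_labels), byrow = TRUE),
            hdr$fs, hdr$channel_labels)
}

#' Write a recording (EDF or binary array + JSON header)
#' @param rec A [recording()].
#' @param path Output path (stem or `.json` path for `bin`).
#' @param format One of `"edf"`, `"bin"`.
#' @return The main output path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "bin")) {
  format <- match.arg(format)
  if (format == "edf") return(write_recording_edf(rec, path))
  stem <- sub("\\.json$", "", path)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         n_samples = ncol(rec$signal), dtype = "float64-le"),
    paste0(stem, ".json"), auto_unbox = TRUE)
  writeBin(as.numeric(t(rec$signal)), paste0(stem, ".dat"), endian = "little")
  invisible(paste0(stem, ".json"))
}

# ---------------------------------------------------------------------------

#' Sample-wise NREM (N2/N3), artifact-free mask
#'
#' @param hyp A [hypnogram()] covering the recording (its span must be at
#'   least `n_samples / fs` seconds; the last epoch may extend beyond).
#' @param art An [artifact_mask()].
#' @param fs Sampling rate in Hz.
#' @param n_samples Recording length in samples.
#' @return A list with `mask` (logical, length `n_samples`, `TRUE` where the
#'   stage is N2 or N3 and the sample lies outside every artifact interval),
#'   `stage_mask` (N2/N3 regardless of artifacts) and `nrem_minutes`
#'   (artifact-free NREM duration; `sum(mask) / fs / 60` exactly).
#' @export
nrem_sample_mask <- function(hyp, art, fs, n_samples) {
  total_s <- n_samples / fs
  if (length(hyp$stages) * hyp$epoch_len < total_s - 1e-9) {
    stop("hypnogram (", length(hyp$stages) * hyp$epoch_len,
         " s) shorter than recording (", total_s, " s)")
  }
  samp_epoch <- pmin(floor((seq_len(n_samples) - 1) / (fs * hyp$epoch_len)) + 1,
                     length(hyp$stages))
  stage_mask <- hyp$stages[samp_epoch] %in% c("N2", "N3")
  art_mask <- artifact_sample_mask(art, fs, n_samples)
  mask <- stage_mask & !art_mask
  list(mask = mask, stage_mask = stage_mask,
       nrem_minutes = sum(mask) / fs / 60)
}

# logical vector marking samples inside any artifact interval
artifact_sample_mask <- function(art, fs, n_samples) {
  m <- logical(n_samples)
  iv <- art$intervals
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      a <- max(1L, floor(iv[i, 1] * fs) + 1L)
      b <- min(n_samples, ceiling(iv[i, 2] * fs))
      if (b >= a) m[a:b] <- TRUE
    }
  }
  m
}
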