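# Channel-wise detection of fast sleep spindles and slow oscillations during
# artifact-free NREM (N2/N3) sleep, event characteristics and topographies,
# and SO-phase coupling of spindles.

#' Detection parameters
#'
#' Defaults implement the standard amplitude-criterion detectors: fast
#' spindles as 12-15 Hz Hilbert-envelope excursions above mean + 1.25 SD for
#' more than 0.5 and less than 3 s; slow oscillations as 0.3-1.25 Hz
#' inter-zero-crossing waves of 0.8-2 s whose trough-to-peak amplitude and
#' trough depth both exceed mean + 1.25 SD of all duration-valid candidates.
#'
#' @param spindle_band,so_band Band edges in Hz.
#' @param filter_order Butterworth order (two-pass / zero-phase).
#' @param envelope_smooth_s Moving-average width applied to the spindle
#'   envelope, seconds.
#' @param envelope_order `"hilbert_first"` (default) rectifies via the
#'   Hilbert transform and then smooths; `"smooth_first"` smooths the
#'   band-passed signal before the Hilbert transform.
#' @param threshold_sd Amplitude criterion in SD units above the mean.
#' @param spindle_dur Open duration interval for spindles, seconds.
#' @param so_dur Closed duration interval for slow oscillations, seconds.
#' @param artifact_pad_s Events must be artifact-free from this long before
#'   their onset until this long after their offset.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(spindle_band = c(12, 15),
                             so_band = c(0.3, 1.25),
                             filter_order = 4,
                             envelope_smooth_s = 0.2,
                             envelope_order = c("hilbert_first", "smooth_first"),
                             threshold_sd = 1.25,
                             spindle_dur = c(0.5, 3),
                             so_dur = c(0.8, 2),
                             artifact_pad_s = 1.0) {
  envelope_order <- match.arg(envelope_order)
  stopifnot(spindle_band[1] > 0, spindle_band[1] < spindle_band[2],
            so_band[1] > 0, so_band[1] < so_band[2],
            spindle_dur[1] < spindle_dur[2], so_dur[1] < so_dur[2],
            threshold_sd > 0)
  structure(as.list(environment()), class = "detection_params")
}

#' Spindle amplitude envelope of a band-passed signal
#'
#' Magnitude of the analytic (Hilbert) signal, smoothed with a centred
#' 200-ms moving average (by default; the smoothing-before-Hilbert reading
#' is available via `order`).
#'
#' @param x Numeric vector, a band-passed single-channel signal.
#' @param fs Sampling rate in Hz.
#' @param smooth_s Moving-average width in seconds.
#' @param order `"hilbert_first"` or `"smooth_first"`.
#' @return Envelope vector of the same length.
#' @export
spindle_envelope <- function(x, fs, smooth_s = 0.2,
                             order = c("hilbert_first", "smooth_first")) {
  order <- match.arg(order)
  w <- as.integer(round(smooth_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  if (order == "hilbert_first") {
    moving_average(Mod(analytic_signal(x)), w)
  } else {
    Mod(analytic_signal(moving_average(x, w)))
  }
}

#' Detect fast sleep spindles
#'
#' Per channel: the recording is band-pass filtered (12-15 Hz, zero-phase
#' Butterworth), the Hilbert envelope computed and smoothed, and the
#' amplitude criterion `mean + threshold_sd * SD` taken over artifact-free
#' N2/N3 samples. Maximal strictly-supra-threshold runs whose duration lies
#' in the open interval `spindle_dur` become events; an event is kept only
#' if every sample lies in N2/N3 and the window from 1 s before onset to 1 s
#' after offset is artifact free. Amplitude is the envelope maximum within
#' the run.
#'
#' @param rec A [recording()] (fs = 200).
#' @param hyp A [hypnogram()] covering the recording.
#' @param art An [artifact_mask()].
#' @param params A [detection_params()].
#' @return A `sleep_events` data frame: channel, kind ("spindle"), onset_s,
#'   offset_s, duration_s, amplitude_uV, peak_time_s (envelope maximum),
#'   so_phase_deg (`NA` until [spindle_so_phase()]).
#' @export
detect_spindles <- function(rec, hyp, art, params = detection_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$signal)
  fs <- rec$fs
  nm <- nrem_sample_mask(hyp, art, fs, n)
  if (!any(nm$mask)) stop("no artifact-free NREM samples in the recording")
  art_samp <- artifact_sample_mask(art, fs, n)
  filt <- butter_bandpass_sos(params$filter_order, params$spindle_band, fs)
  pl <- filtfilt_padlen(n, params$spindle_band, fs)
  pad <- as.integer(round(params$artifact_pad_s * fs))
  art_cum <- c(0L, cumsum(art_samp))
  stage_cum <- c(0L, cumsum(nm$stage_mask))
  ev <- list()
  for (c in seq_len(nrow(rec$signal))) {
    xf <- sos_filtfilt(rec$signal[c, ], filt, padlen = pl)
    env <- spindle_envelope(xf, fs, params$envelope_smooth_s,
                            params$envelope_order)
    thr <- mean(env[nm$mask]) + params$threshold_sd * stats::sd(env[nm$mask])
    runs <- mask_runs(env > thr)
    if (!nrow(runs)) next
    dur <- (runs[, 2] - runs[, 1] + 1L) / fs
    keep <- dur > params$spindle_dur[1] & dur < params$spindle_dur[2]
    runs <- runs[keep, , drop = FALSE]; dur <- dur[keep]
    if (!nrow(runs)) next
    # every sample in N2/N3
    in_stage <- (stage_cum[runs[, 2] + 1L] - stage_cum[runs[, 1]]) ==
      (runs[, 2] - runs[, 1] + 1L)
    # artifact-free with 1-s padding
    a <- pmax(1L, runs[, 1] - pad)
    b <- pmin(n, runs[, 2] + pad)
    art_free <- (art_cum[b + 1L] - art_cum[a]) == 0L
    runs <- runs[in_stage & art_free, , drop = FALSE]
    dur <- dur[in_stage & art_free]
    if (!nrow(runs)) next
    amp <- numeric(nrow(runs)); pk <- numeric(nrow(runs))
    for (j in seq_len(nrow(runs))) {
      seg <- env[runs[j, 1]:runs[j, 2]]
      amp[j] <- max(seg)
      pk[j] <- (runs[j, 1] - 1L + which.max(seg) - 1L) / fs
    }
    ev[[length(ev) + 1]] <- data.frame(
      channel = rec$channel_labels[c], kind = "spindle",
      onset_s = (runs[, 1] - 1L) / fs, offset_s = runs[, 2] / fs,
      duration_s = dur, amplitude_uV = amp, peak_time_s = pk,
      so_phase_deg = NA_real_)
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  rownames(events) <- NULL
  class(events) <- c("sleep_events", "data.frame")
  events
}

#' Detect slow oscillations
#'
#' Per channel on the 0.3-1.25 Hz zero-phase-filtered signal: candidates are
#' the intervals between consecutive positive-to-negative zero crossings
#' whose length lies in the closed interval `so_dur` and that lie entirely
#' in N2/N3. Over all candidates, the mean + 1.25 SD of (a) trough-to-peak
#' amplitude and (b) absolute trough depth are computed; candidates
#' exceeding both criteria become events. Amplitude is stored as the
#' absolute trough depth (positively scaled); the artifact padding rule is
#' the same as for spindles.
#'
#' @inheritParams detect_spindles
#' @return A `sleep_events` data frame with kind `"so"`; `peak_time_s` is
#'   the trough time.
#' @export
detect_slow_oscillations <- function(rec, hyp, art,
                                     params = detection_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$signal)
  fs <- rec$fs
  nm <- nrem_sample_mask(hyp, art, fs, n)
  art_samp <- artifact_sample_mask(art, fs, n)
  filt <- butter_bandpass_sos(params$filter_order, params$so_band, fs)
  pl <- filtfilt_padlen(n, params$so_band, fs)
  pad <- as.integer(round(params$artifact_pad_s * fs))
  art_cum <- c(0L, cumsum(art_samp))
  stage_cum <- c(0L, cumsum(nm$stage_mask))
  ev <- list()
  for (c in seq_len(nrow(rec$signal))) {
    xf <- sos_filtfilt(rec$signal[c, ], filt, padlen = pl)
    # positive-to-negative zero crossings
    dn <- which(xf[-n] > 0 & xf[-1] <= 0)
    if (length(dn) < 2) next
    a <- dn[-length(dn)]; b <- dn[-1]
    dur <- (b - a) / fs
    keep <- dur >= params$so_dur[1] & dur <= params$so_dur[2]
    in_stage <- (stage_cum[b + 1L] - stage_cum[a]) == (b - a + 1L)
    a <- a[keep & in_stage]; b <- b[keep & in_stage]
    dur <- dur[keep & in_stage]
    if (!length(a)) next
    t2p <- numeric(length(a)); trough <- numeric(length(a))
    tr_idx <- integer(length(a))
    for (j in seq_along(a)) {
      seg <- xf[a[j]:b[j]]
      trough[j] <- min(seg)
      t2p[j] <- max(seg) - trough[j]
      tr_idx[j] <- a[j] + which.min(seg) - 1L
    }
    thr_t2p <- mean(t2p) + params$threshold_sd * stats::sd(t2p)
    thr_tr <- mean(abs(trough)) + params$threshold_sd * stats::sd(abs(trough))
    sel <- t2p > thr_t2p & abs(trough) > thr_tr
    if (anyNA(sel)) sel[is.na(sel)] <- FALSE     # single candidate: sd is NA
    pa <- pmax(1L, a - pad); pb <- pmin(n, b + pad)
    art_free <- (art_cum[pb + 1L] - art_cum[pa]) == 0L
    sel <- sel & art_free
    if (!any(sel)) next
    ev[[length(ev) + 1]] <- data.frame(
      channel = rec$channel_labels[c], kind = "so",
      onset_s = (a[sel] - 1L) / fs, offset_s = (b[sel] - 1L) / fs,
      duration_s = dur[sel], amplitude_uV = abs(trough[sel]),
      peak_time_s = (tr_idx[sel] - 1L) / fs, so_phase_deg = NA_real_)
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  rownames(events) <- NULL
  class(events) <- c("sleep_events", "data.frame")
  events
}

#' Per-channel event characteristics (amplitude, duration, density)
#'
#' @param events A `sleep_events` table of one kind.
#' @param hyp,art Hypnogram and artifact mask of the nap the events came
#'   from; density is events per artifact-free NREM minute.
#' @param channel_labels Channel set to report (channels with no events get
#'   `NA` amplitude/duration and density 0).
#' @param fs Sampling rate (default 200).
#' @param n_samples Recording length in samples; defaults to the full
#'   hypnogram span.
#' @return Object of class `event_topography`: data frame with channel,
#'   kind, n_events, amplitude_uV, duration_s, density_per_min; attribute
#'   `nrem_minutes`.
#' @export
characterize_events <- function(events, hyp, art, channel_labels,
                                fs = PIPELINE_FS, n_samples = NULL) {
  kinds <- unique(events$kind)
  if (length(kinds) > 1) stop("events of one kind at a time")
  if (is.null(n_samples)) {
    n_samples <- as.integer(length(hyp$stages) * hyp$epoch_len * fs)
  }
  nrem_min <- nrem_sample_mask(hyp, art, fs, n_samples)$nrem_minutes
  out <- data.frame(channel = channel_labels,
                    kind = if (length(kinds)) kinds else NA_character_,
                    n_events = 0L, amplitude_uV = NA_real_,
                    duration_s = NA_real_, density_per_min = 0)
  for (i in seq_along(channel_labels)) {
    e <- events[events$channel == channel_labels[i], ]
    out$n_events[i] <- nrow(e)
    if (nrow(e)) {
      out$amplitude_uV[i] <- mean(e$amplitude_uV)
      out$duration_s[i] <- mean(e$duration_s)
      out$density_per_min[i] <- nrow(e) / nrem_min
    }
  }
  structure(out, class = c("event_topography", "data.frame"),
            nrem_minutes = nrem_min)
}

#' Extract the SO-band phase at each spindle's envelope maximum
#'
#' For every spindle, a +-2.5 s window around the envelope maximum is
#' band-pass filtered in the SO band (zero-phase Butterworth), Hilbert
#' transformed, and the instantaneous phase at the centre sample taken.
#' Convention: 0 degrees is the SO positive peak (up-state), +-180 degrees
#' the trough. Events whose window would cross a recording edge are skipped
#' (dropped, with the count in attribute `n_skipped`). Each event is also
#' flagged `low_so` when the SO-band envelope at its centre is below the
#' channel's NREM criterion (`mean + threshold_sd * SD`), i.e. when there is
#' no appreciable SO activity to define a phase against.
#'
#' @param rec The nap [recording()].
#' @param events Spindle `sleep_events` (with `peak_time_s`).
#' @param hyp,art Hypnogram and artifacts (for the envelope criterion).
#' @param params A [detection_params()].
#' @param window_s Half window length in seconds (default 2.5).
#' @return `events` with `so_phase_deg` filled in and a logical `low_so`
#'   column; attribute `n_skipped`.
#' @export
spindle_so_phase <- function(rec, events, hyp, art,
                             params = detection_params(), window_s = 2.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$signal)
  fs <- rec$fs
  half <- as.integer(round(window_s * fs))
  filt <- butter_bandpass_sos(params$filter_order, params$so_band, fs)
  nm <- nrem_sample_mask(hyp, art, fs, n)
  pl_full <- filtfilt_padlen(n, params$so_band, fs)
  out <- events
  out$so_phase_deg <- NA_real_
  out$low_so <- NA
  skipped <- logical(nrow(out))
  for (lab in unique(events$channel)) {
    c <- match(lab, rec$channel_labels)
    rows <- which(events$channel == lab)
    # channel-wise envelope criterion for the low-SO flag
    xf_full <- sos_filtfilt(rec$signal[c, ], filt, padlen = pl_full)
    env_full <- Mod(analytic_signal(xf_full))
    env_thr <- mean(env_full[nm$mask]) +
      params$threshold_sd * stats::sd(env_full[nm$mask])
    for (j in rows) {
      ci <- round(events$peak_time_s[j] * fs) + 1L
      if (ci - half < 1L || ci + half > n) {
        skipped[j] <- TRUE
        next
      }
      win <- rec$signal[c, (ci - half):(ci + half)]
      wf <- sos_filtfilt(win, filt, padlen = length(win) - 1L)
      z <- analytic_signal(wf)[half + 1L]
      out$so_phase_deg[j] <- wrap_deg(Arg(z) * 180 / pi)
      out$low_so[j] <- Mod(z) <= env_thr
    }
  }
  out <- out[!skipped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skipped)
  class(out) <- c("sleep_events", "data.frame")
  out
}

#' Split spindles into higher- and lower-coupling halves per channel
#'
#' Per channel, events are ranked by the circular distance of their SO phase
#' to 0 degrees (the up-state); the closer half is the "higher coupling"
#' set. Ties are broken by earlier onset; with an odd count the extra event
#' goes to the higher-coupling set.
#'
#' @param events Spindle `sleep_events` with `so_phase_deg`.
#' @return `events` with an added `coupling` factor (`"higher"`/`"lower"`).
#' @export
split_by_coupling <- function(events) {
  if (!nrow(events)) {
    events$coupling <- character(0)
    return(events)
  }
  if (anyNA(events$so_phase_deg)) stop("events lack SO phases")
  out <- events
  out$coupling <- NA_character_
  for (lab in unique(events$channel)) {
    rows <- which(events$channel == lab)
    d <- abs(wrap_deg(events$so_phase_deg[rows]))
    ord <- order(d, events$onset_s[rows])
    k <- ceiling(length(rows) / 2)
    out$coupling[rows[ord[seq_len(k)]]] <- "higher"
    if (length(rows) > k) {
      out$coupling[rows[ord[(k + 1):length(rows)]]] <- "lower"
    }
  }
  class(out) <- c("sleep_events", "data.frame")
  out
}

#' @export
print.sleep_events <- function(x, ...) {
  cat(sprintf("<sleep_events> %d event(s) (%s) on %d channel(s)\n",
              nrow(x), paste(unique(x$kind), collapse = "+"),
              length(unique(x$channel))))
  invisible(x)
}

#' Write / read an event table as TSV
#' @param events A `sleep_events` data frame.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("sleep_events", "data.frame")
  d
}
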