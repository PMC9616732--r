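# Synthetic cohort generator with full ground truth.
#
# Emulates the statistical structure the analysis assumes: wake recordings
# whose 6-20 Hz oscillatory power is attenuated channel-selectively during
# encoding relative to a vigilance control, NREM naps containing 12-15 Hz
# spindle bursts and 0.3-1.25 Hz slow oscillations with controllable
# per-channel amplitude topographies, von Mises SO-phase coupling of spindle
# centres, and retention scores with a plantable association to the
# encoding-spindle topographic overlap.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a realistic mid-sized nap study: 58-channel scalp EEG at
#' 200 Hz, 5-minute wake recordings, a 30-minute nap that is mostly N2/N3,
#' fast spindles at 2 per minute and slow oscillations at 3 per minute,
#' moderate event signal-to-noise, moderate SO-phase coupling, and a planted
#' encoding-spindle overlap of -0.4 whose across-participant spread drives a
#' retention effect.
#'
#' @param n_participants Number of participants.
#' @param montage A [montage()]; defaults to the built-in 58-channel layout.
#' @param wake_duration_s,sleep_duration_s Recording lengths in seconds.
#' @param stages Optional explicit hypnogram stage vector (30-s epochs); by
#'   default a nap template (brief wake/N1 onset, then N2/N3 cycles with
#'   occasional REM) is built to cover `sleep_duration_s`.
#' @param bg_rms Background EEG RMS amplitude in microvolts.
#' @param bg_beta Exponent of the `1/f^beta` background spectrum.
#' @param bg_white White-noise floor level relative to the `1/f` component.
#' @param wake_osc_rms RMS of the broadband 6-20 Hz oscillatory component in
#'   the wake recordings, microvolts.
#' @param att_max Maximum fractional amplitude attenuation of the 6-20 Hz
#'   component during encoding (0 disables the encoding effect).
#' @param enc_ind_sd Across-participant idiosyncrasy (SD on the latent
#'   attenuation scale) of the encoding topography.
#' @param spindle_rate,so_rate Planted events per artifact-free NREM minute.
#' @param spindle_freq_hz Spindle carrier frequency.
#' @param spindle_dur_range Planted spindle duration range in seconds (full
#'   envelope support, onset to offset).
#' @param so_freq_range SO frequency range in Hz (duration is one cycle).
#' @param spindle_snr,so_snr Event amplitude in units of the RMS of the
#'   background within the event's own band, i.e. the Rayleigh scale of its
#'   Hilbert envelope (spindle: envelope peak; SO: trough depth).
#' @param amp_jitter_sd Log-normal SD of per-event amplitude jitter.
#' @param topo_sd Log-scale SD of per-channel amplitude topographies.
#' @param coupling_kappa von Mises concentration of the spindle-centre SO
#'   phase around 0 degrees (the SO up-state peak); 0 gives uniform phases.
#' @param planted_overlap Target expected Spearman correlation between a
#'   participant's encoding topography and spindle-amplitude topography
#'   (must be in `[-0.95, 0]`).
#' @param overlap_noise SD of the across-participant jitter of the planted
#'   overlap (`Inf` decouples the topographies entirely).
#' @param behavior_effect Slope of retention (percent) on the planted
#'   overlap; negative means stronger overlap (more negative rho) predicts
#'   better retention.
#' @param retention_intercept,retention_sd Intercept and residual SD of the
#'   retention score in percent; scores are clipped to (0, 150].
#' @param artifact_rate_per_min,artifact_dur_s Rate and duration of planted
#'   artifact intervals in the nap.
#' @param seed Integer seed; together with the config it fully determines the
#'   cohort.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 12,
                         montage = builtin_montage(),
                         wake_duration_s = 300,
                         sleep_duration_s = 1800,
                         stages = NULL,
                         bg_rms = 15, bg_beta = 1, bg_white = 0.02,
                         wake_osc_rms = 8,
                         att_max = 0.5, enc_ind_sd = 1,
                         spindle_rate = 2, so_rate = 3,
                         spindle_freq_hz = 13,
                         spindle_dur_range = c(0.8, 1.8),
                         so_freq_range = c(0.6, 1.0),
                         spindle_snr = 4, so_snr = 4,
                         amp_jitter_sd = 0.2, topo_sd = 0.4,
                         coupling_kappa = 4,
                         planted_overlap = -0.4, overlap_noise = 0.2,
                         behavior_effect = -50,
                         retention_intercept = 60, retention_sd = 15,
                         artifact_rate_per_min = 0.1, artifact_dur_s = 5,
                         seed = 1) {
  cfg <- as.list(environment())
  cfg$fs <- PIPELINE_FS
  stopifnot(n_participants >= 1, wake_duration_s > 0, sleep_duration_s > 0,
            spindle_rate >= 0, so_rate >= 0, coupling_kappa >= 0,
            spindle_dur_range[1] > 0.5, spindle_dur_range[2] < 3,
            so_freq_range[1] >= 0.5, so_freq_range[2] <= 1.25)
  if (planted_overlap > 0 || planted_overlap < -0.95) {
    stop("planted_overlap must lie in [-0.95, 0]")
  }
  structure(cfg, class = "synth_config")
}

#' Preset synthetic-cohort configurations
#'
#' `"default"` is [synth_config()] itself. `"high_snr"` raises the event and
#' encoding effect sizes and tightens the planted-overlap jitter, the regime
#' used for parameter-recovery checks. `"null"` plants no encoding effect, no
#' topography overlap and no behaviour link, for calibration of the
#' permutation tests.
#'
#' @param preset One of `"default"`, `"high_snr"`, `"null"`.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(preset = c("default", "high_snr", "null"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(),
    high_snr = list(spindle_snr = 5, so_snr = 5, amp_jitter_sd = 0.1,
                    att_max = 0.7, wake_osc_rms = 12, overlap_noise = 0.05),
    null = list(att_max = 0, planted_overlap = 0, overlap_noise = 0,
                behavior_effect = 0))
  do.call(synth_config, utils::modifyList(base, list(...)))
}

# ---------------------------------------------------------------------------
# background noise model

# Unnormalized background PSD shape on a frequency grid
bg_shape <- function(f, cfg) {
  s <- 1 / (f + 0.5)^cfg$bg_beta + cfg$bg_white
  s[f <= 0] <- 0
  s
}

# Gaussian noise with the background spectrum, scaled to cfg$bg_rms
shaped_noise <- function(n, cfg) {
  f <- (0:(n %/% 2)) * cfg$fs / n
  s <- bg_shape(f, cfg)
  nh <- length(s)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) / sqrt(2)
  X <- sqrt(s) * z
  X[1] <- 0
  full <- c(X, Conj(rev(X[2:(nh - ifelse(n %% 2 == 0, 1, 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * cfg$bg_rms / sqrt(2 * sum(s) / n^2)
}

# Band-limited unit-RMS Gaussian noise (flat spectrum inside band)
band_noise <- function(n, band, fs) {
  f <- (0:(n %/% 2)) * fs / n
  s <- as.numeric(f >= band[1] & f <= band[2])
  nh <- length(s)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) / sqrt(2)
  X <- sqrt(s) * z
  X[1] <- 0
  full <- c(X, Conj(rev(X[2:(nh - ifelse(n %% 2 == 0, 1, 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / sqrt(2 * sum(s) / n^2)
}

#' Band RMS of the synthetic background (analytic)
#'
#' For the Gaussian background with the configured spectrum, the band-limited
#' signal has variance `sigma_band^2`; its Hilbert envelope is Rayleigh with
#' scale `sigma_band`. Planted event amplitudes are multiples of this
#' quantity.
#'
#' @param cfg A `synth_config`.
#' @param band Frequency band in Hz.
#' @param n FFT grid size used for the variance fractions (default: the nap
#'   length).
#' @return Background band RMS in microvolts.
#' @export
background_band_sigma <- function(cfg, band, n = cfg$sleep_duration_s * cfg$fs) {
  f <- (0:(n %/% 2)) * cfg$fs / n
  s <- bg_shape(f, cfg)
  frac <- sum(s[f >= band[1] & f <= band[2]]) / sum(s)
  cfg$bg_rms * sqrt(frac)
}

# ---------------------------------------------------------------------------
# circular helpers

#' Sample from a von Mises distribution (Best-Fisher rejection sampler)
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (0 gives the circular uniform).
#' @return Angles in radians, wrapped to `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) {
    return(wrap_pi(stats::runif(n, -pi, pi) + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    fq <- (1 + r * z) / (r + z)
    cq <- kappa * (r - fq)
    if (cq * (2 - cq) - u[2] > 0 || log(cq / u[2]) + 1 - cq >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(fq)
      i <- i + 1L
    }
  }
  wrap_pi(out)
}

# wrap radians to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Wrap angles in degrees to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Circular mean of angles in degrees
#' @param x Angles in degrees.
#' @return Mean direction in degrees, in (-180, 180].
#' @export
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  wrap_deg(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniform on the circle against a
#' unimodal alternative, using the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`.
#'
#' @param x Angles in degrees.
#' @return List with `rbar` (mean resultant length), `z` (`n * rbar^2`) and
#'   `p`.
#' @export
rayleigh_test <- function(x) {
  r <- x * pi / 180
  n <- length(r)
  rbar <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(rbar = rbar, z = n * rbar^2, p = min(1, p))
}

# ---------------------------------------------------------------------------
# ground-truth planting

#' Plant per-participant ground-truth topographies and behaviour
#'
#' Draws, for every participant, the encoding attenuation topography, the
#' spindle- and SO-amplitude topographies and the retention score. The
#' spindle topography is a mixture of the (rank-normalized) encoding
#' topography and independent noise; the mixture weight `w` is chosen as
#' `w = 2 sin(pi * |rho| / 6)` so that the expected across-channel Spearman
#' correlation between the two topographies equals the participant's planted
#' overlap `rho` (the Pearson-to-Spearman relation for bivariate normal
#' scores). Retention is `intercept + behavior_effect * rho` plus Gaussian
#' noise, clipped to (0, 150].
#'
#' Consumes the RNG stream; [generate_cohort()] seeds it from `cfg$seed`.
#'
#' @param cfg A `synth_config`.
#' @return List of class `synth_truth` with one element per participant:
#'   `enc_loadings` (per-channel attenuation, all <= 0), `spindle_topo` and
#'   `so_topo` (positive, mean 1), `rho_planted`, `retention_pct`, `pre_z`,
#'   `post_z`, and signal seeds.
#' @export
plant_truth <- function(cfg) {
  mon <- cfg$montage
  nch <- length(mon$channel_labels)
  # fixed group profile of encoding attenuation: right temporo-parietal bump
  d2 <- (mon$xy[, 1] - 2)^2 + (mon$xy[, 2] + 1.5)^2
  mu <- stats::qlogis(0.15 + 0.6 * exp(-d2 / 8))
  out <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    g <- mu + cfg$enc_ind_sd * stats::rnorm(nch)
    enc <- -cfg$att_max * stats::plogis(g)
    if (is.infinite(cfg$overlap_noise)) {
      rho <- 0
    } else {
      rho <- cfg$planted_overlap + stats::rnorm(1, 0, cfg$overlap_noise)
      rho <- min(0, max(-0.95, rho))
    }
    w <- 2 * sin(pi * abs(rho) / 6)
    ng <- stats::qnorm((rank(g) - 0.5) / nch)
    tz <- w * ng + sqrt(1 - w^2) * stats::rnorm(nch)
    spindle_topo <- exp(cfg$topo_sd * tz)
    spindle_topo <- spindle_topo / mean(spindle_topo)
    so_topo <- exp(cfg$topo_sd * stats::rnorm(nch))
    so_topo <- so_topo / mean(so_topo)
    retention <- cfg$retention_intercept + cfg$behavior_effect * rho +
      stats::rnorm(1, 0, cfg$retention_sd)
    retention <- min(150, max(0.5, retention))
    pre_z <- atanh(stats::runif(1, 0.75, 0.95))
    out[[i]] <- list(
      id = sprintf("P%02d", i),
      enc_loadings = stats::setNames(enc, mon$channel_labels),
      spindle_topo = stats::setNames(spindle_topo, mon$channel_labels),
      so_topo = stats::setNames(so_topo, mon$channel_labels),
      rho_planted = rho,
      retention_pct = retention,
      pre_z = pre_z,
      post_z = pre_z * retention / 100,
      wake_seed = sample.int(.Machine$integer.max, 1),
      sleep_seed = sample.int(.Machine$integer.max, 1))
  }
  structure(out, class = "synth_truth")
}

# default nap hypnogram: short wake/N1 onset, N2/N3 cycles with brief REM
default_stages <- function(sleep_duration_s, epoch_len = 30) {
  n_epochs <- ceiling(sleep_duration_s / epoch_len)
  cycle <- c(rep("N2", 10), rep("N3", 6), rep("REM", 2))
  stages <- c("W", "W", "N1", "N1",
              rep(cycle, length.out = max(0, n_epochs - 4)))
  stages[seq_len(n_epochs)]
}

# ---------------------------------------------------------------------------
# signal synthesis

#' Generate the paired wake recordings (encoding and vigilance control)
#'
#' Both recordings share the same `1/f` background model and a broadband
#' 6-20 Hz oscillatory component; during encoding the oscillatory amplitude
#' on channel `c` is multiplied by `1 + loading[c]` (loadings <= 0, so power
#' can only decrease).
#'
#' @param cfg A `synth_config`.
#' @param enc_loadings Per-channel attenuation loadings in `[-1, 0]`.
#' @param seed Integer seed for this pair.
#' @return List with `encoding` and `pvt` [recording()]s.
#' @export
generate_wake_pair <- function(cfg, enc_loadings, seed) {
  if (any(enc_loadings > 0)) {
    stop("encoding loadings must be <= 0 (power-decrease convention)")
  }
  nch <- length(cfg$montage$channel_labels)
  stopifnot(length(enc_loadings) == nch)
  set.seed(seed)
  n <- round(cfg$wake_duration_s * cfg$fs)
  enc <- matrix(0, nch, n)
  pvt <- matrix(0, nch, n)
  for (c in seq_len(nch)) {
    enc[c, ] <- shaped_noise(n, cfg) +
      (1 + enc_loadings[c]) * cfg$wake_osc_rms * band_noise(n, c(6, 20), cfg$fs)
    pvt[c, ] <- shaped_noise(n, cfg) +
      cfg$wake_osc_rms * band_noise(n, c(6, 20), cfg$fs)
  }
  list(encoding = recording(enc, cfg$fs, cfg$montage$channel_labels),
       pvt = recording(pvt, cfg$fs, cfg$montage$channel_labels))
}

#' Generate a synthetic nap with embedded spindles and slow oscillations
#'
#' Events are placed only inside artifact-free N2/N3, well separated, on a
#' per-channel slot grid. Each slow oscillation is a single cycle starting at
#' a positive-to-negative zero crossing (trough first, up-state peak second).
#' Each spindle is a sinusoid under a flat-topped envelope with raised-cosine
#' onset/offset ramps (0.25 s), whose centre is placed at the SO phase drawn
#' from von Mises(0 deg, `coupling_kappa`) of a host slow oscillation; 0 deg
#' is the up-state peak. Logged onset/offset delimit the envelope support.
#' Both waveforms are scaled so that the amplitude the detectors measure on
#' the band-pass filtered signal (spindle envelope peak, SO trough depth)
#' equals the logged amplitude, compensating the band-pass attenuation of
#' the finite-length waveforms. If `so_rate` is 0 spindles are planted
#' standalone and their logged phase is `NA`.
#'
#' @param cfg A `synth_config`.
#' @param spindle_topo,so_topo Positive per-channel amplitude multipliers.
#' @param seed Integer seed for this nap.
#' @return List with `recording`, `hypnogram`, `artifacts` and `events` (the
#'   ground-truth log: channel, kind, onset_s, offset_s, duration_s,
#'   amplitude_uV, peak_time_s, so_phase_deg).
#' @export
generate_sleep <- function(cfg, spindle_topo, so_topo, seed) {
  nch <- length(cfg$montage$channel_labels)
  stopifnot(length(spindle_topo) == nch, length(so_topo) == nch,
            all(spindle_topo > 0), all(so_topo > 0))
  set.seed(seed)
  n <- round(cfg$sleep_duration_s * cfg$fs)
  fs <- cfg$fs
  stages <- if (is.null(cfg$stages)) default_stages(cfg$sleep_duration_s)
            else cfg$stages
  hyp <- hypnogram(stages)
  # artifacts: uniform placement over the whole nap
  n_art <- round(cfg$artifact_rate_per_min * cfg$sleep_duration_s / 60)
  art <- if (n_art > 0) {
    starts <- sort(stats::runif(n_art, 0,
                                cfg$sleep_duration_s - cfg$artifact_dur_s))
    suppressWarnings(artifact_mask(cbind(starts, starts + cfg$artifact_dur_s)))
  } else artifact_mask()
  nm <- nrem_sample_mask(hyp, art, fs, n)
  if (cfg$spindle_rate > 0 && nm$nrem_minutes == 0) {
    stop("no artifact-free NREM time to place events in")
  }
  # eligible placement intervals: mask runs shrunk by a safety margin
  margin <- 4
  runs <- mask_runs(nm$mask)
  runs_s <- cbind(runs[, 1, drop = FALSE] / fs + margin,
                  runs[, 2, drop = FALSE] / fs - margin)
  runs_s <- runs_s[runs_s[, 2] > runs_s[, 1], , drop = FALSE]
  lens <- runs_s[, 2] - runs_s[, 1]
  L <- sum(lens)
  n_so <- round(cfg$so_rate * nm$nrem_minutes)
  n_sp <- round(cfg$spindle_rate * nm$nrem_minutes)
  coupled <- n_so > 0
  if (coupled && n_sp > n_so) {
    stop("spindle_rate exceeds so_rate: not every spindle can be coupled ",
         "to its own slow oscillation")
  }
  n_slots <- max(n_so, n_sp)
  env_sd_sp <- background_band_sigma(cfg, c(12, 15), n)
  env_sd_so <- background_band_sigma(cfg, c(0.3, 1.25), n)
  sig <- matrix(0, nch, n)
  ev <- list()
  for (c in seq_len(nch)) {
    sig[c, ] <- shaped_noise(n, cfg)
    if (n_slots == 0) next
    if (L / n_slots < 7) {
      stop("event rate unplaceable without overlap on channel ",
           cfg$montage$channel_labels[c])
    }
    pos <- (seq_len(n_slots) - 0.5) / n_slots * L +
      stats::runif(n_slots, -0.15, 0.15) * L / n_slots
    centers <- map_to_intervals(pos, runs_s)
    so_idx <- if (n_so > 0) sort(sample.int(n_slots, n_so)) else integer(0)
    sp_idx <- if (n_sp > 0) sort(sample.int(
      if (coupled) n_so else n_slots, n_sp)) else integer(0)
    # slow oscillations
    so_t0 <- numeric(0); so_f <- numeric(0); so_amp <- numeric(0)
    if (n_so > 0) {
      so_f <- round(stats::runif(n_so, cfg$so_freq_range[1],
                                 cfg$so_freq_range[2]) / 0.05) * 0.05
      so_amp <- cfg$so_snr * env_sd_so * so_topo[c] *
        exp(stats::rnorm(n_so, 0, cfg$amp_jitter_sd))
      so_t0 <- centers[so_idx] - 0.5 / so_f
      for (j in seq_len(n_so)) {
        idx0 <- round(so_t0[j] * fs) + 1L
        raw <- so_amp[j] / so_gain(so_f[j], fs)
        w <- so_wave(so_f[j], raw, fs)
        len <- round(fs / so_f[j])
        i0 <- idx0 - length(w$pre)
        sig[c, i0:(i0 + length(w$wave) - 1L)] <-
          sig[c, i0:(i0 + length(w$wave) - 1L)] + w$wave
        ev[[length(ev) + 1]] <- data.frame(
          channel = cfg$montage$channel_labels[c], kind = "so",
          onset_s = (idx0 - 1) / fs, offset_s = (idx0 - 1 + len) / fs,
          duration_s = len / fs, amplitude_uV = so_amp[j],
          peak_time_s = (idx0 - 1) / fs + 0.25 / so_f[j],
          so_phase_deg = NA_real_)
      }
    }
    # spindles
    if (n_sp > 0) {
      phi <- rvonmises(n_sp, 0, cfg$coupling_kappa)
      dur <- round(stats::runif(n_sp, cfg$spindle_dur_range[1],
                                cfg$spindle_dur_range[2]) / 0.05) * 0.05
      amp <- cfg$spindle_snr * env_sd_sp * spindle_topo[c] *
        exp(stats::rnorm(n_sp, 0, cfg$amp_jitter_sd))
      for (j in seq_len(n_sp)) {
        if (coupled) {
          k <- sp_idx[j]
          # place envelope max at the drawn SO phase; phase(t) of the host
          # SO -A sin(2 pi f (t - t0)) is 2 pi f (t - t0) + pi/2
          tc <- so_t0[k] + ((phi[j] - pi / 2) %% (2 * pi)) / (2 * pi * so_f[k])
          ph_log <- wrap_deg(phi[j] * 180 / pi)
        } else {
          tc <- centers[sp_idx[j]]
          ph_log <- NA_real_
        }
        raw <- amp[j] / spindle_gain(dur[j], cfg$spindle_freq_hz, fs)
        sig_t <- spindle_waveform(tc, dur[j], raw, cfg$spindle_freq_hz,
                                  fs, stats::runif(1, 0, 2 * pi))
        sig[c, sig_t$idx] <- sig[c, sig_t$idx] + sig_t$wave
        ev[[length(ev) + 1]] <- data.frame(
          channel = cfg$montage$channel_labels[c], kind = "spindle",
          onset_s = tc - dur[j] / 2, offset_s = tc + dur[j] / 2,
          duration_s = dur[j], amplitude_uV = amp[j],
          peak_time_s = tc, so_phase_deg = ph_log)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  events <- events[order(events$channel, events$onset_s), ]
  rownames(events) <- NULL
  class(events) <- c("sleep_events", "data.frame")
  list(recording = recording(sig, fs, cfg$montage$channel_labels),
       hypnogram = hyp, artifacts = art, events = events)
}

# Sinusoid under a flat-topped envelope with raised-cosine ramps; duration
# is the full envelope support (onset to offset)
spindle_waveform <- function(tc, dur, amp, freq, fs, phase0) {
  half <- dur / 2
  tau <- min(0.25, dur / 4)
  i0 <- max(1L, round((tc - half) * fs) + 1L)
  i1 <- round((tc + half) * fs) + 1L
  tt <- ((i0:i1) - 1) / fs - tc
  a <- abs(tt)
  env <- ifelse(a <= half - tau, 1,
                0.5 * (1 + cos(pi * (a - (half - tau)) / tau)))
  env[a > half] <- 0
  list(idx = i0:i1,
       wave = amp * env * cos(2 * pi * freq * tt + phase0))
}

# Attenuation of the detector band-pass on the finite waveforms, cached on
# the (discretized) duration / frequency grids
.gain_cache <- new.env(parent = emptyenv())

spindle_gain <- function(dur, freq, fs) {
  key <- sprintf("sp_%.2f_%g_%g", dur, freq, fs)
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    pad <- round(1.5 * fs)
    w <- spindle_waveform(3, dur, 1, freq, fs, 0)
    x <- numeric(round(6 * fs))
    x[w$idx] <- w$wave
    filt <- butter_bandpass_sos(4, c(12, 15), fs)
    xf <- sos_filtfilt(x, filt)
    g <- max(Mod(analytic_signal(xf)))
    .gain_cache[[key]] <- g
  }
  g
}

# One SO cycle -A sin(2 pi f t) flanked by half-cycle lobes of opposite
# sign (0.35 A), mimicking the surrounding slow activity of an SO train and
# pinning the bounding zero crossings to the cycle edges.
so_wave <- function(f, amp, fs) {
  len <- round(fs / f)
  half <- round(fs / (2 * f))
  tt_pre <- (-(half:1)) / fs
  tt <- (0:(len - 1)) / fs
  tt_post <- (1:half) / fs
  list(pre = 0.35 * amp * -sin(2 * pi * f * tt_pre),
       wave = c(0.35 * amp * -sin(2 * pi * f * tt_pre),
                amp * -sin(2 * pi * f * tt),
                0.35 * amp * -sin(2 * pi * f * tt_post)))
}

so_gain <- function(f, fs) {
  key <- sprintf("so_%.2f_%g", f, fs)
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    x <- numeric(round(16 * fs))
    i0 <- round(8 * fs)
    w <- so_wave(f, 1, fs)
    j0 <- i0 - length(w$pre)
    x[j0:(j0 + length(w$wave) - 1L)] <- w$wave
    filt <- butter_bandpass_sos(4, c(0.3, 1.25), fs)
    xf <- sos_filtfilt(x, filt)
    g <- abs(min(xf))
    .gain_cache[[key]] <- g
  }
  g
}

# start/end sample indices (inclusive) of TRUE runs in a logical vector
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# map positions on the concatenated interval length onto actual times
map_to_intervals <- function(pos, intervals) {
  lens <- intervals[, 2] - intervals[, 1]
  offs <- cumsum(c(0, lens[-length(lens)]))
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    k <- max(which(offs <= pos[i]))
    out[i] <- intervals[k, 1] + min(pos[i] - offs[k], lens[k])
  }
  out
}

empty_events <- function() {
  data.frame(channel = character(0), kind = character(0),
             onset_s = numeric(0), offset_s = numeric(0),
             duration_s = numeric(0), amplitude_uV = numeric(0),
             peak_time_s = numeric(0), so_phase_deg = numeric(0))
}

# ---------------------------------------------------------------------------

#' Generate one participant's full bundle from planted truth
#'
#' @param cfg A `synth_config`.
#' @param truth A `synth_truth` from [plant_truth()].
#' @param i Participant index.
#' @return List with `id`, `wake` (list `encoding`, `pvt`), `sleep` (list
#'   `recording`, `hypnogram`, `artifacts`, `events`) and `behavior` (row
#'   with pre/post Fisher-z scores and retention percent).
#' @export
generate_participant <- function(cfg, truth, i) {
  tr <- truth[[i]]
  wake <- generate_wake_pair(cfg, tr$enc_loadings, tr$wake_seed)
  sleep <- generate_sleep(cfg, tr$spindle_topo, tr$so_topo, tr$sleep_seed)
  list(id = tr$id, wake = wake, sleep = sleep,
       behavior = data.frame(participant = tr$id, pre_z = tr$pre_z,
                             post_z = tr$post_z,
                             retention_pct = tr$retention_pct))
}

#' Generate a complete synthetic cohort
#'
#' Deterministic given the config (including its `seed`): plants the ground
#' truth for every participant, then synthesizes all recordings. For large
#' cohorts prefer [plant_truth()] plus [generate_participant()] to keep only
#' one participant's signals in memory at a time (the pipeline does this).
#'
#' @param cfg A `synth_config`.
#' @return List of class `synth_cohort` with `participants` (list of bundles,
#'   see [generate_participant()]), `truth` and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  truth <- plant_truth(cfg)
  participants <- lapply(seq_len(cfg$n_participants),
                         function(i) generate_participant(cfg, truth, i))
  structure(list(participants = participants, truth = truth, config = cfg),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "<synth_cohort> %d participants, %d channels, wake %gs + nap %gs\n",
    length(x$participants), length(x$config$montage$channel_labels),
    x$config$wake_duration_s, x$config$sleep_duration_s))
  invisible(x)
}
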