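# Config-driven orchestration: simulate (or ingest) a cohort, extract
# encoding patterns, detect sleep events, compute coupling, overlap and all
# group statistics, and emit a reproducible report bundle.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (synthetic cohort from `synth`) or `"ingest"`
#'   (read per-participant files from `participants`).
#' @param synth A [synth_config()] (simulate mode).
#' @param participants Ingest mode: data frame with one row per participant
#'   and columns `id`, `enc_path`, `pvt_path`, `sleep_path`, `hypno_path`,
#'   `artifact_path`, `pre_z`, `post_z` (EDF recordings, TSV annotations).
#' @param montage_path Ingest mode: montage TSV.
#' @param params A [detection_params()].
#' @param n_perm Permutations for both the cluster test and the
#'   topography-shuffling nulls.
#' @param alpha Significance level used for the cluster test.
#' @param reject_pct Percentile for wake epoch rejection.
#' @param fallback_band Frequency band (Hz, inclusive) used to collapse
#'   topographies when the cluster test yields no significant bins.
#' @param seed Seed for the statistical permutations (simulate mode also
#'   seeds the generator from `synth$seed`).
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       synth = synth_config(),
                       participants = NULL, montage_path = NULL,
                       params = detection_params(),
                       n_perm = 1000, alpha = 0.05, reject_pct = 95,
                       fallback_band = c(6, 20), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "ingest") {
    if (is.null(participants) || is.null(montage_path)) {
      stop("ingest mode needs a participants table and a montage path")
    }
    need <- c("id", "enc_path", "pvt_path", "sleep_path", "hypno_path",
              "artifact_path", "pre_z", "post_z")
    miss <- setdiff(need, names(participants))
    if (length(miss)) stop("participants table lacks: ",
                           paste(miss, collapse = ", "))
    paths <- unlist(participants[, c("enc_path", "pvt_path", "sleep_path",
                                     "hypno_path", "artifact_path")])
    gone <- paths[!file.exists(paths)]
    if (length(gone)) stop("missing input file(s): ",
                           paste(gone, collapse = ", "))
  }
  structure(list(mode = mode, synth = synth, participants = participants,
                 montage_path = montage_path, params = params,
                 n_perm = n_perm, alpha = alpha, reject_pct = reject_pct,
                 fallback_band = fallback_band, seed = seed),
            class = "run_config")
}

# per-participant analysis given the recordings; returns topographies
analyze_participant <- function(id, wake_enc, wake_pvt, sleep_rec, hyp, art,
                                cfg) {
  p <- cfg$params
  enc_sp <- epoch_psd(wake_enc, "encoding")
  pvt_sp <- epoch_psd(wake_pvt, "pvt")
  contrast <- power_contrast(enc_sp, pvt_sp,
                             percentile_reject(enc_sp, cfg$reject_pct),
                             percentile_reject(pvt_sp, cfg$reject_pct))
  spindles <- detect_spindles(sleep_rec, hyp, art, p)
  sos <- detect_slow_oscillations(sleep_rec, hyp, art, p)
  spindles <- spindle_so_phase(sleep_rec, spindles, hyp, art, p)
  labels <- sleep_rec$channel_labels
  n_samples <- ncol(sleep_rec$signal)
  topo <- list(
    spindle = characterize_events(spindles, hyp, art, labels,
                                  n_samples = n_samples),
    so = characterize_events(sos, hyp, art, labels, n_samples = n_samples))
  split <- if (nrow(spindles)) split_by_coupling(spindles) else spindles
  topo_hi <- characterize_events(split[split$coupling == "higher", ],
                                 hyp, art, labels, n_samples = n_samples)
  topo_lo <- characterize_events(split[split$coupling == "lower", ],
                                 hyp, art, labels, n_samples = n_samples)
  list(id = id, contrast = contrast, spindles = spindles, sos = sos,
       topo = topo, topo_higher = topo_hi, topo_lower = topo_lo)
}

#' Run the full encoding-sleep overlap pipeline
#'
#' Simulate mode generates each participant, analyzes it, and discards the
#' raw signals before moving on, so memory stays bounded. Stages: wake
#' spectra with percentile rejection and encoding-control contrast; group
#' cluster-based permutation test; per-channel encoding topographies
#' (collapsed over the significant bins, falling back to `fallback_band`
#' when no cluster survives); spindle and SO detection, characteristics and
#' SO-phase coupling; the six overlap correlations per participant; the 2x3
#' repeated-measures ANOVA, Holm-corrected post-hoc tests and partial
#' correlations; the behaviour correlation with both topography-shuffling
#' permutation nulls; and the higher- vs lower-coupling contrast.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory for the report bundle (TSV
#'   tables plus a JSON manifest).
#' @return Object of class `spindletopo_run`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$mode == "simulate") {
    sy <- cfg$synth
    mon <- sy$montage
    set.seed(sy$seed)
    truth <- plant_truth(sy)
    n <- sy$n_participants
    behav <- do.call(rbind, lapply(truth, function(tr) data.frame(
      participant = tr$id, pre_z = tr$pre_z, post_z = tr$post_z)))
    per <- vector("list", n)
    for (i in seq_len(n)) {
      b <- generate_participant(sy, truth, i)
      per[[i]] <- tryCatch(
        analyze_participant(b$id, b$wake$encoding, b$wake$pvt,
                            b$sleep$recording, b$sleep$hypnogram,
                            b$sleep$artifacts, cfg),
        error = function(e) stop("participant ", b$id, ": ",
                                 conditionMessage(e), call. = FALSE))
      rm(b)
    }
  } else {
    mon <- read_montage(cfg$montage_path)
    pt <- cfg$participants
    behav <- data.frame(participant = pt$id, pre_z = pt$pre_z,
                        post_z = pt$post_z)
    per <- vector("list", nrow(pt))
    for (i in seq_len(nrow(pt))) {
      hyp <- read_hypnogram(pt$hypno_path[i])
      art <- read_artifacts(pt$artifact_path[i])
      per[[i]] <- tryCatch(
        analyze_participant(pt$id[i],
                            read_recording(pt$enc_path[i], "edf"),
                            read_recording(pt$pvt_path[i], "edf"),
                            read_recording(pt$sleep_path[i], "edf"),
                            hyp, art, cfg),
        error = function(e) stop("participant ", pt$id[i], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    truth <- NULL
  }
  behav$retention_pct <- suppressWarnings(retention(behav$pre_z, behav$post_z))

  # group encoding pattern
  contrasts <- lapply(per, `[[`, "contrast")
  clus <- cluster_permutation(contrasts, mon, n_perm = cfg$n_perm,
                              cluster_alpha = cfg$alpha, seed = cfg$seed)
  bins <- clus$sig_bins
  used_fallback <- length(bins) == 0
  if (used_fallback) {
    bins <- cfg$fallback_band[1]:cfg$fallback_band[2]
  }
  enc_topos <- lapply(per, function(pp)
    collapse_topography(pp$contrast, bins, participant = pp$id))

  # overlap table: participants x 6 (spindle amp/dur/dens, so amp/dur/dens)
  chars <- c("amplitude", "duration", "density")
  overlaps <- list()
  z_table <- matrix(NA_real_, length(per), 6,
                    dimnames = list(vapply(per, `[[`, "", "id"),
                                    paste(rep(c("spindle", "so"), each = 3),
                                          chars, sep = "_")))
  for (i in seq_along(per)) {
    k <- 0
    for (kind in c("spindle", "so")) {
      for (ch in chars) {
        k <- k + 1
        ov <- topo_overlap(enc_topos[[i]], per[[i]]$topo[[kind]], ch)
        z_table[i, k] <- ov$z
        overlaps[[length(overlaps) + 1]] <- data.frame(
          participant = per[[i]]$id, kind = kind, characteristic = ch,
          rho = ov$rho, z = ov$z, n_channels = ov$n_channels)
      }
    }
  }
  overlap_table <- do.call(rbind, overlaps)

  anova_tab <- rm_anova_2x3(z_table)
  posthoc <- posthoc_tests(z_table)
  # partial correlations among spindle characteristics per participant
  partials <- do.call(rbind, lapply(seq_along(per), function(i) {
    tp <- per[[i]]$topo$spindle
    enc <- enc_topos[[i]]$values[tp$channel]
    data.frame(
      participant = per[[i]]$id,
      amp_given_duration = partial_spearman(enc, tp$amplitude_uV,
                                            tp$duration_s),
      amp_given_density = partial_spearman(enc, tp$amplitude_uV,
                                           tp$density_per_min),
      duration_given_amp = partial_spearman(enc, tp$duration_s,
                                            tp$amplitude_uV),
      density_given_amp = partial_spearman(enc, tp$density_per_min,
                                           tp$amplitude_uV))
  }))

  behcor <- behavior_correlation(z_table[, "spindle_amplitude"],
                                 behav$retention_pct)
  spindle_topos <- lapply(per, function(pp) pp$topo$spindle)
  null_enc <- permutation_null(enc_topos, spindle_topos, behav$retention_pct,
                               "encoding", n_perm = cfg$n_perm,
                               seed = cfg$seed + 1L)
  null_sp <- permutation_null(enc_topos, spindle_topos, behav$retention_pct,
                              "spindle", n_perm = cfg$n_perm,
                              seed = cfg$seed + 2L)
  z_hi <- vapply(seq_along(per), function(i)
    topo_overlap(enc_topos[[i]], per[[i]]$topo_higher, "amplitude")$z, 0)
  z_lo <- vapply(seq_along(per), function(i)
    topo_overlap(enc_topos[[i]], per[[i]]$topo_lower, "amplitude")$z, 0)
  coupling <- coupling_contrast(z_hi, z_lo)

  run <- structure(list(
    config = cfg, montage = mon, behavior = behav,
    cluster = clus, sig_bins = bins, used_fallback = used_fallback,
    enc_topos = enc_topos, participants = per,
    overlap_table = overlap_table, z_table = z_table,
    anova = anova_tab, posthoc = posthoc, partials = partials,
    behavior_correlation = behcor,
    null_encoding = null_enc, null_spindle = null_sp,
    coupling = coupling,
    truth = if (cfg$mode == "simulate") truth else NULL),
    class = "spindletopo_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.spindletopo_run <- function(x, ...) {
  n <- nrow(x$z_table)
  cat(sprintf("<spindletopo_run> %s, %d participants, %d channels\n",
              x$config$mode, n, length(x$montage$channel_labels)))
  cat(sprintf("  significant bins: %s%s\n",
              if (length(x$sig_bins)) paste(range(x$sig_bins), collapse = "-")
              else "none",
              if (x$used_fallback) " (fallback band)" else " Hz"))
  cat(sprintf("  mean spindle-amplitude overlap rho = %.3f\n",
              mean(tanh(x$z_table[, "spindle_amplitude"]))))
  cat(sprintf("  behaviour correlation r = %.3f (p = %.4f)\n",
              x$behavior_correlation$r, x$behavior_correlation$p))
  cat(sprintf("  permutation p: encoding-shuffle %.4f, spindle-shuffle %.4f\n",
              x$null_encoding$p, x$null_spindle$p))
  invisible(x)
}

#' @export
summary.spindletopo_run <- function(object, ...) {
  print(object)
  cat("\nRepeated-measures ANOVA (event type x characteristic):\n")
  print(object$anova, digits = 4)
  cat("\nPost-hoc tests (Holm within family):\n")
  print(object$posthoc, digits = 4)
  invisible(object)
}

#' Write a run's report bundle to a directory
#'
#' TSV tables (overlaps, z table, event-topography summaries, statistics,
#' behaviour, encoding topographies, significant bins) plus a JSON manifest
#' with the configuration, seeds and a config hash.
#'
#' @param run A `spindletopo_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$overlap_table, "overlaps.tsv")
  zt <- data.frame(participant = rownames(run$z_table), run$z_table)
  wt(zt, "overlap_z_table.tsv")
  wt(run$behavior, "behavior.tsv")
  wt(run$anova, "anova.tsv")
  wt(run$posthoc, "posthoc.tsv")
  wt(run$partials, "partial_correlations.tsv")
  enc <- do.call(rbind, lapply(run$enc_topos, function(e) data.frame(
    participant = e$participant, channel = names(e$values),
    delta_power = unname(e$values))))
  wt(enc, "encoding_topographies.tsv")
  topo <- do.call(rbind, lapply(run$participants, function(pp) {
    rbind(cbind(participant = pp$id, as.data.frame(pp$topo$spindle)),
          cbind(participant = pp$id, as.data.frame(pp$topo$so)))
  }))
  wt(topo, "event_topographies.tsv")
  events <- do.call(rbind, lapply(run$participants, function(pp) {
    cbind(participant = pp$id,
          as.data.frame(rbind(as.data.frame(pp$spindles)[
            setdiff(names(pp$spindles), c("low_so", "coupling"))],
            as.data.frame(pp$sos))))
  }))
  wt(events, "events.tsv")
  stats_rows <- data.frame(
    name = c("behavior_r", "behavior_p", "perm_p_encoding_shuffle",
             "perm_p_spindle_shuffle", "coupling_t", "coupling_p"),
    value = c(run$behavior_correlation$r, run$behavior_correlation$p,
              run$null_encoding$p, run$null_spindle$p,
              run$coupling$t, run$coupling$p))
  wt(stats_rows, "statistics.tsv")
  cfg_json <- jsonlite::serializeJSON(run$config)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("spindletopo")),
    mode = run$config$mode,
    n_participants = nrow(run$z_table),
    n_perm = run$config$n_perm,
    seed = run$config$seed,
    synth_seed = if (run$config$mode == "simulate") run$config$synth$seed
                 else NULL,
    sig_bins = run$sig_bins,
    used_fallback = run$used_fallback,
    config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
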