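test_that("generation is fully deterministic given config and seed", {
  cfg <- small_nap_config(2, 5, seed = 11)
  a <- generate_sleep(cfg, c(1, 1.2), c(1, 0.9), seed = 7)
  b <- generate_sleep(cfg, c(1, 1.2), c(1, 0.9), seed = 7)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$events, b$events)
  w1 <- generate_wake_pair(cfg, c(-0.2, 0), seed = 3)
  w2 <- generate_wake_pair(cfg, c(-0.2, 0), seed = 3)
  expect_identical(w1$encoding$signal, w2$encoding$signal)
})

test_that("event counts follow the configured rates exactly", {
  cfg <- small_nap_config(2, 30, spindle_rate = 2, so_rate = 3, seed = 5)
  sl <- generate_sleep(cfg, c(1, 1), c(1, 1), seed = 9)
  nm <- nrem_sample_mask(sl$hypnogram, sl$artifacts, 200,
                         ncol(sl$recording$signal))
  for (ch in c("Fp1", "Fp2")) {
    ev <- sl$events[sl$events$channel == ch, ]
    expect_equal(sum(ev$kind == "spindle"), round(2 * nm$nrem_minutes))
    expect_equal(sum(ev$kind == "so"), round(3 * nm$nrem_minutes))
  }
  # no spindles when the rate is zero
  cfg0 <- small_nap_config(1, 5, spindle_rate = 0, seed = 5)
  sl0 <- generate_sleep(cfg0, 1, 1, seed = 2)
  expect_false(any(sl0$events$kind == "spindle"))
})

test_that("every logged event lies inside N2/N3 and clear of artifacts", {
  cfg <- synth_config(montage = builtin_montage(3), sleep_duration_s = 1200,
                      artifact_rate_per_min = 0.5, seed = 21)
  sl <- generate_sleep(cfg, rep(1, 3), rep(1, 3), seed = 4)
  n <- ncol(sl$recording$signal)
  nm <- nrem_sample_mask(sl$hypnogram, sl$artifacts, 200, n)
  for (i in seq_len(nrow(sl$events))) {
    a <- floor(sl$events$onset_s[i] * 200) + 1
    b <- ceiling(sl$events$offset_s[i] * 200)
    expect_true(all(nm$stage_mask[a:b]))
  }
  # 1-s padded artifact-free requirement
  art <- sl$artifacts$intervals
  if (nrow(art)) {
    for (i in seq_len(nrow(sl$events))) {
      expect_false(any(art[, 1] < sl$events$offset_s[i] + 1 &
                         art[, 2] > sl$events$onset_s[i] - 1))
    }
  }
  # within a kind, events on a channel are at least 2 s apart
  for (ch in unique(sl$events$channel)) {
    for (k in c("spindle", "so")) {
      ev <- sl$events[sl$events$channel == ch & sl$events$kind == k, ]
      if (nrow(ev) > 1) expect_gt(min(diff(sort(ev$onset_s))), 2)
    }
  }
})

test_that("planted overlap is calibrated: mean realized rho within 0.05", {
  cfg <- synth_config(n_participants = 200, planted_overlap = -0.6,
                      overlap_noise = 0, seed = 31)
  set.seed(cfg$seed)
  tr <- plant_truth(cfg)
  rhos <- vapply(tr, function(t)
    as.numeric(spearman_rho(t$enc_loadings, t$spindle_topo)), 0)
  expect_lt(abs(mean(rhos) - (-0.6)), 0.05)

  # decoupled topographies give near-zero overlap
  cfg0 <- synth_config(n_participants = 200, overlap_noise = Inf, seed = 32)
  set.seed(cfg0$seed)
  tr0 <- plant_truth(cfg0)
  rho0 <- vapply(tr0, function(t)
    as.numeric(spearman_rho(t$enc_loadings, t$spindle_topo)), 0)
  expect_lt(abs(mean(rho0)), 0.05)
})

test_that("no behaviour effect breaks the overlap-retention association", {
  cfg <- synth_config(n_participants = 200, behavior_effect = 0, seed = 41)
  set.seed(cfg$seed)
  tr <- plant_truth(cfg)
  r <- cor(vapply(tr, `[[`, 0, "rho_planted"),
           vapply(tr, `[[`, 0, "retention_pct"))
  expect_lt(abs(r), 0.2)
  # retention stays within its (0, 150] scale
  ret <- vapply(tr, `[[`, 0, "retention_pct")
  expect_true(all(ret > 0 & ret <= 150))
})

test_that("wake pair plants channel-selective 6-20 Hz power decreases", {
  cfg <- synth_config(montage = builtin_montage(6), wake_duration_s = 180,
                      seed = 51)
  in_band <- function(x) {
    rec <- recording(matrix(x, nrow = 1), 200, "x")
    mean(bandpass(rec, c(6, 20))$signal^2)
  }
  # zero loadings: power ratio near 1 on every channel
  wp0 <- generate_wake_pair(cfg, rep(0, 6), seed = 1)
  r0 <- vapply(1:6, function(c) in_band(wp0$encoding$signal[c, ]) /
                 in_band(wp0$pvt$signal[c, ]), 0)
  expect_true(all(abs(r0 - 1) < 0.15))

  # a single fully attenuated channel has the smallest ratio
  load1 <- c(0, 0, -1, 0, 0, 0)
  wp1 <- generate_wake_pair(cfg, load1, seed = 2)
  r1 <- vapply(1:6, function(c) in_band(wp1$encoding$signal[c, ]) /
                 in_band(wp1$pvt$signal[c, ]), 0)
  expect_identical(which.min(r1), 3L)

  # i.i.d. loadings rank-correlate with the measured per-channel power change
  set.seed(3)
  load2 <- -runif(6, 0, 0.8)
  wp2 <- generate_wake_pair(cfg, load2, seed = 4)
  r2 <- vapply(1:6, function(c) in_band(wp2$encoding$signal[c, ]) /
                 in_band(wp2$pvt$signal[c, ]), 0)
  expect_gte(as.numeric(spearman_rho(load2, r2)), 0.8)

  expect_error(generate_wake_pair(cfg, c(0.1, rep(0, 5)), seed = 1),
               "decrease")
})

test_that("von Mises sampler hits its mean and the uniform limit", {
  set.seed(6)
  ph <- rvonmises(500, 0, 5) * 180 / pi
  expect_lt(abs(circ_mean_deg(ph)), 10)
  unif <- rvonmises(500, 0, 0) * 180 / pi
  expect_gt(rayleigh_test(unif)$p, 0.05)
})

test_that("coupled spindle phases follow the configured concentration", {
  cfg <- small_nap_config(2, 20, coupling_kappa = 0, seed = 61)
  sl <- generate_sleep(cfg, c(1, 1), c(1, 1), seed = 3)
  ph <- sl$events$so_phase_deg[sl$events$kind == "spindle"]
  expect_gt(rayleigh_test(ph)$p, 0.01)

  cfgk <- small_nap_config(2, 20, coupling_kappa = 8, seed = 62)
  slk <- generate_sleep(cfgk, c(1, 1), c(1, 1), seed = 3)
  phk <- slk$events$so_phase_deg[slk$events$kind == "spindle"]
  expect_lt(abs(circ_mean_deg(phk)), 15)
  expect_lt(rayleigh_test(phk)$p, 0.001)
})

test_that("a full small cohort bundles consistent pieces", {
  cfg <- synth_config(n_participants = 3, montage = builtin_montage(4),
                      wake_duration_s = 60, sleep_duration_s = 300,
                      stages = rep("N2", 10), seed = 71)
  coh <- generate_cohort(cfg)
  expect_length(coh$participants, 3)
  b <- coh$participants[[2]]
  expect_equal(nrow(b$wake$encoding$signal), 4)
  expect_equal(ncol(b$sleep$recording$signal), 300 * 200)
  expect_identical(b$behavior$retention_pct,
                   coh$truth[[2]]$retention_pct)
  # regenerating the same participant reproduces it exactly
  b2 <- generate_participant(cfg, coh$truth, 2)
  expect_identical(b2$sleep$recording$signal, b$sleep$recording$signal)
})
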