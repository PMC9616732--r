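test_that("spindle detector recovers planted bursts and obeys its bounds", {
  cfg <- small_nap_config(2, 20, spindle_snr = 5, so_snr = 4,
                          amp_jitter_sd = 0.1, seed = 91)
  sl <- generate_sleep(cfg, c(1, 1), c(1, 1), seed = 13)
  sp <- detect_spindles(sl$recording, sl$hypnogram, sl$artifacts)
  tru <- sl$events[sl$events$kind == "spindle", ]
  expect_gte(match_recall(sp, tru), 0.85)
  expect_gte(match_precision(sp, tru), 0.85)
  expect_true(all(sp$duration_s > 0.5 & sp$duration_s < 3))
  expect_true(all(sp$amplitude_uV > 0))
})

test_that("sub-duration bursts are not detected", {
  # a 0.3 s burst violates the 'more than 0.5 s' criterion
  fs <- 200
  set.seed(14)
  cfg <- small_nap_config(1, 10, spindle_rate = 0, so_rate = 0, seed = 92)
  sl <- generate_sleep(cfg, 1, 1, seed = 15)
  x <- sl$recording$signal[1, ]
  sig <- background_band_sigma(cfg, c(12, 15))
  tt <- seq(-0.15, 0.15, by = 1 / fs)
  burst <- 8 * sig * cos(2 * pi * 13 * tt) *
    0.5 * (1 + cos(pi * tt / 0.15))
  ctr <- 60 * fs
  x[ctr:(ctr + length(burst) - 1)] <- x[ctr:(ctr + length(burst) - 1)] + burst
  rec <- recording(matrix(x, 1), fs, "Fp1")
  sp <- detect_spindles(rec, sl$hypnogram, sl$artifacts)
  expect_false(any(abs(sp$peak_time_s - 60) < 0.3))
})

test_that("detectors are equivariant to amplitude scaling", {
  cfg <- small_nap_config(1, 10, spindle_snr = 5, so_snr = 4, seed = 93)
  sl <- generate_sleep(cfg, 1, 1, seed = 17)
  rec10 <- recording(sl$recording$signal * 10, 200,
                     sl$recording$channel_labels)
  for (det in list(detect_spindles, detect_slow_oscillations)) {
    e1 <- det(sl$recording, sl$hypnogram, sl$artifacts)
    e10 <- det(rec10, sl$hypnogram, sl$artifacts)
    expect_equal(e1$onset_s, e10$onset_s)
    expect_equal(e1$offset_s, e10$offset_s)
    expect_equal(e10$amplitude_uV, 10 * e1$amplitude_uV, tolerance = 1e-9)
  }
})

test_that("slow-oscillation detector rejects out-of-window durations", {
  # a 0.4 Hz half-wave spans 2.5 s between down-crossings: outside [0.8, 2]
  fs <- 200
  cfg <- small_nap_config(1, 10, spindle_rate = 0, so_rate = 0, seed = 94)
  sl <- generate_sleep(cfg, 1, 1, seed = 19)
  x <- sl$recording$signal[1, ]
  tt <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  ctr <- 100 * fs
  x[ctr:(ctr + length(tt) - 1)] <- x[ctr:(ctr + length(tt) - 1)] -
    60 * sin(2 * pi * 0.4 * tt)
  rec <- recording(matrix(x, 1), fs, "Fp1")
  so <- detect_slow_oscillations(rec, sl$hypnogram, sl$artifacts)
  expect_false(any(abs(so$peak_time_s - (100 + 0.625)) < 0.3))
  expect_true(all(so$duration_s >= 0.8 & so$duration_s <= 2))
})

test_that("an equal-amplitude oscillation yields no events above mean+1.25SD", {
  # degenerate population: every candidate identical, nothing exceeds the
  # criterion
  fs <- 200
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  rec <- recording(matrix(-40 * sin(2 * pi * 0.75 * t), 1), fs, "Fp1")
  hyp <- hypnogram(rep("N2", 20))
  so <- detect_slow_oscillations(rec, hyp, artifact_mask())
  # only filter edge transients can nudge a cycle above the degenerate
  # threshold; the interior must be empty
  interior <- so[so$onset_s > 10 & so$offset_s < 590, ]
  expect_equal(nrow(interior), 0)
})

test_that("event characteristics conserve density and handle empties", {
  cfg <- small_nap_config(2, 30, spindle_rate = 2, seed = 95)
  sl <- generate_sleep(cfg, c(1, 1), c(1, 1), seed = 23)
  nm <- nrem_sample_mask(sl$hypnogram, sl$artifacts, 200,
                         ncol(sl$recording$signal))
  ev <- sl$events[sl$events$kind == "spindle", ]
  class(ev) <- c("sleep_events", "data.frame")
  topo <- characterize_events(ev, sl$hypnogram, sl$artifacts,
                              cfg$montage$channel_labels,
                              n_samples = ncol(sl$recording$signal))
  expect_equal(topo$density_per_min, c(2, 2))
  # density times time equals the integer count exactly
  expect_equal(topo$density_per_min * attr(topo, "nrem_minutes"),
               topo$n_events)

  none <- characterize_events(ev[0, ], sl$hypnogram, sl$artifacts,
                              cfg$montage$channel_labels,
                              n_samples = ncol(sl$recording$signal))
  expect_true(all(none$density_per_min == 0))
  expect_true(all(is.na(none$amplitude_uV)))
})

test_that("events near artifacts are dropped by the 1-s padding rule", {
  cfg <- small_nap_config(1, 10, spindle_snr = 6, amp_jitter_sd = 0,
                          seed = 96)
  sl <- generate_sleep(cfg, 1, 1, seed = 29)
  sp0 <- detect_spindles(sl$recording, sl$hypnogram, sl$artifacts)
  expect_gt(nrow(sp0), 0)
  # an artifact placed 0.5 s after one detected event must remove it
  victim <- sp0[1, ]
  art <- artifact_mask(cbind(victim$offset_s + 0.5, victim$offset_s + 0.6))
  sp1 <- detect_spindles(sl$recording, sl$hypnogram, art)
  expect_false(any(abs(sp1$onset_s - victim$onset_s) < 0.1))
})

test_that("SO phase extraction recovers planted peak and trough placements", {
  # kappa high: phases concentrate at the up-state (0 deg)
  cfg <- small_nap_config(2, 20, coupling_kappa = 50, spindle_snr = 5,
                          so_snr = 5, amp_jitter_sd = 0.1, seed = 97)
  sl <- generate_sleep(cfg, c(1, 1), c(1, 1), seed = 31)
  tru <- sl$events[sl$events$kind == "spindle", ]
  class(tru) <- c("sleep_events", "data.frame")
  ph <- spindle_so_phase(sl$recording, tru, sl$hypnogram, sl$artifacts)
  expect_lt(abs(circ_mean_deg(ph$so_phase_deg)), 15)

  # trough placement: shift planted phases by 180 deg via mu in the sampler
  err <- wrap_deg(ph$so_phase_deg -
                    tru$so_phase_deg[match(paste(ph$channel, ph$peak_time_s),
                                           paste(tru$channel,
                                                 tru$peak_time_s))])
  expect_lt(abs(circ_mean_deg(err)), 15)
  expect_gt(rayleigh_test(ph$so_phase_deg)$rbar, 0.8)
})

test_that("phases over flat background are flagged low-SO", {
  cfg <- small_nap_config(1, 10, spindle_snr = 6, so_rate = 0, seed = 98)
  sl <- generate_sleep(cfg, 1, 1, seed = 37)
  sp <- detect_spindles(sl$recording, sl$hypnogram, sl$artifacts)
  ph <- spindle_so_phase(sl$recording, sp, sl$hypnogram, sl$artifacts)
  expect_true(all(is.finite(ph$so_phase_deg)))
  # no SO activity anywhere: most events sit below the envelope criterion
  expect_gt(mean(ph$low_so), 0.5)
})

test_that("coupling split ranks by circular distance with documented ties", {
  ev <- structure(data.frame(channel = "Cz", kind = "spindle",
                             onset_s = 1:2, offset_s = 2:3, duration_s = 1,
                             amplitude_uV = 1, peak_time_s = 1:2,
                             so_phase_deg = c(10, 170)),
                  class = c("sleep_events", "data.frame"))
  sp <- split_by_coupling(ev)
  expect_identical(sp$coupling[sp$so_phase_deg == 10], "higher")
  expect_identical(sp$coupling[sp$so_phase_deg == 170], "lower")

  ev4 <- ev[c(1, 1, 1, 1), ]
  ev4$onset_s <- 1:4; ev4$peak_time_s <- 1:4
  ev4$so_phase_deg <- c(-5, 5, 175, -175)
  sp4 <- split_by_coupling(ev4)
  expect_setequal(sp4$so_phase_deg[sp4$coupling == "higher"], c(-5, 5))

  # odd count: the extra event joins the higher-coupling set
  ev3 <- ev4[1:3, ]
  sp3 <- split_by_coupling(ev3)
  expect_identical(sum(sp3$coupling == "higher"), 2L)

  # von Mises sample: higher set is closer to 0 on average
  set.seed(7)
  evv <- ev4[rep(1, 100), ]
  evv$onset_s <- 1:100
  evv$so_phase_deg <- rvonmises(100, 0, 5) * 180 / pi
  spv <- split_by_coupling(evv)
  expect_lt(mean(abs(wrap_deg(spv$so_phase_deg[spv$coupling == "higher"]))),
            mean(abs(wrap_deg(spv$so_phase_deg[spv$coupling == "lower"]))))
})

test_that("event tables round-trip through TSV", {
  cfg <- small_nap_config(1, 5, seed = 99)
  sl <- generate_sleep(cfg, 1, 1, seed = 41)
  p <- tempfile(fileext = ".tsv")
  write_events(sl$events, p)
  back <- read_events(p)
  expect_equal(back$onset_s, sl$events$onset_s)
  expect_identical(back$kind, sl$events$kind)
})
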