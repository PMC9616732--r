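test_that("epoch spectra localize tones and scale like power", {
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rec <- recording(matrix(sin(2 * pi * 10 * t), nrow = 1), fs, "Cz")
  sp <- epoch_psd(rec)
  expect_equal(dim(sp$power)[3], 20)
  expect_identical(sp$freqs, 1:20)
  expect_true(all(apply(sp$power[, 1, ], 1, which.max) == 10))
  # a sinusoid of amplitude 1 carries power 1/2 in its bin
  expect_equal(mean(sp$power[, 1, 10]), 0.5, tolerance = 0.05)

  expect_true(all(epoch_psd(recording(matrix(0, 1, 2000), fs, "Cz"))$power == 0))

  # doubling a white-noise amplitude quadruples every bin's mean power
  set.seed(2)
  x <- rnorm(length(t))
  p1 <- apply(epoch_psd(recording(matrix(x, 1), fs, "Cz"))$power[, 1, ], 2, mean)
  p2 <- apply(epoch_psd(recording(matrix(2 * x, 1), fs, "Cz"))$power[, 1, ], 2,
              mean)
  expect_equal(p2 / p1, rep(4, 20), tolerance = 1e-10)

  expect_error(epoch_psd(recording(matrix(0, 1, 300), fs, "Cz")), "2 s")
})

test_that("percentile rejection excludes exactly the strict upper tail", {
  set.seed(3)
  pw <- array(runif(100 * 2 * 20), dim = c(100, 2, 20))
  sp <- structure(list(power = pw, freqs = 1:20,
                       channel_labels = c("a", "b"), condition = NULL),
                  class = "spectra_set")
  keep <- percentile_reject(sp, 95)
  # type-7 95th percentile of 100 distinct values: exactly 5 strictly above
  expect_true(all(apply(!keep, c(2, 3), sum) == 5))
  # sort-based oracle for one cell
  v <- pw[, 1, 1]
  expect_identical(which(!keep[, 1, 1]), which(v > quantile(v, 0.95)))

  expect_true(all(percentile_reject(sp, 100)))
  spc <- sp; spc$power[] <- 1
  expect_true(all(percentile_reject(spc, 95)))
  expect_error(percentile_reject(sp, 50), "pct")
  expect_error(percentile_reject(sp, 101), "pct")
})

test_that("contrast is the per-cell retained-epoch mean difference", {
  set.seed(4)
  pw <- array(rexp(40 * 2 * 20), dim = c(40, 2, 20))
  mk <- function(p) structure(list(power = p, freqs = 1:20,
                                   channel_labels = c("a", "b"),
                                   condition = NULL), class = "spectra_set")
  cm0 <- power_contrast(mk(pw), mk(pw))
  expect_true(all(cm0$delta_power == 0))

  # halving amplitude in 6-20 Hz on one channel: negative delta only there
  pw2 <- pw
  pw2[, 2, 6:20] <- pw2[, 2, 6:20] * 0.25
  cm <- power_contrast(mk(pw2), mk(pw))
  expect_true(all(cm$delta_power[2, 6:20] < 0))
  expect_true(all(cm$delta_power[1, ] == 0))
  expect_true(all(cm$delta_power[2, 1:5] == 0))

  # masked means: oracle by direct computation on one cell
  ke <- percentile_reject(mk(pw2), 90)
  kp <- percentile_reject(mk(pw), 90)
  cmm <- power_contrast(mk(pw2), mk(pw), ke, kp)
  cell <- mean(pw2[ke[, 1, 7], 1, 7]) - mean(pw[kp[, 1, 7], 1, 7])
  expect_equal(cmm$delta_power[1, 7], cell)

  bad <- mk(pw); bad$freqs <- 2:21
  expect_error(power_contrast(mk(pw), bad), "bins")
})

test_that("cluster permutation flags planted decreases and nothing else", {
  mon <- builtin_montage(12)
  mk_cm <- function(m) structure(list(delta_power = m, freqs = 1:20,
                                      channel_labels = mon$channel_labels),
                                 class = "contrast_map")
  set.seed(5)
  maps <- lapply(1:10, function(i) {
    m <- matrix(rnorm(12 * 20, sd = 0.5), 12, 20)
    m[, 6:20] <- m[, 6:20] - 2
    mk_cm(m)
  })
  ct <- cluster_permutation(maps, mon, n_perm = 300, seed = 1)
  expect_true(all(6:20 %in% ct$sig_bins))
  expect_false(any(1:4 %in% ct$sig_bins))
  expect_true(all(vapply(ct$clusters, `[[`, 0, "p") >= 1 / 301))

  expect_error(cluster_permutation(maps[1], mon, n_perm = 10),
               "at least 2")
})

test_that("cluster test is invariant to adjacency-preserving relabeling", {
  mon <- builtin_montage(9)
  set.seed(6)
  base <- lapply(1:8, function(i) matrix(rnorm(9 * 20, sd = 1), 9, 20))
  base <- lapply(base, function(m) { m[, 8:14] <- m[, 8:14] - 1.2; m })
  mk <- function(m, labels) structure(
    list(delta_power = m, freqs = 1:20, channel_labels = labels),
    class = "contrast_map")
  ct1 <- cluster_permutation(lapply(base, mk, labels = mon$channel_labels),
                             mon, n_perm = 200, seed = 9)
  # reverse the channel order everywhere (montage row order carries adjacency)
  perm <- rev(seq_len(9))
  mon2 <- montage(mon$channel_labels[perm], mon$xy[perm, ])
  ct2 <- cluster_permutation(
    lapply(base, function(m) mk(m[perm, ], mon2$channel_labels)),
    mon2, n_perm = 200, seed = 9)
  expect_identical(ct1$sig_bins, ct2$sig_bins)
  expect_equal(sort(vapply(ct1$clusters, `[[`, 0, "mass")),
               sort(vapply(ct2$clusters, `[[`, 0, "mass")))
})

test_that("topography collapse averages the chosen bins per channel", {
  m <- matrix(seq_len(40) / 10, nrow = 2)
  cm <- structure(list(delta_power = m, freqs = 1:20,
                       channel_labels = c("a", "b")), class = "contrast_map")
  one <- collapse_topography(cm, 7)
  expect_equal(unname(one$values), m[, 7])
  several <- collapse_topography(cm, c(6, 8, 10))
  expect_equal(unname(several$values), rowMeans(m[, c(6, 8, 10)]))
  cmc <- cm; cmc$delta_power[] <- -1.5
  expect_equal(unname(collapse_topography(cmc, 6:20)$values), c(-1.5, -1.5))
  expect_error(collapse_topography(cm, integer(0)), "6-20")
  expect_error(collapse_topography(cm, 25), "not present")
})

test_that("a planted single-channel decrease is the topography minimum", {
  cfg <- synth_config(montage = builtin_montage(6), wake_duration_s = 120,
                      seed = 81)
  load <- c(0, 0, 0, -0.9, 0, 0)
  wp <- generate_wake_pair(cfg, load, seed = 5)
  cm <- power_contrast(epoch_psd(wp$encoding), epoch_psd(wp$pvt))
  topo <- collapse_topography(cm, 6:20)
  expect_identical(unname(which.min(topo$values)), 4L)
})
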