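test_that("Spearman correlation matches the d^2 oracle and handles edge cases", {
  expect_equal(as.numeric(spearman_rho(1:8, 1:8)), 1)
  expect_equal(as.numeric(spearman_rho(1:8, 8:1)), -1)
  expect_equal(as.numeric(spearman_rho(1:5, c(2, 1, 4, 3, 5))), 0.8)
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(as.numeric(spearman_rho(x, y)), spearman_d2(x, y),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(as.numeric(spearman_rho(exp(x), y)),
                 as.numeric(spearman_rho(x, y)))
  }
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  # pairwise deletion
  r <- spearman_rho(c(1, 2, NA, 4, 5), c(5, 4, 3, 2, 1))
  expect_identical(attr(r, "n_used"), 4L)
  expect_error(spearman_rho(c(1, NA, NA, NA), c(1, 2, 3, 4)), "3 complete")
})

test_that("Fisher z is odd and clipped", {
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), -fisher_z(-1))
})

test_that("topographic overlap is signed as documented", {
  set.seed(10)
  mon <- builtin_montage(20)
  v <- exp(rnorm(20) * 0.4)
  names(v) <- mon$channel_labels
  enc <- mk_enc_topo(-v)          # encoding is the negated sleep pattern
  expect_equal(topo_overlap(enc, mk_evt_topo(v), "amplitude")$rho, -1)
  # independent topographies: near-zero mean over replicates
  rhos <- replicate(200, {
    a <- stats::setNames(rnorm(20), mon$channel_labels)
    b <- stats::setNames(exp(rnorm(20)), mon$channel_labels)
    topo_overlap(mk_enc_topo(a), mk_evt_topo(b), "amplitude")$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
  expect_error(topo_overlap(mk_enc_topo(stats::setNames(1:5, letters[1:5])),
                            mk_evt_topo(v)), "10 common")
})

test_that("partial rank correlation matches an lm-on-ranks oracle", {
  set.seed(11)
  n <- 40
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)
  got <- partial_spearman(x, y, z)
  # oracle: correlate residuals of rank regressions
  rx <- resid(lm(rank(x) ~ rank(z)))
  ry <- resid(lm(rank(y) ~ rank(z)))
  expect_equal(got, cor(rx, ry), tolerance = 1e-10)
  # x,y related only through the control: partial near zero at large n
  big <- rnorm(2000)
  expect_lt(abs(partial_spearman(big + rnorm(2000), big + rnorm(2000), big)),
            0.1)
  # independent control: partial approximately the plain rho
  c2 <- rnorm(2000); x2 <- rnorm(2000); y2 <- x2 + rnorm(2000)
  expect_equal(partial_spearman(x2, y2, c2),
               as.numeric(spearman_rho(x2, y2)), tolerance = 0.05)
  expect_true(is.na(partial_spearman(1:10, 1:10, 1:10)))
})

test_that("repeated-measures ANOVA matches aov error strata exactly", {
  set.seed(12)
  for (n in c(3, 5)) {
    z <- matrix(rnorm(n * 6), n, 6)
    got <- rm_anova_2x3(z)
    d <- data.frame(
      y = as.vector(z),
      subj = factor(rep(seq_len(n), 6)),
      A = factor(rep(rep(1:2, each = 3), each = n)),
      B = factor(rep(rep(1:3, 2), each = n)))
    fit <- summary(aov(y ~ A * B + Error(subj / (A * B)), data = d))
    f_a <- fit[["Error: subj:A"]][[1]]["A", "F value"]
    f_b <- fit[["Error: subj:B"]][[1]]["B", "F value"]
    f_ab <- fit[["Error: subj:A:B"]][[1]]["A:B", "F value"]
    expect_equal(got$F, c(f_a, f_b, f_ab), tolerance = 1e-8)
    expect_equal(got$df_error, c(n - 1, 2 * (n - 1), 2 * (n - 1)))
    # total SS decomposition closes to within 1e-8 relative
    ss_subj <- 6 * sum((rowMeans(z) - mean(z))^2)
    expect_equal(sum(got$SS) + sum(got$SS_error) + ss_subj,
                 sum((z - mean(z))^2), tolerance = 1e-8)
  }
})

test_that("degenerate and shifted ANOVA tables behave as expected", {
  z <- matrix(2.5, 4, 6)
  got <- rm_anova_2x3(z)
  expect_equal(got$F, c(0, 0, 0))
  expect_equal(got$eta_p_sq, c(0, 0, 0))

  set.seed(13)
  z2 <- matrix(rnorm(24), 4, 6)
  base <- rm_anova_2x3(z2)
  shifted <- z2
  shifted[, 1:3] <- shifted[, 1:3] + 5   # constant offset on spindle cells
  got2 <- rm_anova_2x3(shifted)
  expect_gt(got2$F[1], base$F[1])
  expect_equal(got2$F[3], base$F[3], tolerance = 1e-8)  # interaction unmoved
  expect_equal(got2$F[2], base$F[2], tolerance = 1e-8)

  expect_error(rm_anova_2x3(matrix(c(1, NA), 3, 6)), "missing")
})

test_that("post-hoc t tests match hand computations and Holm order", {
  z <- cbind(c(-1, -2, -3), 0, 0, 0, 0, 0)
  got <- posthoc_tests(z)
  one <- got[got$test == "spindle_vs_zero" &
               got$characteristic == "amplitude", ]
  expect_equal(one$t, -2 * sqrt(3), tolerance = 1e-9)
  expect_equal(one$cohens_d, -2)

  # Holm step-down oracle on (0.01, 0.03, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  expect_true(all(got$p_holm >= got$p - 1e-12))

  # identical paired columns: t = 0, p = 1
  z2 <- matrix(rnorm(18), 3, 6)
  z2[, 4:6] <- z2[, 1:3]
  got2 <- posthoc_tests(z2)
  paired <- got2[got2$test == "paired_spindle_vs_so", ]
  expect_true(all(is.na(paired$t) | abs(paired$t) < 1e-9 |
                    paired$p > 0.999))
})

test_that("behaviour correlation handles direction, p-values and guards", {
  z <- seq(-1, -0.1, length.out = 10)
  ret <- 150 - 50 * z + 0   # strictly decreasing in overlap z
  out <- behavior_correlation(z, ret)
  expect_equal(out$r, -1)
  expect_lt(out$p, 0.01)
  expect_error(behavior_correlation(z[1:4], ret[1:4]), "5 participants")
  expect_true(is.na(behavior_correlation(rep(-0.5, 6), ret[1:6])$r))
  # t-approximation branch at n >= 12
  set.seed(14)
  z2 <- rnorm(20); r2 <- rnorm(20)
  out2 <- behavior_correlation(z2, r2)
  tstat <- out2$r * sqrt(18 / (1 - out2$r^2))
  expect_equal(out2$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
})

test_that("permutation null is reproducible, bounded and directional", {
  set.seed(15)
  mon <- builtin_montage(20)
  n <- 12
  encs <- lapply(1:n, function(i)
    mk_enc_topo(stats::setNames(rnorm(20), mon$channel_labels), i))
  evts <- lapply(1:n, function(i)
    mk_evt_topo(stats::setNames(exp(rnorm(20)), mon$channel_labels)))
  ret <- runif(n, 40, 120)
  a <- permutation_null(encs, evts, ret, "encoding", n_perm = 99, seed = 3)
  b <- permutation_null(encs, evts, ret, "encoding", n_perm = 99, seed = 3)
  expect_identical(a$null, b$null)
  expect_gte(a$p, 1 / 100)
  expect_lte(a$p, 1)
  expect_length(a$null, 99)
  expect_error(permutation_null(encs, evts, rep(100, n), "encoding"),
               "constant")
  expect_error(
    permutation_null(encs, evts, ret, "density"), "arg")
})

test_that("coupling contrast flags constructed differences only", {
  z <- rnorm(10, -0.4, 0.1)
  same <- coupling_contrast(z, z)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  stronger <- coupling_contrast(z - 0.3, z)
  expect_lt(stronger$t, 0)
  expect_lt(stronger$p, 0.01)
  expect_error(coupling_contrast(1, 1), "2 participants")
})
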