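# Encoding-sleep topographic overlap and the group statistics: Spearman
# overlap per participant, 2x3 repeated-measures ANOVA, Holm-corrected
# post-hoc t tests, partial rank correlations, behaviour correlation, the
# two topography-shuffling permutation nulls, and the coupling contrast.

#' Spearman rank correlation (mid-ranks for ties)
#'
#' Pearson correlation of mid-ranks. Pairs with a missing value in either
#' vector are dropped (pairwise deletion; the count is attached as attribute
#' `n_used`). Returns `NA` when either rank vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The correlation, with attribute `n_used`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    out <- NA_real_
  } else {
    out <- stats::cor(rx, ry)
  }
  attr(out, "n_used") <- length(x)
  out
}

#' Encoding-sleep topographic overlap for one participant
#'
#' Spearman correlation, across channels, between the encoding topography
#' and one sleep-event characteristic topography, plus its Fisher z.
#' Because encoding values are negative at engaged sites and all sleep
#' measures are positively scaled, overlap is signified by a negative
#' correlation.
#'
#' @param enc An `encoding_topography`.
#' @param topo An `event_topography` (from [characterize_events()]).
#' @param characteristic One of `"amplitude"`, `"duration"`, `"density"`.
#' @return Object of class `overlap_result`: participant, kind,
#'   characteristic, rho, z, n_channels.
#' @export
topo_overlap <- function(enc, topo,
                         characteristic = c("amplitude", "duration",
                                            "density")) {
  characteristic <- match.arg(characteristic)
  stopifnot(inherits(enc, "encoding_topography"),
            inherits(topo, "event_topography"))
  col <- switch(characteristic, amplitude = "amplitude_uV",
                duration = "duration_s", density = "density_per_min")
  common <- intersect(names(enc$values), topo$channel)
  if (length(common) < 10) {
    stop("fewer than 10 common channels between the topographies")
  }
  x <- enc$values[common]
  y <- topo[[col]][match(common, topo$channel)]
  rho <- spearman_rho(x, y)
  structure(list(participant = enc$participant,
                 kind = topo$kind[1], characteristic = characteristic,
                 rho = as.numeric(rho), z = fisher_z(as.numeric(rho)),
                 n_channels = attr(rho, "n_used")),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result>%s %s %s: rho = %.3f (z = %.3f, %d channels)\n",
              if (is.null(x$participant)) "" else paste0(" [", x$participant, "]"),
              x$kind, x$characteristic, x$rho, x$z, x$n_channels))
  invisible(x)
}

#' First-order partial Spearman correlation
#'
#' All three vectors are rank transformed (mid-ranks); the partial
#' product-moment correlation
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` is computed on the
#' ranks. Undefined (returns `NA`) when the control is collinear with
#' either variable.
#'
#' @param x,y Vectors to correlate.
#' @param control Vector to partial out.
#' @return The partial correlation, or `NA` if degenerate.
#' @export
partial_spearman <- function(x, y, control) {
  stopifnot(length(x) == length(y), length(x) == length(control))
  ok <- stats::complete.cases(x, y, control)
  rx <- rank(x[ok]); ry <- rank(y[ok]); rz <- rank(control[ok])
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (!is.finite(den) || den <= .Machine$double.eps) return(NA_real_)
  (rxy - rxz * ryz) / sqrt(den)
}

#' Two-by-three fully repeated-measures ANOVA
#'
#' Within-subject factors: event type (2 levels) and event characteristic
#' (3 levels). Direct sums-of-squares decomposition; each effect is tested
#' against its own effect-by-subject interaction (uncorrected degrees of
#' freedom, no sphericity correction). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param z_table Numeric matrix, participants x 6 cells, columns ordered as
#'   (type1.char1, type1.char2, type1.char3, type2.char1, type2.char2,
#'   type2.char3) — e.g. spindle amplitude/duration/density then SO
#'   amplitude/duration/density.
#' @return Data frame with one row per effect (`type`, `characteristic`,
#'   `interaction`): SS, df, SS_error, df_error, F, p, eta_p_sq.
#' @export
rm_anova_2x3 <- function(z_table) {
  z_table <- as.matrix(z_table)
  if (any(!is.finite(z_table))) stop("z_table contains missing cells")
  n <- nrow(z_table)
  if (n < 3 || ncol(z_table) != 6) {
    stop("z_table must be participants x 6 with at least 3 participants")
  }
  A <- rep(1:2, each = 3)   # event type per column
  B <- rep(1:3, times = 2)  # characteristic per column
  G <- mean(z_table)
  subj <- rowMeans(z_table)
  mA <- vapply(1:2, function(a) mean(z_table[, A == a]), 0)
  mB <- vapply(1:3, function(b) mean(z_table[, B == b]), 0)
  mAB <- matrix(0, 2, 3)
  for (a in 1:2) for (b in 1:3) mAB[a, b] <- mean(z_table[, A == a & B == b])
  mAS <- vapply(1:2, function(a) rowMeans(z_table[, A == a, drop = FALSE]),
                numeric(n))                     # n x 2
  mBS <- vapply(1:3, function(b) rowMeans(z_table[, B == b, drop = FALSE]),
                numeric(n))                     # n x 3
  ss_A <- 3 * n * sum((mA - G)^2)
  ss_B <- 2 * n * sum((mB - G)^2)
  ss_AB <- n * sum((mAB - outer(mA - G, mB - G, "+") - G)^2)
  # effect-by-subject error terms
  dev_AS <- mAS - matrix(subj, n, 2) - matrix(mA, n, 2, byrow = TRUE) + G
  ss_AS <- 3 * sum(dev_AS^2)
  dev_BS <- mBS - matrix(subj, n, 3) - matrix(mB, n, 3, byrow = TRUE) + G
  ss_BS <- 2 * sum(dev_BS^2)
  ss_total <- sum((z_table - G)^2)
  ss_subj <- 6 * sum((subj - G)^2)
  ss_ABS <- ss_total - ss_subj - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  eff <- data.frame(
    effect = c("type", "characteristic", "interaction"),
    SS = c(ss_A, ss_B, ss_AB),
    df = c(1, 2, 2),
    SS_error = c(ss_AS, ss_BS, ss_ABS),
    df_error = c(n - 1, 2 * (n - 1), 2 * (n - 1)))
  eff$F <- (eff$SS / eff$df) / (eff$SS_error / eff$df_error)
  eff$F[eff$SS_error <= .Machine$double.eps & eff$SS <= .Machine$double.eps] <- 0
  eff$p <- stats::pf(eff$F, eff$df, eff$df_error, lower.tail = FALSE)
  eff$eta_p_sq <- ifelse(eff$SS + eff$SS_error > 0,
                         eff$SS / (eff$SS + eff$SS_error), 0)
  eff
}

#' Post-hoc t tests on the overlap z table
#'
#' Two Holm-corrected families of three tests each: paired t tests (event
#' type 1 vs type 2, per characteristic) and one-sample t tests of the
#' type-1 (spindle) characteristics against zero. Cohen's d is the mean of
#' the tested difference divided by its SD (one-sample: mean / SD of the
#' values).
#'
#' @param z_table As in [rm_anova_2x3()] (columns: spindle amp/dur/dens,
#'   SO amp/dur/dens).
#' @param characteristics Labels for the three characteristics.
#' @return Data frame: test, characteristic, t, df, p, p_holm, cohens_d.
#' @export
posthoc_tests <- function(z_table,
                          characteristics = c("amplitude", "duration",
                                              "density")) {
  z_table <- as.matrix(z_table)
  n <- nrow(z_table)
  if (n < 2) stop("need at least 2 participants")
  row_for <- function(test, b, v) {
    if (stats::sd(v) == 0) {
      # degenerate zero-variance case: no evidence against the null
      data.frame(test = test, characteristic = characteristics[b],
                 t = 0, df = length(v) - 1, p = 1, cohens_d = 0)
    } else {
      tt <- stats::t.test(v)
      data.frame(test = test, characteristic = characteristics[b],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = mean(v) / stats::sd(v))
    }
  }
  paired <- lapply(1:3, function(b)
    row_for("paired_spindle_vs_so", b, z_table[, b] - z_table[, b + 3]))
  onesample <- lapply(1:3, function(b)
    row_for("spindle_vs_zero", b, z_table[, b]))
  out <- rbind(do.call(rbind, paired), do.call(rbind, onesample))
  out$p_holm <- NA_real_
  for (fam in unique(out$test)) {
    i <- out$test == fam
    out$p_holm[i] <- stats::p.adjust(out$p[i], method = "holm")
  }
  rownames(out) <- NULL
  out
}

#' Correlation between overlap and behaviour across participants
#'
#' Spearman correlation between the per-participant overlap Fisher z and the
#' retention score, with an exact permutation p-value for small samples
#' (`n < 12`) and the t approximation otherwise.
#'
#' @param z Per-participant overlap Fisher-z values.
#' @param retention_pct Per-participant retention scores.
#' @return List with `r`, `p`, `n`.
#' @export
behavior_correlation <- function(z, retention_pct) {
  ok <- stats::complete.cases(z, retention_pct)
  z <- z[ok]; retention_pct <- retention_pct[ok]
  n <- length(z)
  if (n < 5) stop("need at least 5 participants")
  if (stats::sd(rank(z)) == 0 || stats::sd(rank(retention_pct)) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- as.numeric(spearman_rho(z, retention_pct))
  if (n < 12 && !anyDuplicated(z) && !anyDuplicated(retention_pct)) {
    p <- stats::cor.test(z, retention_pct, method = "spearman",
                         exact = TRUE)$p.value
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Topography-shuffling permutation null for the behaviour correlation
#'
#' The observed statistic is the Spearman correlation, across participants,
#' between the encoding-spindle overlap Fisher z and retention. Each
#' permutation applies one uniform random permutation to the chosen
#' topography set (encoding or spindle) across participants — retaining the
#' other topography and the behaviour pairing — recomputes every
#' participant's overlap rho and z, and records the correlation with
#' retention. The p value is one-sided with the add-one correction, in the
#' fixed a-priori direction (`"less"`: stronger overlap, i.e. more negative
#' z, goes with better retention, so the observed correlation is expected in
#' the lower tail); a two-sided version is also returned. A fixed direction
#' keeps the p value uniform under the null, which a data-driven
#' (observed-direction) tail would not be.
#'
#' @param enc_topos List of `encoding_topography`s, one per participant.
#' @param event_topos List of `event_topography`s (same participants, same
#'   order).
#' @param retention_pct Per-participant retention scores.
#' @param shuffle_which `"encoding"` or `"spindle"`: which topography set is
#'   shuffled between participants.
#' @param characteristic Sleep characteristic used for the overlap.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the shuffles.
#' @param alternative Direction of the one-sided test: `"less"` (default,
#'   the hypothesized negative correlation) or `"greater"`.
#' @return Object of class `permutation_null`: `shuffled`, `observed_r`,
#'   `null` (length `n_perm`), `p` (one-sided, fixed direction),
#'   `p_two_sided`, `n_perm`.
#' @export
permutation_null <- function(enc_topos, event_topos, retention_pct,
                             shuffle_which = c("encoding", "spindle"),
                             characteristic = "amplitude",
                             n_perm = 1000, seed = NULL,
                             alternative = c("less", "greater")) {
  shuffle_which <- match.arg(shuffle_which)
  alternative <- match.arg(alternative)
  n <- length(enc_topos)
  stopifnot(length(event_topos) == n, length(retention_pct) == n)
  if (stats::sd(retention_pct) == 0) {
    stop("retention is constant; the behaviour correlation is undefined")
  }
  # cross-participant overlap z matrix: z[i, j] pairs encoding i with sleep j
  zmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      enc_i <- enc_topos[[i]]
      zmat[i, j] <- suppressWarnings(
        topo_overlap(enc_i, event_topos[[j]], characteristic)$z)
    }
  }
  if (anyNA(zmat)) {
    stop("undefined overlap for some participant pairing ",
         "(constant topography?)")
  }
  rank_ret <- rank(retention_pct)
  corr_for <- function(zvec) {
    if (stats::sd(rank(zvec)) == 0) return(NA_real_)
    stats::cor(rank(zvec), rank_ret)
  }
  observed <- corr_for(diag(zmat))
  if (is.na(observed)) stop("observed overlap values are constant")
  if (!is.null(seed)) set.seed(seed)
  null <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    zvec <- if (shuffle_which == "encoding") zmat[cbind(perm, seq_len(n))]
            else zmat[cbind(seq_len(n), perm)]
    null[k] <- corr_for(zvec)
  }
  null[is.na(null)] <- 0
  p_one <- if (alternative == "less") (1 + sum(null <= observed)) / (1 + n_perm)
           else (1 + sum(null >= observed)) / (1 + n_perm)
  p_two <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  structure(list(shuffled = shuffle_which, observed_r = observed,
                 null = null, p = p_one, p_two_sided = p_two,
                 n_perm = n_perm),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> shuffled %s: observed r = %.3f, p = %.4f (%d perms)\n",
    x$shuffled, x$observed_r, x$p, x$n_perm))
  invisible(x)
}

#' Paired contrast of overlap for higher- vs lower-coupling spindles
#'
#' @param z_higher,z_lower Per-participant overlap Fisher-z values computed
#'   from the amplitude topographies of the higher- and lower-coupling
#'   spindle subsets.
#' @return List with `t`, `df`, `p`, `mean_diff`, `cohens_d`.
#' @export
coupling_contrast <- function(z_higher, z_lower) {
  stopifnot(length(z_higher) == length(z_lower))
  if (length(z_higher) < 2) stop("need at least 2 participants")
  d <- z_higher - z_lower
  # mirror t.test's own degeneracy threshold so a numerically constant
  # difference is handled before it can error
  if (stats::sd(d) / sqrt(length(d)) <=
        10 * .Machine$double.eps * max(abs(mean(d)), 1e-300)) {
    # zero-variance difference: no evidence (all zero) or a deterministic
    # shift (infinitely precise)
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                  cohens_d = 0))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), cohens_d = sign(mean(d)) * Inf))
  }
  tt <- stats::t.test(z_higher, z_lower, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), cohens_d = mean(d) / stats::sd(d))
}
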