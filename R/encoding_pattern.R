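# Wake encoding-pattern extraction: epoch spectra, percentile artifact
# rejection, encoding - control contrast, group cluster-based permutation
# test over channel x frequency maps, and collapse to per-channel
# topographies.

#' Epoch power spectra (1-s Hanning epochs, 50% overlap, 1-20 Hz)
#'
#' Segments the recording into 1-second epochs with 0.5-second step, tapers
#' each with a Hanning window, and takes the squared-magnitude FFT. Bins are
#' restricted to 1-20 Hz inclusive (1 Hz resolution at 200 Hz / 1 s). Power
#' is scaled so a pure sinusoid of amplitude A at a bin centre yields
#' `A^2 / 2` (its mean-square power) in that bin.
#'
#' @param rec A [recording()] (duration at least 2 s, fs = 200).
#' @param condition Optional condition label stored with the result.
#' @return Object of class `spectra_set`: `power` (array epochs x channels x
#'   20), `freqs` (1:20 Hz), `channel_labels`, `condition`.
#' @export
epoch_psd <- function(rec, condition = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != PIPELINE_FS) stop("epoch_psd requires fs = ", PIPELINE_FS)
  nlen <- ncol(rec$signal)
  nwin <- as.integer(fs)                 # 1 s
  step <- nwin %/% 2L                    # 50% overlap
  if (nlen < 2 * nwin) stop("recording shorter than 2 s")
  starts <- seq(1L, nlen - nwin + 1L, by = step)
  nch <- nrow(rec$signal)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  freqs <- 1:20
  bins <- freqs + 1L                     # FFT bin k holds (k-1) Hz
  pw <- array(0, dim = c(length(starts), nch, length(freqs)))
  scale <- 2 / sum(w)^2                  # |X| = A sum(w) / 2 -> A^2 / 2
  for (e in seq_along(starts)) {
    seg <- rec$signal[, starts[e]:(starts[e] + nwin - 1L), drop = FALSE]
    seg <- seg * rep(w, each = nch)
    ft <- stats::mvfft(t(seg))
    pw[e, , ] <- t(Mod(ft[bins, , drop = FALSE])^2 * scale)
  }
  structure(list(power = pw, freqs = freqs,
                 channel_labels = rec$channel_labels,
                 condition = condition),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set>%s %d epochs x %d channels x %d bins (%g-%g Hz)\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Percentile-based epoch rejection per channel x frequency cell
#'
#' For each (channel, frequency) cell independently, epochs whose power lies
#' strictly above that cell's `pct`-th percentile (linear-interpolation,
#' type 7) are marked excluded. Condition means are later taken over the
#' retained epochs of each cell.
#'
#' @param spectra A `spectra_set` with at least 20 epochs.
#' @param pct Percentile threshold; must lie in (50, 100]. `pct = 100`
#'   excludes nothing.
#' @return Logical array epochs x channels x bins, `TRUE` where the epoch is
#'   retained for that cell.
#' @export
percentile_reject <- function(spectra, pct = 95) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (pct <= 50 || pct > 100) stop("pct must lie in (50, 100]")
  d <- dim(spectra$power)
  if (d[1] < 20) stop("percentile rejection needs at least 20 epochs")
  keep <- array(TRUE, dim = d)
  for (ch in seq_len(d[2])) {
    v <- spectra$power[, ch, , drop = TRUE]         # epochs x bins
    thr <- apply(v, 2, stats::quantile, probs = pct / 100, type = 7,
                 names = FALSE)
    keep[, ch, ] <- v <= rep(thr, each = d[1])
  }
  keep
}

#' Encoding - control power contrast
#'
#' Per (channel, frequency) cell: mean power over retained encoding epochs
#' minus mean power over retained control epochs (absolute power change in
#' microvolts squared).
#'
#' @param enc,pvt `spectra_set`s with identical channels and bins.
#' @param enc_keep,pvt_keep Optional retention masks from
#'   [percentile_reject()]; default keeps everything.
#' @return Object of class `contrast_map`: `delta_power` (channels x bins),
#'   `freqs`, `channel_labels`.
#' @export
power_contrast <- function(enc, pvt, enc_keep = NULL, pvt_keep = NULL) {
  stopifnot(inherits(enc, "spectra_set"), inherits(pvt, "spectra_set"))
  if (!identical(enc$freqs, pvt$freqs)) stop("frequency bins differ")
  if (!identical(enc$channel_labels, pvt$channel_labels)) {
    stop("channel sets differ")
  }
  m_enc <- masked_cell_means(enc$power, enc_keep)
  m_pvt <- masked_cell_means(pvt$power, pvt_keep)
  structure(list(delta_power = m_enc - m_pvt, freqs = enc$freqs,
                 channel_labels = enc$channel_labels),
            class = "contrast_map")
}

masked_cell_means <- function(pw, keep) {
  if (is.null(keep)) return(apply(pw, c(2, 3), mean))
  stopifnot(identical(dim(keep), dim(pw)))
  num <- apply(pw * keep, c(2, 3), sum)
  den <- apply(keep, c(2, 3), sum)
  num / den
}

#' Channel adjacency from montage layout
#'
#' Two channels are neighbours when their layout distance is below
#' `factor` times the median nearest-neighbour distance — a standard
#' neighbourhood construction for regular scalp layouts.
#'
#' @param mon A [montage()].
#' @param factor Distance threshold multiplier (default 1.5).
#' @return List of integer vectors, per-channel neighbour indices.
#' @export
montage_adjacency <- function(mon, factor = 1.5) {
  d <- as.matrix(stats::dist(mon$xy))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- factor * stats::median(nn)
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= thr))
}

#' Group cluster-based permutation test on contrast maps
#'
#' Paired test of the per-cell contrast against zero across participants:
#' one-sample t per (channel, frequency) cell; cells with `|t|` above the
#' two-sided critical value at `cell_alpha` (df = n - 1) are clustered by
#' adjacency (neighbouring channels at the same frequency; +-1 frequency bin
#' on the same channel), separately for positive and negative cells. The
#' cluster statistic is the sum of member t values. The null distribution is
#' the maximum absolute cluster statistic under random participant-wise sign
#' flips; cluster `p = (1 + #{null >= |observed|}) / (1 + n_perm)`. The
#' significant frequency-bin set is the union of bins in clusters with
#' `p < cluster_alpha`.
#'
#' @param contrasts List of `contrast_map`s, one per participant (>= 2).
#' @param mon The [montage()] shared by all maps.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param cell_alpha Cell-level threshold alpha (two-sided, default 0.05).
#' @param cluster_alpha Cluster-level alpha (default 0.05).
#' @param seed Optional integer seed for the sign flips.
#' @return Object of class `cluster_test`: `clusters` (list: `cells` matrix
#'   of (channel, bin) indices, `mass`, `p`), `sig_bins` (significant
#'   frequencies in Hz), `mask` (channels x bins), `tmap`, `freqs`,
#'   `n_perm`.
#' @export
cluster_permutation <- function(contrasts, mon, n_perm = 1000,
                                cell_alpha = 0.05, cluster_alpha = 0.05,
                                seed = NULL) {
  np <- length(contrasts)
  if (np < 2) stop("cluster test needs at least 2 participants (df = n - 1)")
  nch <- length(mon$channel_labels)
  freqs <- contrasts[[1]]$freqs
  nf <- length(freqs)
  for (cm in contrasts) {
    stopifnot(inherits(cm, "contrast_map"),
              identical(cm$channel_labels, mon$channel_labels),
              identical(cm$freqs, freqs))
  }
  X <- t(vapply(contrasts, function(cm) as.numeric(cm$delta_power),
                numeric(nch * nf)))           # participants x cells
  ncell <- ncol(X)
  tcrit <- stats::qt(1 - cell_alpha / 2, df = np - 1)
  adj <- cell_adjacency(montage_adjacency(mon), nch, nf)
  ss2 <- colSums(X^2)
  tmap_of <- function(signs) {
    m <- as.numeric(signs %*% X) / np
    v <- (ss2 - np * m^2) / (np - 1)
    m / sqrt(v / np)
  }
  tobs <- tmap_of(rep(1, np))
  clusters <- find_clusters(tobs, tcrit, adj)
  if (!is.null(seed)) set.seed(seed)
  null_max <- numeric(n_perm)
  if (length(clusters)) {
    S <- matrix(sample(c(-1, 1), n_perm * np, replace = TRUE), n_perm, np)
    M <- S %*% X / np
    for (p_i in seq_len(n_perm)) {
      m <- M[p_i, ]
      v <- (ss2 - np * m^2) / (np - 1)
      tp <- m / sqrt(v / np)
      cl <- find_clusters(tp, tcrit, adj)
      null_max[p_i] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass")))
                       else 0
    }
  }
  out_clusters <- lapply(clusters, function(cl) {
    cells <- cbind(channel = (cl$cells - 1L) %% nch + 1L,
                   bin = (cl$cells - 1L) %/% nch + 1L)
    p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    list(cells = cells, mass = cl$mass, p = p)
  })
  mask <- matrix(FALSE, nch, nf)
  sig_bins <- integer(0)
  for (cl in out_clusters) {
    if (cl$p < cluster_alpha) {
      mask[cl$cells] <- TRUE
      sig_bins <- union(sig_bins, cl$cells[, "bin"])
    }
  }
  structure(list(clusters = out_clusters,
                 sig_bins = sort(freqs[sig_bins]),
                 mask = mask,
                 tmap = matrix(tobs, nch, nf),
                 freqs = freqs, n_perm = n_perm,
                 cell_alpha = cell_alpha, cluster_alpha = cluster_alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  mass %8.1f  cells %4d  p = %.4f\n",
                cl$mass, nrow(cl$cells), cl$p))
  }
  if (length(x$sig_bins)) {
    cat("  significant bins (Hz):", paste(x$sig_bins, collapse = " "), "\n")
  } else cat("  no significant clusters\n")
  invisible(x)
}

# adjacency over flattened (channel, bin) cells: channel neighbours at the
# same bin, +-1 bin on the same channel
cell_adjacency <- function(ch_adj, nch, nf) {
  adj <- vector("list", nch * nf)
  for (b in seq_len(nf)) {
    off <- (b - 1L) * nch
    for (c in seq_len(nch)) {
      nb <- ch_adj[[c]] + off
      if (b > 1) nb <- c(nb, c + off - nch)
      if (b < nf) nb <- c(nb, c + off + nch)
      adj[[c + off]] <- nb
    }
  }
  adj
}

# connected components of supra-threshold cells, split by sign of t
find_clusters <- function(tvec, tcrit, adj) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvec > tcrit)
    if (!length(supra)) next
    in_supra <- logical(length(tvec))
    in_supra[supra] <- TRUE
    visited <- logical(length(tvec))
    for (s in supra) {
      if (visited[s]) next
      comp <- integer(0)
      stack <- s
      visited[s] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, v)
        for (w in adj[[v]]) {
          if (in_supra[w] && !visited[w]) {
            visited[w] <- TRUE
            stack <- c(stack, w)
          }
        }
      }
      out[[length(out) + 1]] <- list(cells = sort(comp),
                                     mass = sum(tvec[comp]))
    }
  }
  out
}

#' Collapse a contrast map to a per-channel encoding topography
#'
#' Per channel, the mean of the power change over the given frequency bins
#' (mean rather than sum, so the scale does not depend on how many bins were
#' significant).
#'
#' @param contrast A `contrast_map`.
#' @param bins Frequencies in Hz to collapse over (typically the significant
#'   bins of the cluster test). Must be nonempty.
#' @param participant Optional participant id stored with the result.
#' @return Object of class `encoding_topography`: `values` (named
#'   per-channel power change, microvolts squared), `bins`, `participant`.
#' @export
collapse_topography <- function(contrast, bins, participant = NULL) {
  stopifnot(inherits(contrast, "contrast_map"))
  if (length(bins) == 0) {
    stop("empty significant-bin set; fall back to the full 6-20 Hz band ",
         "(e.g. bins = 6:20) if the cluster test found nothing")
  }
  idx <- match(bins, contrast$freqs)
  if (anyNA(idx)) stop("bins not present in the contrast map: ",
                       paste(bins[is.na(idx)], collapse = ", "))
  vals <- rowMeans(contrast$delta_power[, idx, drop = FALSE])
  structure(list(values = stats::setNames(vals, contrast$channel_labels),
                 bins = bins, participant = participant),
            class = "encoding_topography")
}

#' @export
print.encoding_topography <- function(x, ...) {
  cat(sprintf("<encoding_topography>%s %d channels, bins %s Hz, mean %.3f uV^2\n",
              if (is.null(x$participant)) "" else paste0(" [", x$participant, "]"),
              length(x$values), paste(range(x$bins), collapse = "-"),
              mean(x$values)))
  invisible(x)
}
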