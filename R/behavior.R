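# Sequence-memory performance and the sleep retention score.

#' Fisher-z sequence-memory score from a retrieved object order
#'
#' The order in which the participant placed the `n` objects is correlated
#' with the true ascending order `1..n`. Because both vectors are
#' permutations (rank vectors), Pearson and Spearman correlation coincide.
#' The correlation is clipped to `+-(1 - 1e-6)` before the Fisher z
#' transform so perfect performance stays finite.
#'
#' @param selected_order Integer vector, a permutation of `1..n` (`n >= 3`):
#'   position `i` holds the true sequence index of the object placed `i`-th.
#' @return List with `r` (the clipped correlation) and `z` (`atanh(r)`).
#' @export
sequence_score <- function(selected_order) {
  n <- length(selected_order)
  if (n < 3 || !setequal(selected_order, seq_len(n))) {
    stop("selected_order must be a permutation of 1..n with n >= 3")
  }
  r <- stats::cor(as.numeric(selected_order), seq_len(n))
  r <- clip_r(r)
  list(r = r, z = atanh(r))
}

clip_r <- function(r, eps = 1e-6) pmin(1 - eps, pmax(-(1 - eps), r))

#' Fisher z transform with clipping
#' @param r Correlation value(s).
#' @return `atanh` of `r` clipped to `+-(1 - 1e-6)`.
#' @export
fisher_z <- function(r) atanh(clip_r(r))

#' Sleep retention score in percent
#'
#' `100 * post / pre` on the Fisher-z sequence scores. Participants with
#' non-positive pre-sleep performance have no meaningful relative change;
#' their retention is `NA` (with a warning).
#'
#' @param pre_z,post_z Pre- and post-sleep Fisher-z sequence scores.
#' @return Retention in percent (possibly `NA`).
#' @export
retention <- function(pre_z, post_z) {
  out <- ifelse(pre_z > 0, 100 * post_z / pre_z, NA_real_)
  if (anyNA(out)) {
    warning("retention undefined for ", sum(is.na(out)),
            " participant(s) with non-positive pre-sleep score")
  }
  out
}
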