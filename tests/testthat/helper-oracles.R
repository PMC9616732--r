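# Shared fixtures and independent oracles used across the suite.

# Spearman via the rank-difference formula (no ties): 1 - 6 sum d^2 / (n(n^2-1))
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# event-matching rates against a ground-truth log
match_recall <- function(det, tru, col = "onset_s", tol = 0.25) {
  mean(vapply(seq_len(nrow(tru)), function(i) {
    d <- det[det$channel == tru$channel[i], ]
    any(abs(d[[col]] - tru[[col]][i]) <= tol)
  }, logical(1)))
}

match_precision <- function(det, tru, col = "onset_s", tol = 0.25) {
  mean(vapply(seq_len(nrow(det)), function(j) {
    d <- tru[tru$channel == det$channel[j], ]
    any(abs(d[[col]] - det[[col]][j]) <= tol)
  }, logical(1)))
}

# wrap planted topography vectors in the classes the overlap layer expects
mk_enc_topo <- function(values, id = NULL) {
  structure(list(values = values, bins = 6:20, participant = id),
            class = "encoding_topography")
}

mk_evt_topo <- function(values, kind = "spindle") {
  structure(data.frame(channel = names(values), kind = kind, n_events = 50L,
                       amplitude_uV = unname(values), duration_s = 1,
                       density_per_min = 2),
            class = c("event_topography", "data.frame"))
}

# background-spectrum noise for property tests (internal generator)
shaped_noise_for_tests <- function(n, cfg) spindletopo:::shaped_noise(n, cfg)

# small all-NREM nap config used by several detector tests
small_nap_config <- function(nch = 2, minutes = 10, ...) {
  synth_config(montage = builtin_montage(nch),
               sleep_duration_s = minutes * 60,
               stages = rep("N2", minutes * 2),
               artifact_rate_per_min = 0, ...)
}
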