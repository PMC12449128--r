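# Shared fixtures: all test data are generated in code, at small scale.

# A compact session: 6 jars x 2 blocks = 12 trials.
small_session <- function(seed = 42) {
  build_session(make_jars(6, 0.2, 0.8), n_blocks = 2, seed = seed)
}

# Full-size session matching the scanner task (18 jars x 3 blocks).
study_session <- function(seed = 42) {
  build_session(seed = seed)
}

# A tiny voxel layout for neural tests (~33 voxels).
tiny_layout <- function(...) {
  voxel_layout(dim = c(8, 8, 8), mask_radius = 2, effect_radius = 1.4, ...)
}

# One row per (trial, sample) behavior table with an exactly known response.
exact_behavior <- function(session, spec) {
  pred <- beliefvar:::final_predictions(spec, session)
  m <- if (!is.null(pred$alpha)) pred$alpha / (pred$alpha + pred$beta) else pred$point
  dplyr::left_join(
    session,
    tibble::tibble(trial_id = pred$trial_id, reported_estimate = m),
    by = "trial_id"
  )
}

# Widely spaced single-condition events whose convolved responses do not
# overlap (for LS-S oracle checks).
sparse_events <- function(n_events = 8, spacing_s = 40, duration = 1,
                          trial_type = "sample_1") {
  tibble::tibble(
    block_id = 1,
    onset = 10 + spacing_s * (seq_len(n_events) - 1),
    duration = duration,
    trial_type = trial_type,
    trial_id = seq_len(n_events)
  )
}

# Noise-free BOLD from given per-event amplitudes through the canonical HRF.
bold_from_amplitudes <- function(events, amplitudes, tr = 0.645,
                                 pad_s = 30, noise_sd = 0) {
  n_scans <- ceiling((max(events$onset + events$duration) + pad_s) / tr)
  E <- vapply(seq_len(nrow(events)), function(i) {
    beliefvar:::convolve_events(events$onset[i], events$duration[i],
                                tr, n_scans)[, 1L]
  }, numeric(n_scans))
  A <- as.matrix(amplitudes)
  Y <- E %*% A
  if (noise_sd > 0) Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))
  Y
}
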