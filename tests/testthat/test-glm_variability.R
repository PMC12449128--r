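test_that("the canonical HRF peaks near 5 s and derivatives behave", {
  basis <- hrf_basis(0.05)
  t <- seq(0, 32, by = 0.05)
  expect_equal(t[which.max(basis[, "canonical"])], 5, tolerance = 0.3)
  expect_equal(max(basis[, "canonical"]), 1)
  # the temporal derivative of a pulse returning to baseline integrates to ~0
  expect_lt(abs(sum(basis[, "temporal_deriv"]) * 0.05), 0.05)
  # finer sampling converges to the same curve
  coarse <- hrf_basis(0.2)[, "canonical"]
  fine <- hrf_basis(0.05)[, "canonical"]
  expect_lt(max(abs(coarse - fine[seq(1, length(fine), by = 4)])), 1e-6)
})

test_that("design matrices have 3 columns per condition plus a constant", {
  sess <- small_session()
  ev <- session_events(sess)
  ev1 <- ev[ev$block_id == 1, ]
  n_scans <- ceiling((max(ev1$onset + ev1$duration) + 24) / 0.645)
  X <- build_design(ev1, tr = 0.645, n_scans = n_scans)
  expect_equal(ncol(X), 7 * 3 + 1)   # 21 task regressors + constant
  expect_true(all(colSums(abs(X)) > 0))
  expect_error(build_design(ev1, tr = 0.645, n_scans = 10), "past the end")
})

test_that("convolution is linear in the event set", {
  ev <- sparse_events(6)
  n_scans <- 700
  both <- beliefvar:::convolve_events(ev$onset, ev$duration, 0.645, n_scans)
  parts <- beliefvar:::convolve_events(ev$onset[1:3], ev$duration[1:3], 0.645, n_scans) +
    beliefvar:::convolve_events(ev$onset[4:6], ev$duration[4:6], 0.645, n_scans)
  expect_equal(both, parts, tolerance = 1e-12)
})

test_that("LS-S recovers amplitudes exactly on non-overlapping noiseless events", {
  ev <- sparse_events(8, spacing_s = 50)
  amps <- matrix(c(1, -2, 0.5, 3, 2, -1, 0.25, 4), ncol = 1)
  Y <- bold_from_amplitudes(ev, amps, pad_s = 200)
  tb <- lss_betas(Y, ev, "sample_1", tr = 0.645)
  expect_equal(as.vector(tb$betas), as.vector(amps), tolerance = 1e-6)

  # equals standard per-trial OLS: a full model with one regressor per
  # event (which, for disjoint events, is per-trial estimation)
  n_scans <- nrow(Y)
  E <- vapply(seq_len(nrow(ev)), function(i) {
    beliefvar:::convolve_events(ev$onset[i], ev$duration[i], 0.645, n_scans)[, 1L]
  }, numeric(n_scans))
  ols <- unname(coef(lm(Y[, 1] ~ E))[-1])
  expect_equal(as.vector(tb$betas), ols, tolerance = 1e-6)

  # constant signal offsets are absorbed by the constant column
  tb2 <- lss_betas(Y + 17, ev, "sample_1", tr = 0.645)
  expect_equal(tb2$betas, tb$betas, tolerance = 1e-8)
})

test_that("events in the final 20 s of a run are not estimated", {
  ev <- sparse_events(5, spacing_s = 30)
  tr <- 0.645
  n_scans <- ceiling((max(ev$onset) + 10) / tr)  # last event 10 s from end
  E <- vapply(seq_len(nrow(ev)), function(i) {
    beliefvar:::convolve_events(ev$onset[i], ev$duration[i], tr, n_scans)[, 1L]
  }, numeric(n_scans))
  Y <- E %*% matrix(1, 5, 1) + matrix(rnorm(n_scans), n_scans, 1)
  tb <- lss_betas(Y, ev, "sample_1", tr = tr)
  expect_equal(tb$trial_id, 1:4)
})

test_that("SD-BOLD matches closed forms and pools runs", {
  b1 <- structure(list(condition = "sample_1",
                       betas = matrix(c(1, 2, 3), 3, 1), trial_id = 1:3),
                  class = "trial_beta_matrix")
  b2 <- structure(list(condition = "sample_2",
                       betas = matrix(5, 3, 1), trial_id = 1:3),
                  class = "trial_beta_matrix")
  m <- sd_bold(list(b1, b2))
  expect_equal(unname(m$sd[, 1]), c(1, 0))
  # pooling across runs concatenates trials
  b1b <- structure(list(condition = "sample_1",
                        betas = matrix(c(5, 6, 7), 3, 1), trial_id = 4:6),
                   class = "trial_beta_matrix")
  m2 <- sd_bold(list(b1, b1b))
  expect_equal(unname(m2$sd[1, 1]), sd(c(1, 2, 3, 5, 6, 7)))
  expect_equal(unname(m2$n_trials["sample_1"]), 6L)
  single <- structure(list(condition = "x", betas = matrix(1, 1, 1),
                           trial_id = 1), class = "trial_beta_matrix")
  expect_error(sd_bold(list(single)), ">= 2 trials")
})

test_that("SD change slopes follow the SD profile", {
  m <- matrix(c(5, 4, 3, 2, 1, 2, 2, 2, 2, 2), 5, 2)
  rownames(m) <- paste0("sample_", 1:5)
  ch <- sdbold_change(m)
  expect_equal(ch$slope, c(-1, 0), tolerance = 1e-12)
  expect_lt(ch$p_value[1], 0.001)
})

test_that("condition-mean GLM matches LS-S means and is flat for equal amplitudes", {
  # 15 widely spaced events, conditions assigned round-robin: no overlap
  ev <- tibble::tibble(
    block_id = 1,
    onset = 10 + 50 * (0:14),
    duration = 1,
    trial_type = paste0("sample_", rep(1:5, 3)),
    trial_id = 1:15
  )
  cond_amp <- c(2, 1, 3, 0.5, 1.5)
  amps <- matrix(cond_amp[rep(1:5, 3)], ncol = 1)
  Y <- bold_from_amplitudes(ev, amps, pad_s = 200)
  cond <- condition_mean_glm(list(Y), list(ev), tr = 0.645)
  expect_equal(unname(cond[paste0("sample_", 1:5), 1]), cond_amp,
               tolerance = 1e-5)
  # matches LS-S trial means on this non-overlapping design
  lssm <- lss_betas_run(Y, ev, tr = 0.645)
  for (s in 1:5) {
    cc <- paste0("sample_", s)
    expect_equal(unname(cond[cc, 1]), mean(lssm[[cc]]$betas), tolerance = 1e-5)
  }
  # equal amplitudes: equal betas, zero cubic coefficient
  Yflat <- bold_from_amplitudes(ev, matrix(1, nrow(ev), 1), pad_s = 200)
  cflat <- condition_mean_glm(list(Yflat), list(ev), tr = 0.645)
  expect_lt(diff(range(cflat[, 1])), 1e-6)
  expect_lt(abs(condition_poly_coef(cflat, 3)), 1e-6)
})

test_that("the parametric uncertainty GLM recovers the modulation sign", {
  sess <- small_session()
  traj <- uncertainty_trajectories(sess)
  ev <- session_events(sess)
  ev1 <- dplyr::filter(ev, block_id == 1)
  is_s <- grepl("^sample_", ev1$trial_type)
  smp <- ev1[is_s, ]
  mods <- dplyr::left_join(
    smp |> dplyr::mutate(sample_index = as.integer(sub("sample_", "", trial_type))),
    traj, by = c("trial_id", "sample_index"))$post_var
  n_scans <- ceiling((max(ev1$onset + ev1$duration) + 24) / 0.645)
  amps <- matrix(1, nrow(ev1), 2)
  amps[is_s, 1] <- 1 + 10 * (mods - mean(mods))
  amps[is_s, 2] <- 1 - 10 * (mods - mean(mods))
  Y <- bold_from_amplitudes(ev1, amps)
  beta <- parametric_uncertainty_glm(list(Y), list(ev1), list(mods), tr = 0.645)
  expect_gt(beta[1], 1)
  expect_lt(beta[2], -1)
  # adding a constant to the modulators changes nothing (mean-centering)
  beta2 <- parametric_uncertainty_glm(list(Y), list(ev1), list(mods + 5),
                                      tr = 0.645)
  expect_equal(beta2, beta, tolerance = 1e-8)
  # a constant modulator first warns (zero column) then fails as singular
  expect_warning(
    try(parametric_uncertainty_glm(list(Y), list(ev1),
                                   list(rep(0.1, sum(is_s))), tr = 0.645),
        silent = TRUE),
    "Constant modulator")
  expect_error(
    parametric_uncertainty_glm(list(Y), list(ev1), list(mods[-1]), tr = 0.645))
})

test_that("split-half reliability is 1 for duplicated halves and ~0 for noise", {
  half <- matrix(rnorm(20 * 30), 20, 30)
  dup <- structure(list(condition = "sample_1",
                        betas = rbind(half, half), trial_id = 1:40),
                   class = "trial_beta_matrix")
  expect_equal(split_half_reliability(list(dup))$r, 1, tolerance = 1e-10)

  set.seed(2)
  rs <- replicate(60, {
    noise <- structure(list(condition = "sample_1",
                            betas = matrix(rnorm(40 * 100), 40, 100),
                            trial_id = 1:40), class = "trial_beta_matrix")
    split_half_reliability(list(noise))$r
  })
  expect_lt(abs(median(rs)), 0.2)
})

test_that("the design-implied noise scale is positive per condition", {
  sess <- small_session()
  ev1 <- dplyr::filter(session_events(sess), block_id == 1)
  n_scans <- ceiling((max(ev1$onset + ev1$duration) + 24) / 0.645)
  k <- lss_noise_scale(ev1, tr = 0.645, n_scans = n_scans)
  expect_equal(sort(names(k)), paste0("sample_", 1:5))
  expect_true(all(k > 0))
})
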