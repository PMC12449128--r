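# Synthetic 4-D BOLD generator: event amplitudes whose across-trial
# dispersion in designated "effect" voxels follows the observer's
# posterior-variance trajectory, convolved with the canonical HRF.

#' Define a voxel layout
#'
#' A small 3-D grid with a spherical in-brain mask; a contiguous inner
#' sphere of "effect" voxels is coupled to the uncertainty trajectory, the
#' remaining mask voxels are "null". The default desk-scale geometry is a
#' 12 x 12 x 12 grid with a ~200-voxel mask.
#'
#' @param dim Grid dimensions (length 3).
#' @param mask_radius Radius (voxels) of the in-brain sphere.
#' @param effect_radius Radius of the inner effect sphere.
#' @param gain Coupling gain between posterior variance and amplitude SD in
#'   effect voxels (see [generate_subject_bold()]).
#' @param base_sd Baseline across-trial amplitude SD shared by all voxels.
#' @return A `voxel_layout`: list with `dim`, `mask` (index matrix of
#'   in-mask voxel coordinates), `label` (`"effect"`/`"null"` per mask
#'   voxel), `gain`, `base_sd`.
#' @export
voxel_layout <- function(dim = c(12, 12, 12), mask_radius = 3.6,
                         effect_radius = 2.6, gain = 2, base_sd = 0.3) {
  center <- (dim + 1) / 2
  grid <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                                z = seq_len(dim[3])))
  d2 <- sqrt(rowSums(sweep(grid, 2, center)^2))
  mask <- grid[d2 <= mask_radius, , drop = FALSE]
  label <- ifelse(d2[d2 <= mask_radius] <= effect_radius, "effect", "null")
  structure(list(dim = dim, mask = mask, label = label, gain = gain,
                 base_sd = base_sd), class = "voxel_layout")
}

#' @export
print.voxel_layout <- function(x, ...) {
  cat("<voxel_layout> ", paste(x$dim, collapse = " x "), " grid, ",
      nrow(x$mask), " mask voxels (", sum(x$label == "effect"),
      " effect / ", sum(x$label == "null"), " null), gain = ", x$gain,
      "\n", sep = "")
  invisible(x)
}

#' Generate synthetic BOLD runs for one subject
#'
#' For every sample event of trial t at period s, the event amplitude in
#' voxel v is drawn from `Normal(mean_amplitude, sd_vs)`, where for effect
#' voxels `sd_vs = base_sd + gain * Var_s / ref_var` (the observer's
#' posterior variance after sample s, normalized by the flat-prior
#' reference variance 1/12 so the coupling is scale-free and comparable
#' across subjects) while for null voxels the dispersion stays at the
#' `base_sd` baseline for every period.
#' Estimation and gambling events get small constant-dispersion amplitudes.
#' Amplitudes are convolved with the canonical HRF and white Gaussian scan
#' noise (and optionally a slow sinusoidal drift) is added.
#'
#' @param session Session tibble from [build_session()].
#' @param trajectories Output of [uncertainty_trajectories()] for the same
#'   session (per-sample posterior variances of the coupled observer).
#' @param layout A `voxel_layout`.
#' @param tr Repetition time in seconds (0.645 by default).
#' @param mean_amplitude Mean event amplitude (signal units).
#' @param noise_sd SD of additive white scan noise.
#' @param ref_var Reference variance normalizing the posterior variance
#'   (1/12, the flat-prior belief variance, by default).
#' @param nuisance_sd Across-trial amplitude SD of the estimation and
#'   gambling nuisance events. The default (`NULL`) matches each nuisance
#'   event's variance contribution per unit regressor energy to that of a
#'   baseline sample event (`base_sd` scaled by the ratio of convolved
#'   kernel norms), so the trial-wise variance environment seen by the
#'   LS-S estimator is stationary across the whole trial and null voxels
#'   stay flat across sample periods.
#' @param drift_amplitude Amplitude of an optional 0.005 Hz sinusoidal
#'   drift (0 = off).
#' @param pad_s Seconds of rest appended after the last event (covers the
#'   HRF tail; keep > 20 so no estimable event falls in the pruned window).
#' @param seed Optional integer seed (bit-identical runs for a fixed seed).
#' @return A list of runs; each run is a list with `bold` (n_scans x
#'   n_voxels), `events` (tibble), `tr`, `block_id`, and `truth` (the
#'   drawn event amplitudes and per-event SDs).
#' @export
generate_subject_bold <- function(session, trajectories, layout,
                                  tr = 0.645, mean_amplitude = 1,
                                  noise_sd = 0.5, drift_amplitude = 0,
                                  ref_var = 1 / 12, nuisance_sd = NULL,
                                  pad_s = 24, seed = NULL) {
  stopifnot(inherits(layout, "voxel_layout"))
  key <- c("trial_id", "sample_index")
  traj <- trajectories[, c(key, "post_var")]
  if (!all(session$trial_id %in% traj$trial_id)) {
    abort("`trajectories` do not cover every session trial.")
  }
  events_all <- session_events(session)
  n_vox <- nrow(layout$mask)
  effect <- layout$label == "effect"
  with_seed(seed, {
    lapply(sort(unique(events_all$block_id)), function(b) {
      events <- events_all[events_all$block_id == b, ]
      n_scans <- ceiling((max(events$onset + events$duration) + pad_s) / tr)
      is_sample <- grepl("^sample_", events$trial_type)
      sidx <- as.integer(sub("^sample_", "", events$trial_type[is_sample]))
      m <- dplyr::left_join(
        tibble::tibble(trial_id = events$trial_id[is_sample],
                       sample_index = sidx),
        traj, by = key)
      rel_var <- m$post_var / ref_var
      # per-event amplitude SD: uncertainty-coupled in effect voxels,
      # flat baseline dispersion in null voxels
      sd_effect <- layout$base_sd + layout$gain * rel_var
      sd_null <- layout$base_sd
      n_ev <- nrow(events)
      ev_sd <- if (is.null(nuisance_sd)) {
        # energy-matched: SD scaled by convolved kernel norm relative to a
        # 1 s sample event
        norm_of <- function(dur) {
          k <- convolve_events(0, dur, tr, ceiling((dur + 32) / tr))[, 1L]
          sqrt(sum(k^2))
        }
        durs <- unique(events$duration)
        norms <- vapply(durs, norm_of, numeric(1))
        ref <- norms[which.min(abs(durs - 1))]
        layout$base_sd * ref / norms[match(events$duration, durs)]
      } else {
        rep(nuisance_sd, n_ev)
      }
      A <- matrix(rnorm(n_ev * n_vox, mean_amplitude, ev_sd), n_ev, n_vox)
      A[is_sample, effect] <- rnorm(sum(is_sample) * sum(effect),
                                    mean_amplitude, rep(sd_effect, sum(effect)))
      A[is_sample, !effect] <- rnorm(sum(is_sample) * sum(!effect),
                                     mean_amplitude, sd_null)
      # canonical-HRF regressor per event; signal = E %*% A
      reg <- event_regressors(events, tr, n_scans)
      E <- vapply(reg$E, function(e) e[, 1L], numeric(n_scans))
      bold <- E %*% A + matrix(rnorm(n_scans * n_vox, 0, noise_sd),
                               n_scans, n_vox)
      if (drift_amplitude > 0) {
        t_s <- (seq_len(n_scans) - 1) * tr
        bold <- bold + drift_amplitude *
          sin(2 * pi * 0.005 * t_s + runif(1, 0, 2 * pi))
      }
      list(bold = bold, events = events, tr = tr, block_id = b,
           truth = list(amplitudes = A,
                        sample_sd_effect = sd_effect,
                        sample_sd_null = sd_null))
    })
  })
}

#' Write synthetic runs in a BIDS-like layout
#'
#' Writes one 4-D NIfTI per run, a mask and an effect-label NIfTI, one
#' BIDS-style events TSV per run (`onset`, `duration`, `trial_type`,
#' `trial_id`), and a ground-truth JSON.
#'
#' @param runs List of runs from [generate_subject_bold()].
#' @param layout The `voxel_layout` used to generate them.
#' @param dir Output directory (created if needed).
#' @param voxel_size_mm Voxel edge length recorded in the NIfTI header.
#' @return The output directory, invisibly.
#' @export
write_bids_like <- function(runs, layout, dir, voxel_size_mm = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dim3 <- layout$dim
  lin <- layout$mask[, 1] + dim3[1] * (layout$mask[, 2] - 1) +
    dim3[1] * dim3[2] * (layout$mask[, 3] - 1)
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    vol <- array(0, c(dim3, nrow(run$bold)))
    flat <- matrix(vol, prod(dim3), nrow(run$bold))
    flat[lin, ] <- t(run$bold)
    vol <- array(flat, c(dim3, nrow(run$bold)))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3), run$tr)
    RNifti::writeNifti(img, file.path(dir, sprintf("run-%02d_bold.nii", r)))
    readr::write_tsv(run$events,
                     file.path(dir, sprintf("run-%02d_events.tsv", r)))
  }
  mask_arr <- array(0L, dim3); mask_arr[lin] <- 1L
  label_arr <- array(0L, dim3)
  label_arr[lin] <- ifelse(layout$label == "effect", 2L, 1L)
  mask_img <- RNifti::asNifti(mask_arr)
  RNifti::pixdim(mask_img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii"))
  label_img <- RNifti::asNifti(label_arr)
  RNifti::pixdim(label_img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(label_img, file.path(dir, "labels.nii"))
  truth <- list(
    schema_version = "1.0",
    n_runs = length(runs),
    tr = runs[[1]]$tr,
    gain = layout$gain,
    base_sd = layout$base_sd,
    n_mask_voxels = nrow(layout$mask),
    n_effect_voxels = sum(layout$label == "effect")
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a BIDS-like synthetic dataset back
#'
#' @param dir Directory written by [write_bids_like()].
#' @return A list of runs (`bold` matrices restricted to the mask,
#'   `events`, `tr`) plus `mask`, `label`.
#' @export
read_bids_like <- function(dir) {
  mask_arr <- RNifti::readNifti(file.path(dir, "mask.nii"))
  label_arr <- RNifti::readNifti(file.path(dir, "labels.nii"))
  lin <- which(mask_arr == 1L)
  bold_files <- sort(list.files(dir, "^run-\\d+_bold\\.nii$",
                                full.names = TRUE))
  runs <- lapply(bold_files, function(f) {
    img <- RNifti::readNifti(f)
    tr <- RNifti::pixdim(img)[4]
    flat <- matrix(img, prod(dim(img)[1:3]), dim(img)[4])
    events <- readr::read_tsv(sub("_bold\\.nii$", "_events.tsv", f),
                              show_col_types = FALSE)
    list(bold = t(flat[lin, , drop = FALSE]), events = events, tr = tr)
  })
  list(runs = runs, mask = lin,
       label = ifelse(label_arr[lin] == 2L, "effect", "null"))
}
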