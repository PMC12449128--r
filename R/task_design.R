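# Marble-task design: jars, binomial sample draws, and full session
# sequences shared by the behavioral and neural simulations.

#' Construct a set of jars with blue-marble proportions
#'
#' Jars are the latent states of the estimation task: each holds an unseen
#' proportion of blue marbles that the observer must infer from samples. The
#' default grid spans 0.1 to 0.91 with 18 jars, matching the study design.
#'
#' @param n_jars Number of jars (>= 2).
#' @param p_min,p_max Bounds of the blue-marble proportion grid, both in (0, 1).
#' @return A tibble with columns `jar_id` and `p_blue` (evenly spaced,
#'   distinct proportions spanning `[p_min, p_max]`).
#' @examples
#' make_jars()
#' make_jars(2, 0.25, 0.75)
#' @export
make_jars <- function(n_jars = 18, p_min = 0.1, p_max = 0.91) {
  if (!is_count(n_jars) || n_jars < 2) {
    abort("`n_jars` must be an integer >= 2.")
  }
  if (!(p_min > 0 && p_max < 1 && p_min < p_max)) {
    abort("Need 0 < p_min < p_max < 1.")
  }
  tibble::tibble(
    jar_id = seq_len(n_jars),
    p_blue = seq(p_min, p_max, length.out = n_jars)
  )
}

#' Draw the fixed sample set for one jar
#'
#' Each jar is associated with one fixed set of samples: `n_samples` draws
#' whose sizes come from `sizes` (1, 5 or 9 marbles by default, manipulating
#' sample informativeness) and whose blue counts are binomial in the jar's
#' `p_blue`. The draw is performed once per jar; across repeated trials of
#' the same jar only the sample order changes.
#'
#' @param p_blue Blue-marble proportion of the jar.
#' @param n_samples Number of samples per trial (5 by default).
#' @param sizes Allowed marble counts per sample; each sample's size is drawn
#'   uniformly from this set.
#' @return A tibble with columns `sample_index`, `size`, `n_blue`, `n_red`.
#' @export
draw_jar_samples <- function(p_blue, n_samples = 5, sizes = c(1, 5, 9)) {
  check_proportion(p_blue, "p_blue")
  stopifnot(is_count(n_samples), n_samples >= 1, length(sizes) >= 1)
  size <- sizes[sample.int(length(sizes), n_samples, replace = TRUE)]
  n_blue <- rbinom(n_samples, size, p_blue)
  tibble::tibble(
    sample_index = seq_len(n_samples),
    size = as.integer(size),
    n_blue = as.integer(n_blue),
    n_red = as.integer(size - n_blue)
  )
}

#' Build a full session trial sequence
#'
#' A session presents every jar once per block, in random order within each
#' block, with the jar's fixed sample set re-used across blocks in freshly
#' permuted order. Event onsets are laid out per block (one scanner run per
#' block): each sample lasts `sample_duration_s` followed by a fixation
#' interval drawn uniformly from `iti_range_s` in `iti_step_s` steps; the
#' estimation phase and a nuisance gambling phase follow the fifth sample.
#'
#' @param jars Tibble from [make_jars()].
#' @param n_blocks Number of blocks / scanner runs (3 by default).
#' @param n_samples Samples per trial.
#' @param sizes Allowed sample sizes.
#' @param iti_range_s Fixation interval range in seconds (uniform in steps).
#' @param iti_step_s Step of the fixation grid, seconds.
#' @param sample_duration_s Sample presentation duration, seconds.
#' @param estimation_duration_s Estimation phase duration, seconds.
#' @param gambling_duration_s Gambling (nuisance) phase duration, seconds.
#' @param lead_in_s Dead time at the start of each run, seconds.
#' @param iti_trial_s Gap after the gambling phase before the next trial.
#' @param drop_rate Proportion of trials marked as missing responses
#'   (`valid = FALSE`), to exercise missing-data handling. Off by default.
#' @param seed Optional integer seed; the same seed reproduces the session
#'   bit-identically.
#' @return A tibble with one row per (trial, sample): `trial_id`, `block_id`,
#'   `jar_id`, `p_blue`, `sample_index`, `size`, `n_blue`, `n_red`,
#'   `onset_s`, `duration_s`, `estimation_onset_s`, `gambling_onset_s`,
#'   `valid`. Onsets are seconds from the start of the trial's run (0-based).
#' @export
build_session <- function(jars = make_jars(),
                          n_blocks = 3,
                          n_samples = 5,
                          sizes = c(1, 5, 9),
                          iti_range_s = c(2, 6),
                          iti_step_s = 0.5,
                          sample_duration_s = 1,
                          estimation_duration_s = 7,
                          gambling_duration_s = 2.5,
                          lead_in_s = 10,
                          iti_trial_s = 2,
                          drop_rate = 0,
                          seed = NULL) {
  stopifnot(nrow(jars) >= 1, is_count(n_blocks), n_blocks >= 1)
  with_seed(seed, {
    # one fixed sample set per jar, shared across blocks
    jar_samples <- lapply(seq_len(nrow(jars)), function(i) {
      draw_jar_samples(jars$p_blue[i], n_samples = n_samples, sizes = sizes)
    })
    iti_grid <- seq(iti_range_s[1], iti_range_s[2], by = iti_step_s)
    trial_id <- 0L
    rows <- vector("list", n_blocks * nrow(jars))
    for (b in seq_len(n_blocks)) {
      order_b <- sample.int(nrow(jars))
      t_run <- lead_in_s
      for (j in order_b) {
        trial_id <- trial_id + 1L
        smp <- jar_samples[[j]][sample.int(n_samples), ]
        smp$sample_index <- seq_len(n_samples)
        itis <- iti_grid[sample.int(length(iti_grid), n_samples, replace = TRUE)]
        onsets <- t_run + cumsum(c(0, rep(sample_duration_s, n_samples - 1) +
                                     itis[-n_samples]))
        est_onset <- onsets[n_samples] + sample_duration_s + itis[n_samples]
        gam_onset <- est_onset + estimation_duration_s + 0.5
        rows[[trial_id]] <- tibble::tibble(
          trial_id = trial_id,
          block_id = b,
          jar_id = jars$jar_id[j],
          p_blue = jars$p_blue[j],
          sample_index = smp$sample_index,
          size = smp$size,
          n_blue = smp$n_blue,
          n_red = smp$n_red,
          onset_s = onsets,
          duration_s = sample_duration_s,
          estimation_onset_s = est_onset,
          gambling_onset_s = gam_onset
        )
        t_run <- gam_onset + gambling_duration_s + iti_trial_s
      }
    }
    session <- dplyr::bind_rows(rows)
    n_trials <- max(session$trial_id)
    dropped <- if (drop_rate > 0) {
      sample.int(n_trials, size = round(drop_rate * n_trials))
    } else integer(0)
    session$valid <- !(session$trial_id %in% dropped)
    session
  })
}

#' Convert a session into per-run BIDS-style event tables
#'
#' @param session Tibble from [build_session()].
#' @return A tibble with columns `block_id`, `onset`, `duration`,
#'   `trial_type` (`sample_1` ... `sample_5`, `estimation`, `gambling`) and
#'   `trial_id`, sorted by onset within run.
#' @export
session_events <- function(session) {
  samples <- session |>
    dplyr::transmute(
      block_id = .data$block_id,
      onset = .data$onset_s,
      duration = .data$duration_s,
      trial_type = paste0("sample_", .data$sample_index),
      trial_id = .data$trial_id
    )
  per_trial <- session |>
    dplyr::distinct(.data$trial_id, .data$block_id, .data$estimation_onset_s,
                    .data$gambling_onset_s)
  extra <- dplyr::bind_rows(
    per_trial |>
      dplyr::transmute(block_id = .data$block_id, onset = .data$estimation_onset_s,
                       duration = 7, trial_type = "estimation",
                       trial_id = .data$trial_id),
    per_trial |>
      dplyr::transmute(block_id = .data$block_id, onset = .data$gambling_onset_s,
                       duration = 2.5, trial_type = "gambling",
                       trial_id = .data$trial_id)
  )
  dplyr::bind_rows(samples, extra) |>
    dplyr::arrange(.data$block_id, .data$onset)
}

#' Write / read a session as TSV
#'
#' @param session Session tibble.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the session tibble (reader).
#' @export
write_session_tsv <- function(session, path) {
  readr::write_tsv(session, path)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
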