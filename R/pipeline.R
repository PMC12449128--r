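# End-to-end study replica: simulate agents and BOLD, fit models, compute
# SD-BOLD maps, run PLS and the latent regressions, from one configuration.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    task = list(n_jars = 18, p_min = 0.1, p_max = 0.91, n_blocks = 3,
                sizes = c(1, 5, 9), iti_range_s = c(2, 6)),
    agents = list(n_subjects = 30, family = "bayes_rho_sigma",
                  rho_meanlog = log(2.45), rho_sdlog = 1.1,
                  rho_max = 20, sigma_meanlog = log(0.10),
                  sigma_sdlog = 0.15, sigma_range = c(0.03, 0.3)),
    neuro = list(dim = c(12, 12, 12), mask_radius = 3.6,
                 effect_radius = 2.6, gain = 2, base_sd = 0.3,
                 noise_sd = 0.5, tr = 0.645, mean_amplitude = 1),
    analysis = list(n_perm = 500, n_boot = 500, bsr_threshold = 3,
                    cluster_min_size = 25, rank = TRUE, n_starts = 10,
                    fit_families = c("bayes_rho_sigma", "bayes_delta_sigma",
                                     "rescorla_wagner"))
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and out-of-bound values. The
#' operation is idempotent: `validate_config(validate_config(x))` equals
#' `validate_config(x)`.
#'
#' @param config A named list, a YAML file path, or `NULL` (defaults).
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("No config file at '%s'.", config))
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("Unknown config block(s):", paste(unknown, collapse = ", ")))
  }
  out <- defaults
  for (blk in names(config)) {
    if (blk == "seed") { out$seed <- as.integer(config$seed); next }
    unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown key(s) in '%s': %s", blk,
                    paste(unknown, collapse = ", ")))
    }
    out[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  with(out$task, {
    if (!(p_min > 0 && p_max < 1 && p_min < p_max)) {
      abort("task$p_min / p_max must satisfy 0 < p_min < p_max < 1.")
    }
  })
  if (exp(out$agents$rho_meanlog) < 1) {
    abort("agents$rho_meanlog implies a median prior width below 1.")
  }
  if (out$agents$sigma_range[1] <= 0) abort("sigma must be positive.")
  if (out$analysis$n_perm < 100 || out$analysis$n_boot < 100) {
    abort("analysis$n_perm and n_boot must be >= 100.")
  }
  out
}

#' Draw an agent population
#'
#' Prior widths are log-normal around the fitted group median (2.45) and
#' truncated to \[1, rho_max\]; response noise is log-normal around the
#' fitted median (0.10), truncated to `sigma_range`. This population is the
#' study condition emulated by the synthetic datasets.
#'
#' @param config Validated configuration (the `agents` block is used).
#' @param seed Integer seed.
#' @return A tibble `subject_id`, `family`, `rho`, `sigma`.
#' @export
draw_agent_population <- function(config = validate_config(), seed = NULL) {
  a <- config$agents
  with_seed(seed, {
    rho <- pmin(a$rho_max,
                pmax(1, exp(rnorm(a$n_subjects, a$rho_meanlog, a$rho_sdlog))))
    sigma <- pmin(a$sigma_range[2],
                  pmax(a$sigma_range[1],
                       exp(rnorm(a$n_subjects, a$sigma_meanlog, a$sigma_sdlog))))
    tibble::tibble(subject_id = seq_len(a$n_subjects), family = a$family,
                   rho = rho, sigma = sigma)
  })
}

#' Run the full study replica
#'
#' Executes every stage in order: task design, agent simulation, model
#' fitting and BIC comparison, behavioral metrics, synthetic BOLD
#' generation, LS-S / SD-BOLD estimation, task and behavioral PLS with
#' permutation inference, polynomial contrasts, and the rank-based latent
#' regression of change-in-SD-BOLD on the fitted observer parameters.
#' Identical seeds produce identical reports.
#'
#' @param config Configuration list or YAML path (see [validate_config()]).
#' @param out_dir Optional directory: the machine-readable JSON report and
#'   a per-subject TSV are written there.
#' @return A `pipeline_report` list with per-stage results and a `report`
#'   element of scalar summaries.
#' @export
run_full_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  t0 <- Sys.time()

  # -- task design
  jars <- make_jars(cfg$task$n_jars, cfg$task$p_min, cfg$task$p_max)
  session <- build_session(jars, n_blocks = cfg$task$n_blocks,
                           sizes = cfg$task$sizes,
                           iti_range_s = cfg$task$iti_range_s,
                           seed = derive_seed(seed, "task"))

  # -- agents and behavior
  agents <- draw_agent_population(cfg, seed = derive_seed(seed, "population"))
  behav <- simulate_agents(agents, session, seed = derive_seed(seed, "agents"))
  fits <- fit_observers(behav, families = cfg$analysis$fit_families,
                        n_starts = cfg$analysis$n_starts,
                        seed = derive_seed(seed, "fits"))
  comparison <- compare_models(fits)
  summary_tbl <- behavior_summary(behav)
  errs <- estimation_errors(behav)
  bias_test <- trialwise_bias_test(errs)

  # -- synthetic BOLD and SD-BOLD
  layout <- voxel_layout(cfg$neuro$dim, cfg$neuro$mask_radius,
                         cfg$neuro$effect_radius, cfg$neuro$gain,
                         cfg$neuro$base_sd)
  conds <- paste0("sample_", 1:5)
  n_sub <- nrow(agents)
  sd_arr <- NULL
  slopes <- NULL
  for (i in seq_len(n_sub)) {
    traj <- uncertainty_trajectories(session, rho = agents$rho[i])
    runs <- generate_subject_bold(session, traj, layout,
                                  tr = cfg$neuro$tr,
                                  mean_amplitude = cfg$neuro$mean_amplitude,
                                  noise_sd = cfg$neuro$noise_sd,
                                  seed = derive_seed(seed, "bold", i))
    betas <- purrr::map(runs, function(run) {
      lss_betas_run(run$bold, run$events, tr = run$tr, conditions = conds)
    }) |> purrr::flatten()
    sdmap <- sd_bold(betas)
    if (is.null(sd_arr)) {
      sd_arr <- array(NA_real_, c(n_sub, length(conds), ncol(sdmap$sd)))
      slopes <- matrix(NA_real_, n_sub, ncol(sdmap$sd))
    }
    sd_arr[i, , ] <- sdmap$sd[conds, ]
    slopes[i, ] <- sdbold_change(sdmap)$slope
  }

  # -- task PLS of SD-BOLD across sample periods
  tpls <- task_pls(sd_arr)
  tpls <- permutation_test(tpls, n_perm = cfg$analysis$n_perm,
                           seed = derive_seed(seed, "perm_task"))
  poly <- polynomial_contrasts(tpls$brain_scores[, , 1L])

  # -- behavioral PLS of slopes vs median error
  rho_hat <- fits |>
    dplyr::filter(.data$family == "bayes_rho_sigma") |>
    dplyr::arrange(.data$subject_id)
  subj_tbl <- summary_tbl |>
    dplyr::left_join(rho_hat |> dplyr::select("subject_id", "rho", "sigma"),
                     by = "subject_id")
  # multivariate outlier screening (Cook's distance > 4/n) on the latent
  # change-in-SD / error relationship; flagged subjects are dropped from
  # this and the downstream latent analyses
  pre <- behavioral_pls(slopes, subj_tbl$median_error,
                        rank = cfg$analysis$rank)
  out_idx <- cooks_screen(pre$brain_scores[, 1L], rank(subj_tbl$median_error))
  keep <- setdiff(seq_len(n_sub), out_idx)
  slopes <- slopes[keep, , drop = FALSE]
  subj_tbl <- subj_tbl[keep, ]
  bpls <- behavioral_pls(slopes, subj_tbl$median_error,
                         rank = cfg$analysis$rank)
  bpls <- permutation_test(bpls, n_perm = cfg$analysis$n_perm,
                           seed = derive_seed(seed, "perm_behav"))
  bpls <- bootstrap_bsr(bpls, n_boot = cfg$analysis$n_boot,
                        threshold = cfg$analysis$bsr_threshold,
                        seed = derive_seed(seed, "boot"))
  clus <- cluster_threshold(volume_from_mask(bpls$bsr_mask[, 1L], layout),
                            min_size = cfg$analysis$cluster_min_size,
                            values = volume_from_mask(bpls$bsr[, 1L], layout))

  # -- latent regression: delta-SD-BOLD brain scores on fitted rho, sigma
  # (univariate-outlier winsorization of the fitted parameters, as for the
  # behavioral summary measures)
  subj_tbl$latent_dsdbold <- bpls$brain_scores[, 1L]
  subj_tbl$rho <- winsorize(subj_tbl$rho)
  subj_tbl$sigma <- winsorize(subj_tbl$sigma)
  latreg <- latent_regression(subj_tbl, "latent_dsdbold", c("rho", "sigma"),
                              rank = cfg$analysis$rank)

  report <- list(
    config_seed = seed,
    n_subjects = n_sub,
    n_outliers_removed = length(out_idx),
    n_trials = max(session$trial_id),
    n_voxels = nrow(layout$mask),
    winning_family = comparison$winner,
    median_rho_hat = median(rho_hat$rho),
    median_sigma_hat = median(rho_hat$sigma),
    group_median_error = median(subj_tbl$median_error),
    mean_extreme_jar_bias = mean(subj_tbl$extreme_jar_bias),
    bias_test_p = bias_test$p_value,
    task_pls_p = tpls$p_perm[1L],
    linear_contrast_p = poly$p_value[poly$order == "linear"],
    linear_contrast_eta = poly$eta_sq_partial[poly$order == "linear"],
    behav_pls_p = bpls$p_perm[1L],
    behav_pls_latent_cor = bpls$latent_cor[1L],
    n_robust_clusters = nrow(clus$clusters),
    rho_effect_p = latreg$terms$p_value[latreg$terms$term == "rho"],
    sigma_effect_p = latreg$terms$p_value[latreg$terms$term == "sigma"],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- list(config = cfg, agents = agents, fits = fits,
              comparison = comparison, behavior = subj_tbl,
              bias_test = bias_test, sd_bold = sd_arr, slopes = slopes,
              layout = layout, task_pls = tpls, poly_contrasts = poly,
              behav_pls = bpls, clusters = clus$clusters,
              latent_regression = latreg, report = report)
  class(out) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep_out <- report
    rep_out$elapsed_s <- NULL # keep the JSON byte-identical across reruns
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(subj_tbl, file.path(out_dir, "subjects.tsv"))
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("<pipeline_report>\n")
  cat(sprintf("  %d subjects, %d trials, %d voxels (seed %d)\n",
              r$n_subjects, r$n_trials, r$n_voxels, r$config_seed))
  cat(sprintf("  winning model: %s (median rho = %.2f, sigma = %.2f)\n",
              r$winning_family, r$median_rho_hat, r$median_sigma_hat))
  cat(sprintf("  group median estimation error: %.3f\n", r$group_median_error))
  cat(sprintf("  task PLS p = %.4g (linear contrast p = %.3g)\n",
              r$task_pls_p, r$linear_contrast_p))
  cat(sprintf("  behavioral PLS p = %.4g, latent r = %.3f\n",
              r$behav_pls_p, r$behav_pls_latent_cor))
  cat(sprintf("  rho effect p = %.4g, sigma effect p = %.4g\n",
              r$rho_effect_p, r$sigma_effect_p))
  invisible(x)
}
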