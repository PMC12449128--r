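# Maximum-likelihood fitting of observer models, BIC model comparison, agent
# simulation, and parameter / model recovery studies.

start_caps <- c(rho = 10, delta = 2, sigma = 0.5, learning_rate = 1)

#' Fit one observer model to one subject's behavior
#'
#' Bounded quasi-Newton minimization (`optim`, L-BFGS-B) of the dataset
#' negative log-likelihood from `n_starts` random interior starting points;
#' the best converged solution is kept. Bounds: rho in \[1, 50\], delta in
#' \[0, 5\], sigma in \[1e-3, 1\], learning rate in \[0, 1\]. Starts are
#' drawn uniformly over the empirically plausible sub-box (rho <= 10,
#' delta <= 2, sigma <= 0.5) so multi-start search concentrates where fitted
#' values live while the optimizer may still move to the full bounds.
#'
#' @param data Long behavior tibble: one row per (trial, sample) with
#'   `trial_id`, `sample_index`, `n_blue`, `n_red`, `reported_estimate`, and
#'   optionally `valid` (invalid trials are dropped before fitting).
#' @param family Observer family name (see [observer_spec()]).
#' @param n_starts Number of random starts (10 by default).
#' @param seed Optional integer seed; the same seed reproduces the fit
#'   bit-identically.
#' @return An `observer_fit` object: fitted `spec`, `negloglik`, `n_trials`,
#'   `n_params`, `bic`, `n_starts`, `converged`.
#' @export
fit_observer <- function(data, family, n_starts = 10, seed = NULL) {
  family <- match.arg(family, OBSERVER_FAMILIES)
  if ("valid" %in% names(data)) data <- dplyr::filter(data, .data$valid)
  n_trials <- dplyr::n_distinct(data$trial_id)
  if (n_trials < 2) abort("Need at least 2 valid trials to fit.")
  info <- observer_param_info(family)
  k <- length(info$names)
  caps <- pmin(info$upper, start_caps[info$names])

  prep <- prepare_trials(data)
  nll_fun <- make_negloglik_fun(family, prep)
  objective <- function(par) {
    names(par) <- info$names
    nll <- nll_fun(par)
    if (!is.finite(nll)) 1e10 else nll
  }

  with_seed(seed, {
    starts <- matrix(runif(n_starts * k, rep(info$lower, each = n_starts),
                           rep(caps, each = n_starts)),
                     nrow = n_starts)
    runs <- lapply(seq_len(n_starts), function(i) {
      tryCatch(
        optim(starts[i, ], objective, method = "L-BFGS-B",
              lower = info$lower, upper = info$upper,
              control = list(maxit = 500)),
        error = function(e) NULL
      )
    })
    runs <- Filter(Negate(is.null), runs)
    if (length(runs) == 0) {
      return(structure(list(
        spec = NULL, family = family, negloglik = NA_real_,
        n_trials = n_trials, n_params = k, bic = NA_real_,
        n_starts = n_starts, converged = FALSE
      ), class = "observer_fit"))
    }
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    # guard against optimizer round-off just outside the box
    par <- setNames(pmin(pmax(best$par, info$lower), info$upper), info$names)
    structure(list(
      spec = observer_spec(family, par),
      family = family,
      negloglik = best$value,
      n_trials = n_trials,
      n_params = k,
      bic = k * log(n_trials) + 2 * best$value,
      n_starts = n_starts,
      converged = any(vapply(runs, `[[`, numeric(1), "convergence") == 0)
    ), class = "observer_fit")
  })
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("<observer_fit> ", x$family,
      sprintf(" (n = %d trials, k = %d)\n", x$n_trials, x$n_params), sep = "")
  if (!is.null(x$spec)) {
    cat("  ", paste(sprintf("%s = %.4g", names(x$spec$params), x$spec$params),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  -lnL = %.3f, BIC = %.3f, converged = %s\n",
              x$negloglik, x$bic, x$converged))
  invisible(x)
}

#' @export
tidy.observer_fit <- function(x, ...) {
  if (is.null(x$spec)) return(tibble::tibble(term = character(), estimate = numeric()))
  tibble::tibble(term = names(x$spec$params),
                 estimate = unname(x$spec$params))
}

#' @export
glance.observer_fit <- function(x, ...) {
  tibble::tibble(family = x$family, negloglik = x$negloglik,
                 n_trials = x$n_trials, n_params = x$n_params,
                 bic = x$bic, converged = x$converged)
}

#' Bayesian Information Criterion of a fit
#'
#' `BIC = k ln(n) - 2 ln(L) = k ln(n) + 2 * negloglik`, with `n` the number
#' of valid trials (one response per trial) and `k` the number of free
#' parameters.
#'
#' @param fit An `observer_fit`, or a negative log-likelihood when `k` and
#'   `n` are given explicitly.
#' @param k,n Parameter and trial counts (taken from `fit` when omitted).
#' @return The BIC value.
#' @export
bic_of <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "observer_fit")) {
    nll <- fit$negloglik
    k <- k %||% fit$n_params
    n <- n %||% fit$n_trials
  } else {
    nll <- fit
  }
  if (is.null(n) || n <= 0) abort("`n` must be a positive trial count.")
  k * log(n) + 2 * nll
}

#' Fit several families to several subjects
#'
#' @param data Long behavior tibble with a `subject_id` column (plus the
#'   columns required by [fit_observer()]).
#' @param families Character vector of observer families.
#' @param n_starts Random starts per fit.
#' @param seed Master seed; per-(subject, family) seeds are derived.
#' @return A tibble with one row per (subject, family): `subject_id`,
#'   `family`, `fit` (list column), `negloglik`, `bic`, `converged`, and the
#'   fitted parameters unnested as columns.
#' @export
fit_observers <- function(data, families = OBSERVER_FAMILIES,
                          n_starts = 10, seed = NULL) {
  subjects <- sort(unique(data$subject_id))
  grid <- tidyr::expand_grid(subject_id = subjects, family = families)
  fits <- purrr::pmap(grid, function(subject_id, family) {
    sub <- dplyr::filter(data, .data$subject_id == !!subject_id)
    s <- if (is.null(seed)) NULL else {
      derive_seed(seed, paste0("fit_", family), match(subject_id, subjects))
    }
    fit_observer(sub, family, n_starts = n_starts, seed = s)
  })
  grid$fit <- fits
  grid$negloglik <- vapply(fits, `[[`, numeric(1), "negloglik")
  grid$bic <- vapply(fits, `[[`, numeric(1), "bic")
  grid$converged <- vapply(fits, `[[`, logical(1), "converged")
  params <- purrr::map_dfr(fits, function(f) {
    if (is.null(f$spec)) return(tibble::tibble(.rows = 1))
    tibble::as_tibble(as.list(f$spec$params))
  })
  dplyr::bind_cols(grid, params)
}

#' Compare fitted model families by BIC
#'
#' @param fits Tibble from [fit_observers()] (needs `subject_id`, `family`,
#'   `bic`). Every subject must be fitted under every family.
#' @return A list with `per_subject` (wide tibble of per-subject BICs),
#'   `total` (summed BIC per family, ascending), and `winner` (family with
#'   the minimal summed BIC).
#' @export
compare_models <- function(fits) {
  counts <- fits |>
    dplyr::count(.data$family) |>
    dplyr::pull(.data$n)
  if (length(unique(counts)) != 1) {
    abort("Every family must be fitted to the same set of subjects.")
  }
  per_subject <- fits |>
    dplyr::select("subject_id", "family", "bic") |>
    tidyr::pivot_wider(names_from = "family", values_from = "bic")
  total <- fits |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(bic = sum(.data$bic), .groups = "drop") |>
    dplyr::arrange(.data$bic)
  list(per_subject = per_subject, total = total,
       winner = total$family[1L])
}

# --- simulation -------------------------------------------------------------

# Sample from Normal(mean, sd) truncated to [0, 1] via inverse-CDF.
rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

snap_to_grid <- function(x) pmin(1, pmax(0, round(x * 100) / 100))

#' Simulate one agent's responses on a session
#'
#' Reported estimates are sampled from the observer's choice rule (truncated
#' normal around the model prediction, or a draw from the final beta
#' distribution) and snapped to the 1/100 response grid of the estimation
#' interface.
#'
#' @param spec An `observer_spec`.
#' @param session Session tibble from [build_session()].
#' @param seed Optional integer seed.
#' @return The session rows with a per-trial `reported_estimate` column.
#' @export
simulate_responses <- function(spec, session, seed = NULL) {
  pred <- final_predictions(spec, session)
  with_seed(seed, {
    raw <- if (is_draw_family(spec$family)) {
      rbeta(nrow(pred), pred$alpha, pred$beta)
    } else {
      m <- if (is_bayes_family(spec$family)) {
        pred$alpha / (pred$alpha + pred$beta)
      } else {
        pred$point
      }
      rtruncnorm01(nrow(pred), m, spec_param(spec, "sigma", 0))
    }
    resp <- tibble::tibble(trial_id = pred$trial_id,
                           reported_estimate = snap_to_grid(raw))
    dplyr::left_join(session, resp, by = "trial_id")
  })
}

#' Simulate a population of agents
#'
#' @param agents Tibble with `subject_id` and a `spec` list-column of
#'   `observer_spec` objects (or columns `family` plus parameter columns).
#' @param session A session tibble shared by all agents, or a list of
#'   sessions (one per agent).
#' @param seed Master seed; per-agent seeds are derived.
#' @return Long behavior tibble across agents with `subject_id` prepended.
#' @export
simulate_agents <- function(agents, session, seed = NULL) {
  specs <- if ("spec" %in% names(agents)) {
    agents$spec
  } else {
    purrr::pmap(agents, function(subject_id, family, ...) {
      pars <- c(...)
      info <- observer_param_info(family)
      do.call(observer_spec, c(list(family), as.list(pars[info$names])))
    })
  }
  purrr::map_dfr(seq_len(nrow(agents)), function(i) {
    sess <- if (is.data.frame(session)) session else session[[i]]
    s <- if (is.null(seed)) NULL else derive_seed(seed, "agents", i)
    out <- simulate_responses(specs[[i]], sess, seed = s)
    dplyr::bind_cols(tibble::tibble(subject_id = agents$subject_id[i],
                                    .rows = nrow(out)), out)
  })
}

# --- recovery ---------------------------------------------------------------

default_param_ranges <- list(
  rho = c(1, 10), delta = c(0.3, 2), sigma = c(0.03, 0.2),
  learning_rate = c(0.1, 0.9)
)

sample_params <- function(family, n, ranges = default_param_ranges) {
  info <- observer_param_info(family)
  out <- lapply(info$names, function(p) {
    r <- ranges[[p]]
    runif(n, r[1], r[2])
  })
  names(out) <- info$names
  tibble::as_tibble(out)
}

#' Parameter recovery study
#'
#' Simulates agents with known parameters drawn uniformly from `ranges`,
#' refits the generating family, and summarizes recovered-versus-true
#' agreement per parameter.
#'
#' @param family Generating (and fitted) observer family.
#' @param n_subjects Number of simulated agents.
#' @param session Session tibble used for every agent.
#' @param ranges Named list of parameter ranges to draw true values from.
#' @param n_starts Random starts per fit.
#' @param seed Master seed.
#' @return A list: `results` (tibble of true and recovered values per agent)
#'   and `summary` (per-parameter Pearson correlation and median absolute
#'   error).
#' @export
recovery_study <- function(family, n_subjects = 30, session = NULL,
                           ranges = default_param_ranges, n_starts = 10,
                           seed = NULL) {
  session <- session %||% build_session(seed = if (is.null(seed)) NULL else
    derive_seed(seed, "task"))
  truth <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "truth"),
                     sample_params(family, n_subjects, ranges))
  agents <- dplyr::bind_cols(tibble::tibble(subject_id = seq_len(n_subjects),
                                            family = family), truth)
  behav <- simulate_agents(agents, session, seed = seed)
  fits <- fit_observers(behav, families = family, n_starts = n_starts,
                        seed = seed)
  info <- observer_param_info(family)
  results <- dplyr::bind_cols(
    agents |> dplyr::rename_with(~ paste0("true_", .x), dplyr::all_of(info$names)),
    fits |> dplyr::select(dplyr::all_of(info$names)) |>
      dplyr::rename_with(~ paste0("est_", .x))
  )
  summary <- purrr::map_dfr(info$names, function(p) {
    tv <- results[[paste0("true_", p)]]
    ev <- results[[paste0("est_", p)]]
    tibble::tibble(parameter = p,
                   correlation = cor(tv, ev),
                   median_abs_error = median(abs(tv - ev)))
  })
  list(results = results, summary = summary)
}

#' Model recovery study
#'
#' Simulates datasets from each generating family, fits all candidate
#' families to each dataset, and tabulates which family wins the summed BIC.
#'
#' @param families Candidate (and generating) families.
#' @param n_datasets Datasets per generating family.
#' @param n_subjects Agents per dataset.
#' @param session Session tibble shared by all datasets.
#' @param ranges Parameter ranges for true values.
#' @param n_starts Random starts per fit.
#' @param seed Master seed.
#' @return A list: `confusion` (tibble generating family x winning family
#'   counts) and `recovery_rate` (per generating family, proportion of
#'   datasets won by the generating family).
#' @export
model_recovery_study <- function(families = c("bayes_rho_sigma",
                                              "bayes_delta_sigma",
                                              "rescorla_wagner"),
                                 n_datasets = 10, n_subjects = 30,
                                 session = NULL,
                                 ranges = default_param_ranges,
                                 n_starts = 10, seed = NULL) {
  session <- session %||% build_session(seed = if (is.null(seed)) NULL else
    derive_seed(seed, "task"))
  grid <- tidyr::expand_grid(generating = families,
                             dataset = seq_len(n_datasets))
  winners <- purrr::pmap_chr(grid, function(generating, dataset) {
    s <- if (is.null(seed)) NULL else {
      derive_seed(seed, paste0("mr_", generating), dataset)
    }
    truth <- with_seed(s, sample_params(generating, n_subjects, ranges))
    agents <- dplyr::bind_cols(
      tibble::tibble(subject_id = seq_len(n_subjects), family = generating),
      truth)
    behav <- simulate_agents(agents, session, seed = s)
    fits <- fit_observers(behav, families = families, n_starts = n_starts,
                          seed = s)
    compare_models(fits)$winner
  })
  grid$winner <- winners
  confusion <- grid |>
    dplyr::count(.data$generating, .data$winner, name = "n_datasets")
  recovery_rate <- grid |>
    dplyr::group_by(.data$generating) |>
    dplyr::summarise(rate = mean(.data$winner == .data$generating),
                     .groups = "drop")
  list(confusion = confusion, recovery_rate = recovery_rate)
}
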