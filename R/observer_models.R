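# Beta-binomial Bayesian observer models and the Rescorla-Wagner comparison
# model: belief updating, trajectories, and response likelihoods.
#
# The observer represents the latent blue-marble proportion as a beta
# distribution. Conjugacy with the binomial sample likelihood makes every
# posterior a beta distribution again, so a trial's belief trajectory is a
# sequence of (alpha, beta) pairs. Two behavioral deviations from the
# unbiased observer are parameterized: a prior width rho >= 1 (alpha = beta
# = rho before the first sample; larger rho = narrower prior around 0.5) and
# an evidence weight delta >= 0 (counts enter as B^delta, R^delta; delta < 1
# underweights large samples). Two choice rules map the final belief to a
# reported estimate: a truncated-normal rule centered on the posterior mean
# with free noise sigma, and a posterior-draw rule where the report is a
# draw from the final beta distribution.

OBSERVER_FAMILIES <- c(
  "bayes_rho_sigma", "bayes_delta_sigma",
  "bayes_rho_draw", "bayes_delta_draw",
  "rescorla_wagner"
)

# Free parameters and box bounds per model family. One-sided constraints
# (rho >= 1, delta >= 0) get generous upper bounds well beyond fitted values.
observer_param_info <- function(family) {
  switch(family,
    bayes_rho_sigma   = list(names = c("rho", "sigma"),
                             lower = c(1, 1e-3), upper = c(50, 1)),
    bayes_delta_sigma = list(names = c("delta", "sigma"),
                             lower = c(0, 1e-3), upper = c(5, 1)),
    bayes_rho_draw    = list(names = "rho", lower = 1, upper = 50),
    bayes_delta_draw  = list(names = "delta", lower = 0, upper = 5),
    rescorla_wagner   = list(names = c("learning_rate", "sigma"),
                             lower = c(0, 1e-3), upper = c(1, 1)),
    abort(sprintf("Unknown observer family '%s'.", family))
  )
}

#' Specify an observer model
#'
#' @param family One of `"bayes_rho_sigma"`, `"bayes_delta_sigma"`,
#'   `"bayes_rho_draw"`, `"bayes_delta_draw"`, `"rescorla_wagner"`. The
#'   `rho` families fit the prior width (evidence weight fixed at 1); the
#'   `delta` families fit the evidence weight (flat prior, rho = 1). The
#'   `sigma` families use the truncated-normal choice rule, the `draw`
#'   families report draws from the final beta distribution.
#' @param ... Named parameter values (`rho`, `delta`, `sigma`,
#'   `learning_rate`) as required by the family.
#' @return An `observer_spec` object.
#' @examples
#' observer_spec("bayes_rho_sigma", rho = 2.45, sigma = 0.10)
#' @export
observer_spec <- function(family, ...) {
  family <- match.arg(family, OBSERVER_FAMILIES)
  params <- c(...)
  info <- observer_param_info(family)
  missing <- setdiff(info$names, names(params))
  if (length(missing) > 0) {
    abort(sprintf("Family '%s' needs parameter(s): %s.",
                  family, paste(missing, collapse = ", ")))
  }
  params <- params[info$names]
  bad <- params < info$lower | params > info$upper
  if (any(bad)) {
    abort(sprintf("Parameter(s) out of bounds for '%s': %s.",
                  family, paste(info$names[bad], collapse = ", ")))
  }
  structure(list(family = family, params = params), class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("<observer_spec> ", x$family, "\n  ",
      paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

spec_param <- function(spec, name, default) {
  if (name %in% names(spec$params)) unname(spec$params[[name]]) else default
}

is_draw_family <- function(family) grepl("_draw$", family)
is_bayes_family <- function(family) grepl("^bayes_", family)

#' Beta belief states
#'
#' A belief state is a beta distribution over the latent blue-marble
#' proportion. `alpha` and `beta` may be vectors (parallel states).
#'
#' @param alpha,beta Positive beta parameters.
#' @return A `belief_state` object with fields `alpha`, `beta`.
#' @export
belief <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) abort("alpha and beta must be > 0.")
  structure(list(alpha = alpha, beta = beta), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat("<belief_state> Beta(alpha, beta), n =", length(x$alpha), "\n")
  m <- belief_moments(x)
  print(utils::head(tibble::tibble(alpha = x$alpha, beta = x$beta,
                                   mean = m$mean, variance = m$variance), 10))
  invisible(x)
}

#' Initialize the prior belief
#'
#' The symmetric prior Beta(rho, rho): rho = 1 is the flat (unbiased) prior;
#' larger rho concentrates prior belief on 0.5.
#'
#' @param rho Prior width parameter, >= 1.
#' @return A `belief_state`.
#' @export
init_belief <- function(rho = 1) {
  if (any(rho < 1)) abort("`rho` must be >= 1.")
  belief(rho, rho)
}

# 0^delta := 0 for every delta (a zero count contributes no evidence).
# Preserves matrix dimensions.
weight_count <- function(x, delta) {
  out <- x
  out[] <- 0
  nz <- x > 0
  out[nz] <- x[nz]^delta
  out
}

#' Update a belief with one sample
#'
#' Conjugate beta-binomial update with optional evidence weighting:
#' alpha' = alpha + B^delta, beta' = beta + R^delta (0^delta defined as 0).
#' `delta = 1` is exact Bayes.
#'
#' @param state A `belief_state`.
#' @param n_blue,n_red Blue and red marble counts of the sample.
#' @param delta Evidence weight, >= 0.
#' @return The updated `belief_state`.
#' @export
update_belief <- function(state, n_blue, n_red, delta = 1) {
  stopifnot(inherits(state, "belief_state"), delta >= 0)
  belief(state$alpha + weight_count(n_blue, delta),
         state$beta + weight_count(n_red, delta))
}

#' Mean and variance of a belief state
#'
#' @param state A `belief_state`.
#' @return A tibble with columns `mean` = alpha/(alpha+beta) and
#'   `variance` = alpha*beta / ((alpha+beta)^2 (alpha+beta+1)).
#' @export
belief_moments <- function(state) {
  a <- state$alpha; b <- state$beta; s <- a + b
  tibble::tibble(mean = a / s, variance = a * b / (s^2 * (s + 1)))
}

#' Belief trajectory over one trial
#'
#' Applies the prior and five successive updates, returning the belief after
#' each step. For `delta = 1` the final state depends only on the pooled
#' counts (sample order is exchangeable).
#'
#' @param spec An `observer_spec` of a Bayesian family.
#' @param draws Tibble with columns `n_blue`, `n_red`, one row per sample in
#'   presentation order.
#' @return A tibble with one row per step (0 = prior): `step`, `alpha`,
#'   `beta`, `mean`, `variance`.
#' @export
trial_trajectory <- function(spec, draws) {
  stopifnot(inherits(spec, "observer_spec"))
  if (!is_bayes_family(spec$family)) {
    abort("trial_trajectory() requires a Bayesian observer family; use rw_trajectory().")
  }
  rho <- spec_param(spec, "rho", 1)
  delta <- spec_param(spec, "delta", 1)
  state <- init_belief(rho)
  states <- vector("list", nrow(draws) + 1L)
  states[[1L]] <- state
  for (s in seq_len(nrow(draws))) {
    state <- update_belief(state, draws$n_blue[s], draws$n_red[s], delta)
    states[[s + 1L]] <- state
  }
  purrr::map2_dfr(states, seq_along(states) - 1L, function(st, step) {
    m <- belief_moments(st)
    tibble::tibble(step = step, alpha = st$alpha, beta = st$beta,
                   mean = m$mean, variance = m$variance)
  })
}

#' Rescorla-Wagner point-estimate trajectory
#'
#' Delta-rule update of a point estimate of the blue-marble proportion:
#' `R[s+1] = R[s] - lr * (R[s] - B_s / (B_s + R_s))`.
#'
#' @param learning_rate Learning rate in \[0, 1\].
#' @param draws Tibble with `n_blue`, `n_red` per sample, in order.
#' @param init Initial point estimate (0.5 by default).
#' @return Numeric vector of length `nrow(draws) + 1` (element 1 = `init`).
#' @export
rw_trajectory <- function(learning_rate, draws, init = 0.5) {
  if (learning_rate < 0 || learning_rate > 1) {
    abort("`learning_rate` must lie in [0, 1].")
  }
  est <- numeric(nrow(draws) + 1L)
  est[1L] <- init
  for (s in seq_len(nrow(draws))) {
    target <- draws$n_blue[s] / (draws$n_blue[s] + draws$n_red[s])
    est[s + 1L] <- est[s] - learning_rate * (est[s] - target)
  }
  est
}

# --- response likelihoods ---------------------------------------------------

# log density of Normal(mean, sd) truncated to [0, 1] (renormalized mass).
log_dtruncnorm01 <- function(x, mean, sd) {
  dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(1, mean, sd) - pnorm(0, mean, sd))
}

# Reported estimates live on the grid {0, 0.01, ..., 1}; the draw-rule
# likelihood is the beta probability mass of the 1/100-wide response bin
# around the grid value (half-width bins at the edges), which keeps the
# likelihood a proper probability.
log_pbeta_bin <- function(x, alpha, beta) {
  lo <- pmax(0, x - 0.005)
  hi <- pmin(1, x + 0.005)
  log(pbeta(hi, alpha, beta) - pbeta(lo, alpha, beta))
}

#' Log-likelihood of one reported estimate
#'
#' For `sigma` families (and Rescorla-Wagner) this is the log density of a
#' normal distribution truncated to \[0, 1\], centered on the model-predicted
#' estimate. For `draw` families it is the log probability of the reported
#' grid value under the final beta distribution, integrated over its
#' 1/100-wide response bin.
#'
#' @param spec An `observer_spec`.
#' @param final_state A `belief_state` (Bayesian families) or numeric point
#'   estimate (Rescorla-Wagner).
#' @param reported Reported proportion estimate(s) in \[0, 1\].
#' @return Log-likelihood, vectorized over parallel states / reports.
#' @export
response_loglik <- function(spec, final_state, reported) {
  check_proportion(reported, "reported")
  if (is_draw_family(spec$family)) {
    stopifnot(inherits(final_state, "belief_state"))
    log_pbeta_bin(reported, final_state$alpha, final_state$beta)
  } else {
    sigma <- spec_param(spec, "sigma", NA_real_)
    if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
    m <- if (inherits(final_state, "belief_state")) {
      belief_moments(final_state)$mean
    } else {
      as.numeric(final_state)
    }
    log_dtruncnorm01(reported, m, sigma)
  }
}

# --- vectorized dataset likelihood ------------------------------------------

# Precompute per-trial sample count matrices and the response vector so the
# likelihood can be evaluated thousands of times (multi-start optimization)
# as pure vectorized arithmetic.
prepare_trials <- function(data) {
  wide <- data[order(data$trial_id, data$sample_index), ]
  n_s <- max(wide$sample_index)
  ids <- unique(wide$trial_id)
  if (nrow(wide) != length(ids) * n_s) {
    abort("Every trial needs the same number of samples.")
  }
  Bmat <- matrix(wide$n_blue, ncol = n_s, byrow = TRUE)
  Rmat <- matrix(wide$n_red, ncol = n_s, byrow = TRUE)
  reported <- NULL
  if ("reported_estimate" %in% names(wide)) {
    first <- seq(1, nrow(wide), by = n_s)
    reported <- wide$reported_estimate[first]
    rep_ok <- tapply(wide$reported_estimate, wide$trial_id,
                     function(x) length(unique(x)) == 1L)
    if (!all(rep_ok)) abort("`reported_estimate` must be constant within trial.")
  }
  list(Bmat = Bmat, Rmat = Rmat, reported = reported, trial_id = ids)
}

# Fast negative log-likelihood closure over prepared trial data; `par` is
# the named parameter vector of the family.
make_negloglik_fun <- function(family, prep) {
  Bmat <- prep$Bmat; Rmat <- prep$Rmat; reported <- prep$reported
  rsB <- rowSums(Bmat); rsR <- rowSums(Rmat)
  switch(family,
    bayes_rho_sigma = function(par) {
      a <- par[["rho"]] + rsB; b <- par[["rho"]] + rsR
      -sum(log_dtruncnorm01(reported, a / (a + b), par[["sigma"]]))
    },
    bayes_rho_draw = function(par) {
      -sum(log_pbeta_bin(reported, par[["rho"]] + rsB, par[["rho"]] + rsR))
    },
    bayes_delta_sigma = function(par) {
      a <- 1 + rowSums(weight_count(Bmat, par[["delta"]]))
      b <- 1 + rowSums(weight_count(Rmat, par[["delta"]]))
      -sum(log_dtruncnorm01(reported, a / (a + b), par[["sigma"]]))
    },
    bayes_delta_draw = function(par) {
      a <- 1 + rowSums(weight_count(Bmat, par[["delta"]]))
      b <- 1 + rowSums(weight_count(Rmat, par[["delta"]]))
      -sum(log_pbeta_bin(reported, a, b))
    },
    rescorla_wagner = function(par) {
      est <- rep(0.5, nrow(Bmat))
      lr <- par[["learning_rate"]]
      for (s in seq_len(ncol(Bmat))) {
        est <- est - lr * (est - Bmat[, s] / (Bmat[, s] + Rmat[, s]))
      }
      -sum(log_dtruncnorm01(reported, est, par[["sigma"]]))
    }
  )
}

# Final model prediction for every trial of a long behavior table (columns
# trial_id, sample_index, n_blue, n_red). Returns a tibble keyed by trial_id
# with the final belief (Bayes) or point estimate (RW).
final_predictions <- function(spec, trials) {
  ids <- sort(unique(trials$trial_id))
  if (is_bayes_family(spec$family)) {
    rho <- spec_param(spec, "rho", 1)
    delta <- spec_param(spec, "delta", 1)
    fb <- rowsum(weight_count(trials$n_blue, delta), trials$trial_id)
    fr <- rowsum(weight_count(trials$n_red, delta), trials$trial_id)
    ord <- match(ids, as.numeric(rownames(fb)))
    tibble::tibble(trial_id = ids,
                   alpha = rho + fb[ord, 1L],
                   beta = rho + fr[ord, 1L])
  } else {
    lr <- spec_param(spec, "learning_rate", NA_real_)
    wide <- trials |>
      dplyr::arrange(.data$trial_id, .data$sample_index)
    n_s <- max(wide$sample_index)
    bm <- matrix(wide$n_blue, ncol = n_s, byrow = TRUE)
    rm_ <- matrix(wide$n_red, ncol = n_s, byrow = TRUE)
    est <- rep(0.5, nrow(bm))
    for (s in seq_len(n_s)) {
      est <- est - lr * (est - bm[, s] / (bm[, s] + rm_[, s]))
    }
    tibble::tibble(trial_id = ids, point = est)
  }
}

#' Negative log-likelihood of a behavioral dataset
#'
#' Sum of per-trial response negative log-likelihoods under an observer
#' specification. Trials flagged invalid (missing responses) must be removed
#' upstream.
#'
#' @param spec An `observer_spec`.
#' @param data Long tibble with one row per (trial, sample): `trial_id`,
#'   `sample_index`, `n_blue`, `n_red`, and a per-trial `reported_estimate`
#'   (constant within trial).
#' @return The negative log-likelihood (finite for valid parameters).
#' @export
dataset_negloglik <- function(spec, data) {
  if (nrow(data) == 0) abort("`data` has no trials.")
  prep <- prepare_trials(data)
  make_negloglik_fun(spec$family, prep)(spec$params)
}

#' Posterior mean / variance trajectories of the unbiased observer
#'
#' Computes, for every (trial, sample) of a session, the posterior mean and
#' variance after that sample under a Bayesian observer (flat prior and
#' exact updating by default). The posterior variance trajectory is the
#' uncertainty modulator used by the parametric GLM and by the synthetic
#' BOLD generator.
#'
#' @param session Session tibble from [build_session()] (or any long table
#'   with `trial_id`, `sample_index`, `n_blue`, `n_red`).
#' @param rho Prior width (1 = flat prior).
#' @param delta Evidence weight (1 = exact Bayes).
#' @return The input rows with `post_mean`, `post_var` and `prior_var`
#'   columns appended.
#' @export
uncertainty_trajectories <- function(session, rho = 1, delta = 1) {
  out <- session |>
    dplyr::arrange(.data$trial_id, .data$sample_index) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(
      .alpha = rho + cumsum(weight_count(.data$n_blue, delta)),
      .beta = rho + cumsum(weight_count(.data$n_red, delta))
    ) |>
    dplyr::ungroup()
  s <- out$.alpha + out$.beta
  out$post_mean <- out$.alpha / s
  out$post_var <- out$.alpha * out$.beta / (s^2 * (s + 1))
  out$prior_var <- rho * rho / ((2 * rho)^2 * (2 * rho + 1))
  out$.alpha <- NULL
  out$.beta <- NULL
  out
}

#' Plot the belief trajectory of an observer over one trial
#'
#' Shows the belief mean and its central 95% band after each sample.
#'
#' @param object An `observer_spec`.
#' @param draws Tibble of per-sample `n_blue`, `n_red` in order.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot observer_spec
#' @export
autoplot.observer_spec <- function(object, draws, ...) {
  traj <- trial_trajectory(object, draws)
  traj$lo <- qbeta(0.025, traj$alpha, traj$beta)
  traj$hi <- qbeta(0.975, traj$alpha, traj$beta)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$step, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample", y = "belief about p(blue)") +
    ggplot2::ylim(0, 1)
}
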