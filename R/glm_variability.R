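# Event-related GLM machinery: double-gamma HRF basis, design matrices,
# least-squares-single (LS-S) trial betas, SD-BOLD maps and their change,
# condition-mean and parametric-uncertainty GLMs.

#' Canonical HRF basis
#'
#' The canonical double-gamma hemodynamic response (gamma densities with
#' shape 6 and 16, rate 1, undershoot ratio 1/6) plus its temporal
#' derivative and dispersion derivative, sampled on a time grid of step
#' `dt`. Each basis function is normalized to unit peak absolute value.
#'
#' @param dt Sampling step in seconds (e.g. the TR, or a finer microtime
#'   grid used before downsampling).
#' @param length_s Support of the response in seconds (32 by default).
#' @return A matrix with columns `canonical`, `temporal_deriv`,
#'   `dispersion_deriv` and one row per grid point (time `(0:n) * dt`).
#' @export
hrf_basis <- function(dt, length_s = 32) {
  stopifnot(dt > 0)
  t <- seq(0, length_s, by = dt)
  dgamma_hrf <- function(t, a1 = 6, a2 = 16, b = 1, ratio = 1 / 6) {
    stats::dgamma(t, shape = a1, rate = b) -
      ratio * stats::dgamma(t, shape = a2, rate = b)
  }
  h <- dgamma_hrf(t)
  # temporal derivative: finite difference over a 0.1 s onset shift
  td <- (h - dgamma_hrf(pmax(t - 0.1, 0))) / 0.1
  # dispersion derivative: finite difference in the rate parameter
  dd <- (h - dgamma_hrf(t, b = 1.01)) / 0.01
  basis <- cbind(canonical = h, temporal_deriv = td, dispersion_deriv = dd)
  sweep(basis, 2, apply(abs(basis), 2, max), "/")
}

# Convolve a set of events (onsets/durations, unit or modulated amplitude)
# with an HRF basis on an oversampled grid, then sample at scan times.
# Event sticks are sparse, so the convolution is done by accumulating
# shifted copies of the basis kernels (much faster than an FFT here).
# Returns an n_scans x ncol(basis) matrix.
convolve_events <- function(onsets, durations, tr, n_scans,
                            amplitudes = NULL, oversample = 16,
                            basis = NULL) {
  amplitudes <- amplitudes %||% rep(1, length(onsets))
  dt <- tr / oversample
  n_fine <- n_scans * oversample
  if (any(floor(onsets / dt) + 1L > n_fine)) {
    abort("Event onset past the end of the run.")
  }
  basis <- basis %||% hrf_basis(dt)
  nb <- nrow(basis)
  # one boxcar-convolved kernel per distinct duration, then one shifted
  # add per event
  kernels <- list()
  out_fine <- matrix(0, n_fine + nb + max(1L, round(max(durations) / dt)),
                     ncol(basis))
  for (i in seq_along(onsets)) {
    from <- floor(onsets[i] / dt) + 1L
    len <- max(1L, round(durations[i] / dt))
    key <- as.character(len)
    if (is.null(kernels[[key]])) {
      k <- matrix(0, nb + len - 1L, ncol(basis))
      for (j in seq_len(len)) {
        k[j:(j + nb - 1L), ] <- k[j:(j + nb - 1L), ] + basis
      }
      kernels[[key]] <- k
    }
    k <- kernels[[key]]
    idx <- from:(from + nrow(k) - 1L)
    out_fine[idx, ] <- out_fine[idx, ] + amplitudes[i] * k
  }
  scan_idx <- (seq_len(n_scans) - 1L) * oversample + 1L
  out_fine[scan_idx, , drop = FALSE]
}

#' Build a run design matrix
#'
#' One stick/boxcar regressor per condition, convolved with the canonical
#' HRF and its two derivatives (3 columns per condition), plus a run
#' constant. With the seven task conditions (five sample periods,
#' estimation, gambling) this yields the 21-regressor-plus-constant layout.
#'
#' @param events Event tibble for one run: `onset`, `duration`,
#'   `trial_type`.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes in the run.
#' @param oversample Microtime oversampling factor.
#' @return A `design_matrix`: numeric matrix (n_scans x columns) with
#'   attributes `conditions` and column names `<condition>.<basis>`.
#' @export
build_design <- function(events, tr, n_scans, oversample = 16) {
  if (any(events$onset >= n_scans * tr)) {
    abort("Event onsets extend past the end of the run.")
  }
  conds <- unique(events$trial_type)
  empty <- setdiff(conds, events$trial_type)
  if (length(empty) > 0) {
    warn(paste("Conditions without events omitted:",
               paste(empty, collapse = ", ")))
    conds <- setdiff(conds, empty)
  }
  basis <- hrf_basis(tr / oversample)
  cols <- lapply(conds, function(cc) {
    ev <- events[events$trial_type == cc, ]
    convolve_events(ev$onset, ev$duration, tr, n_scans,
                    oversample = oversample, basis = basis)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- as.vector(outer(colnames(basis), conds,
                                 function(b, cc) paste(cc, b, sep = ".")))
  X <- cbind(X, constant = 1)
  structure(X, conditions = conds, class = c("design_matrix", class(X)))
}

# Per-event convolved 3-basis regressors for one run, cached: every subject
# of a simulated study shares the same session, so the (identical) event
# regressors are computed once per run rather than once per subject.
.regressor_cache <- new.env(parent = emptyenv())

event_regressors <- function(events, tr, n_scans, oversample = 16) {
  key <- paste(c(n_scans, tr, oversample, round(events$onset, 4),
                 round(events$duration, 4)), collapse = ",")
  hit <- .regressor_cache[[key]]
  if (!is.null(hit)) return(hit)
  basis <- hrf_basis(tr / oversample)
  E <- lapply(seq_len(nrow(events)), function(i) {
    convolve_events(events$onset[i], events$duration[i], tr, n_scans,
                    oversample = oversample, basis = basis)
  })
  out <- list(E = E, total = Reduce(`+`, E))
  if (length(ls(.regressor_cache)) > 30) {
    rm(list = ls(.regressor_cache), envir = .regressor_cache)
  }
  .regressor_cache[[key]] <- out
  out
}

# OLS betas for Y (n_scans x n_vox) on X; returns coefficients (p x n_vox).
ols_betas <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) abort("Singular design matrix.")
  qr.coef(qr_x, Y)
}

#' Least-squares-single trial betas
#'
#' For each event of `condition`, fits a GLM with two event regressors: the
#' single event and the pooled set of all other events (of every
#' condition), each convolved with the 3-function HRF basis, plus a run
#' constant (7 columns). The single event's canonical-HRF beta is retained.
#' Events with onsets in the final `prune_tail_s` seconds of the run are
#' not estimated (HRF truncation) but still contribute to the pooled
#' regressor.
#'
#' @param bold Numeric matrix, n_scans x n_voxels.
#' @param events Event tibble for the run (`onset`, `duration`,
#'   `trial_type`, `trial_id`).
#' @param condition The `trial_type` whose trials are estimated.
#' @param tr Repetition time, seconds.
#' @param prune_tail_s Tail window whose onsets are discarded (20 s).
#' @param oversample Microtime oversampling factor.
#' @return A `trial_beta_matrix`: list with `condition`, `betas` (retained
#'   trials x voxels, canonical betas), `trial_id`.
#' @export
lss_betas <- function(bold, events, condition, tr, prune_tail_s = 20,
                      oversample = 16) {
  lss_betas_run(bold, events, tr, conditions = condition,
                prune_tail_s = prune_tail_s, oversample = oversample)[[1L]]
}

#' @rdname lss_betas
#' @param conditions Character vector of conditions to estimate in one pass
#'   (the per-event regressors are shared, so estimating all conditions of
#'   a run together is much cheaper than repeated [lss_betas()] calls).
#'   Defaults to every condition with >= 2 estimable events.
#' @return `lss_betas_run()`: a named list of `trial_beta_matrix`, one per
#'   condition.
#' @export
lss_betas_run <- function(bold, events, tr, conditions = NULL,
                          prune_tail_s = 20, oversample = 16) {
  n_scans <- nrow(bold)
  limit <- n_scans * tr - prune_tail_s
  reg <- event_regressors(events, tr, n_scans, oversample)
  E <- reg$E
  total <- reg$total
  conditions <- conditions %||% grep("^sample_", unique(events$trial_type),
                                     value = TRUE)
  out <- lapply(conditions, function(condition) {
    target <- which(events$trial_type == condition & events$onset < limit)
    if (length(target) < 2) {
      abort(sprintf("Fewer than 2 estimable '%s' events in this run.",
                    condition))
    }
    betas <- matrix(NA_real_, length(target), ncol(bold))
    for (k in seq_along(target)) {
      i <- target[k]
      X <- cbind(E[[i]], total - E[[i]], constant = 1)
      b <- tryCatch(ols_betas(X, bold), error = function(e) {
        abort(sprintf("Singular LS-S design at trial_id %s (onset %.1f s).",
                      events$trial_id[i], events$onset[i]))
      })
      betas[k, ] <- b[1L, ] # canonical beta of the single event
    }
    structure(list(condition = condition, betas = betas,
                   trial_id = events$trial_id[target]),
              class = "trial_beta_matrix")
  })
  names(out) <- conditions
  out
}

#' Design-implied noise scale of LS-S betas per condition
#'
#' The sampling variance of an LS-S single-event beta under white scan
#' noise is `c_i * sigma^2` with `c_i = [(X_i' X_i)^{-1}]_{11}` computable
#' from the design alone. Because event context differs systematically
#' across sample periods (e.g. the final sample always neighbors the
#' estimation phase), `c_i` has a period-specific profile that imprints on
#' raw SD estimates even in voxels with no amplitude variability. This
#' function returns the per-condition noise SD multiplier
#' `sqrt(mean(c_i))`; dividing an [sd_bold()] map's rows by it yields
#' noise-calibrated SDs suitable for testing per-voxel change against a
#' flat null.
#'
#' @inheritParams lss_betas
#' @return A named numeric vector: one multiplier per condition.
#' @export
lss_noise_scale <- function(events, tr, n_scans, conditions = NULL,
                            prune_tail_s = 20, oversample = 16) {
  limit <- n_scans * tr - prune_tail_s
  reg <- event_regressors(events, tr, n_scans, oversample)
  E <- reg$E
  total <- reg$total
  conditions <- conditions %||% grep("^sample_", unique(events$trial_type),
                                     value = TRUE)
  out <- vapply(conditions, function(condition) {
    target <- which(events$trial_type == condition & events$onset < limit)
    ci <- vapply(target, function(i) {
      X <- cbind(E[[i]], total - E[[i]], constant = 1)
      solve(crossprod(X))[1L, 1L]
    }, numeric(1))
    sqrt(mean(ci))
  }, numeric(1))
  names(out) <- conditions
  out
}

#' Across-trial SD of trial betas (SD-BOLD)
#'
#' Pools trial betas across runs per condition and computes, per voxel, the
#' sample standard deviation (n - 1 denominator) across trials.
#'
#' @param beta_list A list of `trial_beta_matrix` objects (possibly several
#'   runs per condition).
#' @return An `sdbold_map`: list with `sd` (condition x voxel matrix, rows
#'   ordered by condition name) and `n_trials` per condition.
#' @export
sd_bold <- function(beta_list) {
  conds <- vapply(beta_list, `[[`, character(1), "condition")
  by_cond <- split(beta_list, conds)
  cond_names <- sort(names(by_cond))
  rows <- lapply(cond_names, function(cc) {
    betas <- do.call(rbind, lapply(by_cond[[cc]], `[[`, "betas"))
    if (nrow(betas) < 2) abort("Need >= 2 trials per condition for an SD.")
    apply(betas, 2, sd)
  })
  sd <- do.call(rbind, rows)
  rownames(sd) <- cond_names
  n_trials <- vapply(cond_names, function(cc) {
    sum(vapply(by_cond[[cc]], function(b) nrow(b$betas), integer(1)))
  }, integer(1))
  structure(list(sd = sd, n_trials = n_trials), class = "sdbold_map")
}

#' Change in SD-BOLD across sample periods
#'
#' Per voxel, the least-squares slope of SD-BOLD over the ordered sample
#' periods (1...S), with its standard error, t statistic and two-sided p
#' value (from the residual t distribution with S - 2 df).
#'
#' @param map An `sdbold_map` (or a condition x voxel matrix with ordered
#'   rows).
#' @return A tibble with one row per voxel: `voxel`, `slope`, `se`, `t`,
#'   `p_value`.
#' @export
sdbold_change <- function(map) {
  sd <- if (inherits(map, "sdbold_map")) map$sd else map
  s <- seq_len(nrow(sd))
  xc <- s - mean(s)
  sxx <- sum(xc^2)
  slope <- drop(crossprod(xc, sd)) / sxx
  fitted <- outer(xc, slope) + matrix(colMeans(sd), nrow(sd), ncol(sd),
                                      byrow = TRUE)
  rss <- colSums((sd - fitted)^2)
  df <- nrow(sd) - 2
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  tibble::tibble(voxel = seq_along(slope), slope = slope, se = se, t = tval,
                 p_value = 2 * pt(-abs(tval), df))
}

#' Whole-run condition-mean GLM
#'
#' Multi-condition GLM per run with the full 3-basis design; returns the
#' canonical beta per condition and voxel, averaged across runs (the
#' across-run contrast used to summarize condition effects).
#'
#' @param bold_list List of n_scans x n_voxels matrices (one per run).
#' @param events_list List of event tibbles, parallel to `bold_list`.
#' @param tr Repetition time, seconds.
#' @param oversample Microtime oversampling factor.
#' @return A condition x voxel matrix of mean canonical betas.
#' @export
condition_mean_glm <- function(bold_list, events_list, tr, oversample = 16) {
  per_run <- purrr::map2(bold_list, events_list, function(bold, events) {
    X <- build_design(events, tr, nrow(bold), oversample = oversample)
    b <- ols_betas(X, bold)
    conds <- attr(X, "conditions")
    canon <- b[paste(conds, "canonical", sep = "."), , drop = FALSE]
    rownames(canon) <- conds
    canon
  })
  conds <- sort(Reduce(intersect, lapply(per_run, rownames)))
  Reduce(`+`, lapply(per_run, function(m) m[conds, , drop = FALSE])) /
    length(per_run)
}

#' Polynomial change coefficient across ordered conditions
#'
#' Orthogonal-polynomial coefficient (linear, quadratic or cubic) of a
#' condition x voxel matrix over the ordered conditions, per voxel. Used to
#' quantify e.g. the cubic MEAN-BOLD change across the five sample periods.
#'
#' @param cond_betas Condition x voxel matrix with ordered rows.
#' @param degree 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return Numeric vector of per-voxel coefficients.
#' @export
condition_poly_coef <- function(cond_betas, degree = 3) {
  n <- nrow(cond_betas)
  stopifnot(degree >= 1, degree <= n - 1)
  w <- contr.poly(n)[, degree]
  drop(crossprod(w, cond_betas))
}

#' Parametric uncertainty GLM
#'
#' Design per run: one pooled sample-onset regressor, its parametric
#' modulation by trial-wise posterior variance (mean-centered before
#' convolution), the estimation regressor and the gambling nuisance
#' regressor, each convolved with the 3-function basis (12 regressors),
#' plus a run constant. Returns the canonical beta of the modulation
#' regressor per voxel, averaged across runs.
#'
#' @param bold_list List of n_scans x n_voxels run matrices.
#' @param events_list List of run event tibbles.
#' @param modulator_list List of numeric vectors: one posterior-variance
#'   value per sample event of the run (in event-row order of the sample
#'   events of that run).
#' @param tr Repetition time, seconds.
#' @param oversample Microtime oversampling factor.
#' @return Numeric vector: per-voxel mean canonical modulation beta.
#' @export
parametric_uncertainty_glm <- function(bold_list, events_list,
                                       modulator_list, tr, oversample = 16) {
  per_run <- purrr::pmap(list(bold_list, events_list, modulator_list),
                         function(bold, events, modulator) {
    n_scans <- nrow(bold)
    basis <- hrf_basis(tr / oversample)
    is_sample <- grepl("^sample_", events$trial_type)
    smp <- events[is_sample, ]
    if (length(modulator) != nrow(smp)) {
      abort("Need one modulator value per sample event.")
    }
    mod <- modulator - mean(modulator)
    if (all(mod == 0)) {
      warn("Constant modulator: the mean-centered regressor is all zero.")
    }
    Xs <- convolve_events(smp$onset, smp$duration, tr, n_scans,
                          oversample = oversample, basis = basis)
    Xm <- convolve_events(smp$onset, smp$duration, tr, n_scans,
                          amplitudes = mod, oversample = oversample,
                          basis = basis)
    other <- lapply(c("estimation", "gambling"), function(cc) {
      ev <- events[events$trial_type == cc, ]
      if (nrow(ev) == 0) return(NULL)
      convolve_events(ev$onset, ev$duration, tr, n_scans,
                      oversample = oversample, basis = basis)
    })
    X <- do.call(cbind, c(list(Xs, Xm), Filter(Negate(is.null), other)))
    X <- cbind(X, constant = 1)
    b <- ols_betas(X, bold)
    b[4L, ] # canonical beta of the modulation regressor
  })
  Reduce(`+`, per_run) / length(per_run)
}

#' Split-half reliability of SD-BOLD
#'
#' Computes SD-BOLD separately over the first and second half of trials
#' (by trial order) of each condition and correlates the two voxel-wise
#' maps.
#'
#' @param beta_list List of `trial_beta_matrix` objects.
#' @return A tibble per condition: `condition`, `r` (across-voxel Pearson
#'   correlation of first-half and second-half SDs).
#' @export
split_half_reliability <- function(beta_list) {
  conds <- vapply(beta_list, `[[`, character(1), "condition")
  by_cond <- split(beta_list, conds)
  purrr::map_dfr(names(by_cond), function(cc) {
    betas <- do.call(rbind, lapply(by_cond[[cc]], `[[`, "betas"))
    ord <- order(unlist(lapply(by_cond[[cc]], `[[`, "trial_id")))
    betas <- betas[ord, , drop = FALSE]
    n <- nrow(betas)
    if (n < 4) abort("Need >= 4 trials for split-half reliability.")
    h1 <- seq_len(floor(n / 2))
    sd1 <- apply(betas[h1, , drop = FALSE], 2, sd)
    sd2 <- apply(betas[-h1, , drop = FALSE], 2, sd)
    tibble::tibble(condition = cc, r = cor(sd1, sd2))
  })
}

#' @export
print.sdbold_map <- function(x, ...) {
  cat("<sdbold_map> ", nrow(x$sd), " conditions x ", ncol(x$sd), " voxels\n",
      sep = "")
  print(tibble::tibble(condition = rownames(x$sd),
                       n_trials = unname(x$n_trials),
                       median_sd = apply(x$sd, 1, median)))
  invisible(x)
}

#' Plot the distribution of SD-BOLD across voxels per sample period
#'
#' @param object An `sdbold_map`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot sdbold_map
#' @export
autoplot.sdbold_map <- function(object, ...) {
  sd <- object$sd
  colnames(sd) <- paste0("v", seq_len(ncol(sd)))
  df <- tibble::as_tibble(sd, rownames = "condition") |>
    tidyr::pivot_longer(-"condition", names_to = "voxel", values_to = "sd")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$sd)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "across-trial SD of trial betas")
}
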