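# Task and behavioral partial least squares with permutation significance,
# bootstrap salience ratios, cluster thresholding, and the rank-based
# latent regressions built on brain scores.

new_pls_result <- function(kind, d, saliences, weights, brain_scores,
                           behavior_scores = NULL, latent_cor = NULL,
                           data = list()) {
  structure(list(kind = kind, singular_values = d, saliences = saliences,
                 weights = weights, brain_scores = brain_scores,
                 behavior_scores = behavior_scores, latent_cor = latent_cor,
                 p_perm = NULL, bsr = NULL, data = data),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> ", x$kind, " PLS: ", length(x$singular_values),
      " latent variable(s)\n", sep = "")
  df <- tibble::tibble(lv = seq_along(x$singular_values),
                       singular_value = x$singular_values)
  if (!is.null(x$latent_cor)) df$latent_cor <- x$latent_cor
  if (!is.null(x$p_perm)) df$p_perm <- x$p_perm
  print(df)
  invisible(x)
}

#' @export
tidy.pls_result <- function(x, ...) {
  tibble::tibble(lv = seq_along(x$singular_values),
                 singular_value = x$singular_values,
                 prop_covariance = x$singular_values^2 /
                   sum(x$singular_values^2),
                 latent_cor = x$latent_cor %||% NA_real_,
                 p_perm = x$p_perm %||% NA_real_)
}

#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_lv = length(x$singular_values),
                 first_sv = x$singular_values[1L],
                 first_p_perm = (x$p_perm %||% NA_real_)[1L])
}

# mean-centered condition x voxel matrix for task PLS
task_pls_matrix <- function(brain) {
  centered <- sweep(brain, c(1, 3), apply(brain, c(1, 3), mean))
  apply(centered, c(2, 3), mean)
}

#' Task PLS of condition-wise brain measures
#'
#' Mean-centered task PLS: each subject's condition x voxel matrix is
#' centered on the subject's per-voxel grand mean, the group average of
#' the centered matrices is decomposed by SVD, and latent variables carry
#' condition weights and voxel saliences. Brain scores are the dot product
#' of a subject's (uncentered) condition rows with the saliences.
#'
#' @param brain Numeric array, subject x condition x voxel (>= 2
#'   conditions, >= 3 subjects).
#' @return A `pls_result` with `singular_values`, `weights` (condition x
#'   LV), `saliences` (voxel x LV), and `brain_scores` (subject x condition
#'   x LV array).
#' @export
task_pls <- function(brain) {
  stopifnot(length(dim(brain)) == 3)
  if (dim(brain)[2] < 2) abort("Task PLS needs >= 2 conditions.")
  if (dim(brain)[1] < 3) abort("Task PLS needs >= 3 subjects.")
  M <- task_pls_matrix(brain)
  sv <- svd(M)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  idx <- seq_len(max(k, 1L))
  scores <- array(NA_real_, c(dim(brain)[1:2], length(idx)))
  for (l in idx) {
    scores[, , l] <- apply(brain, 1, function(x) x %*% sv$v[, l]) |> t()
  }
  new_pls_result("task", sv$d[idx], sv$v[, idx, drop = FALSE],
                 sv$u[, idx, drop = FALSE], scores,
                 data = list(brain = brain))
}

# cross-block correlation (or covariance) matrix for behavioral PLS
behavioral_pls_matrix <- function(brain, behavior, standardize = TRUE) {
  if (standardize) {
    cor(behavior, brain)
  } else {
    crossprod(scale(behavior, scale = FALSE),
              scale(brain, scale = FALSE)) / (nrow(brain) - 1)
  }
}

#' Behavioral PLS of brain-behavior covariance
#'
#' Decomposes the behavior x voxel cross-correlation matrix by SVD. By
#' default both blocks are column-wise rank-transformed first (average
#' ranks for ties) so latent relationships are monotone rather than
#' strictly linear, and the latent correlation is Spearman-type.
#'
#' @param brain Numeric matrix, subject x voxel.
#' @param behavior Numeric vector or subject x variable matrix.
#' @param rank Rank-transform both blocks first (default TRUE).
#' @param standardize Use correlations (TRUE, default) rather than
#'   covariances for the cross-block matrix.
#' @return A `pls_result` with voxel `saliences`, behavior `weights`,
#'   per-subject `brain_scores` and `behavior_scores` (subject x LV), and
#'   the per-LV `latent_cor` between them.
#' @export
behavioral_pls <- function(brain, behavior, rank = TRUE, standardize = TRUE) {
  behavior <- as.matrix(behavior)
  if (nrow(behavior) != nrow(brain)) abort("Subject counts differ.")
  if (nrow(brain) < 4) abort("Behavioral PLS needs >= 4 subjects.")
  if (any(apply(behavior, 2, sd) == 0)) abort("Constant behavior column.")
  Xr <- if (rank) rank_columns(brain) else brain
  Yr <- if (rank) as.matrix(rank_columns(behavior)) else behavior
  R <- behavioral_pls_matrix(Xr, Yr, standardize = standardize)
  sv <- svd(R)
  k <- max(1L, sum(sv$d > max(sv$d) * 1e-12))
  idx <- seq_len(k)
  brain_scores <- Xr %*% sv$v[, idx, drop = FALSE]
  behavior_scores <- Yr %*% sv$u[, idx, drop = FALSE]
  latent_cor <- vapply(idx, function(l) {
    cor(brain_scores[, l], behavior_scores[, l])
  }, numeric(1))
  new_pls_result("behavior", sv$d[idx], sv$v[, idx, drop = FALSE],
                 sv$u[, idx, drop = FALSE], brain_scores, behavior_scores,
                 latent_cor,
                 data = list(brain = Xr, behavior = Yr, rank = rank,
                             standardize = standardize))
}

pls_singular_values <- function(pls, k) {
  if (pls$kind == "task") {
    svd(task_pls_matrix(pls$data$brain), nu = 0, nv = 0)$d[seq_len(k)]
  } else {
    svd(behavioral_pls_matrix(pls$data$brain, pls$data$behavior,
                              pls$data$standardize), nu = 0, nv = 0)$d[seq_len(k)]
  }
}

#' Permutation test for PLS latent variables
#'
#' Behavioral PLS: subject rows of the behavior block are permuted against
#' the brain block. Task PLS: condition labels are permuted within subject.
#' Each LV's p value is the proportion of permuted singular values (of the
#' same rank order) at or above the observed one, with the (b + 1)/(B + 1)
#' correction so p is never exactly zero.
#'
#' @param pls A `pls_result`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return The `pls_result` with `p_perm` filled in.
#' @export
permutation_test <- function(pls, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(pls, "pls_result"))
  if (n_perm < 100) abort("Use at least 100 permutations.")
  k <- length(pls$singular_values)
  obs <- pls$singular_values
  with_seed(seed, {
    exceed <- numeric(k)
    if (pls$kind == "behavior") {
      X <- pls$data$brain
      Y <- pls$data$behavior
      n <- nrow(X)
      for (b in seq_len(n_perm)) {
        dp <- svd(behavioral_pls_matrix(X, Y[sample.int(n), , drop = FALSE],
                                        pls$data$standardize),
                  nu = 0, nv = 0)$d[seq_len(k)]
        exceed <- exceed + (dp >= obs)
      }
    } else {
      brain <- pls$data$brain
      n_sub <- dim(brain)[1]; n_cond <- dim(brain)[2]
      for (b in seq_len(n_perm)) {
        perm <- brain
        for (s in seq_len(n_sub)) {
          perm[s, , ] <- brain[s, sample.int(n_cond), ]
        }
        dp <- svd(task_pls_matrix(perm), nu = 0, nv = 0)$d[seq_len(k)]
        exceed <- exceed + (dp >= obs)
      }
    }
    pls$p_perm <- (exceed + 1) / (n_perm + 1)
    pls
  })
}

#' Bootstrap salience ratios
#'
#' Subjects are resampled with replacement, the PLS is re-estimated, each
#' resample's saliences are sign-aligned to the original LV (by the sign of
#' their dot product), and the bootstrap standard error of each voxel's
#' salience is accumulated. The bootstrap salience ratio (BSR) is the
#' original salience divided by this SE; `abs(BSR) > threshold` (3, roughly
#' a 99.9% confidence criterion) marks robust voxels.
#'
#' @param pls A `pls_result`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param threshold BSR threshold for the robust-voxel mask.
#' @param seed Optional integer seed.
#' @return The `pls_result` with `bsr` (voxel x LV matrix) and
#'   `bsr_mask` (logical, same shape) filled in; degenerate resamples
#'   (a single unique subject) are skipped and counted in `n_boot_used`.
#' @export
bootstrap_bsr <- function(pls, n_boot = 1000, threshold = 3, seed = NULL) {
  stopifnot(inherits(pls, "pls_result"))
  if (n_boot < 100) abort("Use at least 100 bootstrap resamples.")
  k <- length(pls$singular_values)
  n_vox <- nrow(pls$saliences)
  n_sub <- if (pls$kind == "task") dim(pls$data$brain)[1] else
    nrow(pls$data$brain)
  with_seed(seed, {
    acc <- matrix(0, n_vox, k); acc2 <- matrix(0, n_vox, k); used <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_sub, replace = TRUE)
      if (length(unique(idx)) < 2) next
      Vb <- tryCatch({
        if (pls$kind == "task") {
          svd(task_pls_matrix(pls$data$brain[idx, , , drop = FALSE]))$v
        } else {
          svd(behavioral_pls_matrix(pls$data$brain[idx, , drop = FALSE],
                                    pls$data$behavior[idx, , drop = FALSE],
                                    pls$data$standardize))$v
        }
      }, error = function(e) NULL)
      if (is.null(Vb) || ncol(Vb) < k) next
      for (l in seq_len(k)) {
        v <- Vb[, l] * sign(sum(Vb[, l] * pls$saliences[, l]))
        acc[, l] <- acc[, l] + v
        acc2[, l] <- acc2[, l] + v^2
      }
      used <- used + 1L
    }
    if (used < 2) abort("Bootstrap degenerate: fewer than 2 usable resamples.")
    se <- sqrt(pmax(0, (acc2 - acc^2 / used) / (used - 1)))
    bsr <- pls$saliences / se
    bsr[se == 0] <- sign(pls$saliences[se == 0]) * Inf
    pls$bsr <- bsr
    pls$bsr_mask <- abs(bsr) > threshold
    pls$n_boot_used <- used
    pls
  })
}

#' Map mask-voxel values into a 3-D volume
#'
#' @param values Numeric vector, one value per mask voxel of `layout`.
#' @param layout A `voxel_layout`.
#' @param fill Background value outside the mask.
#' @return A 3-D array of dimension `layout$dim`.
#' @export
volume_from_mask <- function(values, layout, fill = 0) {
  vol <- array(fill, layout$dim)
  vol[layout$mask] <- values
  vol
}

#' Cluster-threshold a robust-voxel mask
#'
#' Labels 6-connected (face-adjacent) components of a 3-D logical mask and
#' removes components smaller than `min_size` voxels.
#'
#' @param mask 3-D logical array (e.g. `abs(BSR) > 3` mapped through
#'   [volume_from_mask()]).
#' @param min_size Minimum cluster extent in voxels (25 by default).
#' @param values Optional 3-D numeric array (e.g. BSR) used to report each
#'   cluster's peak.
#' @return A list: `mask` (the thresholded logical array) and `clusters`
#'   (tibble with `cluster_id`, `size`, peak coordinates `x`, `y`, `z`, and
#'   `peak_value` when `values` is given).
#' @export
cluster_threshold <- function(mask, min_size = 25, values = NULL) {
  stopifnot(length(dim(mask)) == 3)
  dims <- dim(mask)
  labels <- array(0L, dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  next_id <- 0L
  todo <- which(mask & labels == 0L)
  for (start in todo) {
    if (labels[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    labels[start] <- next_id
    while (length(queue) > 0) {
      v <- queue[[1L]]; queue <- queue[-1L]
      co <- arrayInd(v, dims)
      for (j in seq_len(6)) {
        cn <- co + nb[j, ]
        if (any(cn < 1) || any(cn > dims)) next
        li <- cn[1] + dims[1] * (cn[2] - 1) + dims[1] * dims[2] * (cn[3] - 1)
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- next_id
          queue <- c(queue, li)
        }
      }
    }
  }
  sizes <- tabulate(labels[labels > 0L], nbins = next_id)
  keep <- which(sizes >= min_size)
  out_mask <- array(labels %in% keep, dims)
  clusters <- purrr::map_dfr(seq_along(keep), function(i) {
    id <- keep[i]
    vox <- which(labels == id)
    peak <- if (is.null(values)) vox[1L] else vox[which.max(abs(values[vox]))]
    co <- arrayInd(peak, dims)
    tibble::tibble(cluster_id = i, size = sizes[id],
                   x = co[1], y = co[2], z = co[3],
                   peak_value = if (is.null(values)) NA_real_ else values[peak])
  })
  list(mask = out_mask, clusters = clusters)
}

#' Flag multivariate outliers by Cook's distance
#'
#' Fits a least-squares regression of `y` on the columns of `x` and flags
#' observations with Cook's distance above `4/n`.
#'
#' @param x Numeric vector, matrix or data frame of predictors.
#' @param y Numeric outcome.
#' @param threshold Cutoff; defaults to `4 / length(y)`.
#' @return Integer indices of flagged observations.
#' @export
cooks_screen <- function(x, y, threshold = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  if (n <= ncol(x) + 1) abort("Need n > k + 1 observations.")
  fit <- lm(y ~ x)
  if (any(is.na(coef(fit)))) abort("Singular regression fit.")
  # an (essentially) exact fit has no meaningful leverage-scaled residuals
  sigma_hat <- suppressWarnings(summary(fit)$sigma)
  if (sigma_hat <= 1e-10 * max(abs(y - mean(y)), .Machine$double.xmin)) {
    return(integer(0))
  }
  d <- cooks.distance(fit)
  d[!is.finite(d)] <- 0
  which(d > (threshold %||% (4 / n)))
}

#' Project a voxel measure onto existing saliences
#'
#' Computes per-subject dot products of a voxel-wise measure with the
#' saliences estimated in another analysis, yielding a spatially-matched
#' latent control variable.
#'
#' @param saliences Voxel vector (or voxel x LV matrix) of saliences.
#' @param measure Subject x voxel matrix in the same voxel space.
#' @return Subject vector (or subject x LV matrix) of latent scores.
#' @export
spatially_matched_latent <- function(saliences, measure) {
  saliences <- as.matrix(saliences)
  if (ncol(measure) != nrow(saliences)) abort("Voxel spaces differ.")
  out <- measure %*% saliences
  if (ncol(out) == 1L) drop(out) else out
}

#' Rank-based latent regression
#'
#' Least-squares regression of a subject-level outcome on latent scores
#' and/or model parameters, optionally (by default) on column-wise ranks.
#' Per predictor, reports the t statistic, p value, and semi-partial eta
#' squared (the predictor's sum of squares when entered last, over the
#' total sum of squares).
#'
#' @param data Tibble of subject-level variables.
#' @param response Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param rank Rank-transform all variables first (default TRUE).
#' @return A list: `terms` (tibble with `term`, `estimate`, `t`,
#'   `p_value`, `eta_sq_partial`) and `model` (one-row tibble with `F`,
#'   `df1`, `df2`, `p_value`, `r_squared`, `n`, plus a condition-number
#'   collinearity warning when appropriate).
#' @export
latent_regression <- function(data, response, predictors, rank = TRUE) {
  d <- data[, c(response, predictors)]
  if (any(!complete.cases(d))) d <- d[complete.cases(d), ]
  if (nrow(d) <= length(predictors) + 1) abort("Need n > k + 1 subjects.")
  if (rank) d <- dplyr::mutate(d, dplyr::across(dplyr::everything(),
                                                ~ rank(.x, ties.method = "average")))
  names(d)[1] <- ".y"
  fit <- lm(.y ~ ., data = d)
  X <- model.matrix(fit)
  kappa_x <- kappa(X, exact = TRUE)
  if (kappa_x > 1e8) warn(sprintf("Ill-conditioned design (kappa = %.2g).",
                                  kappa_x))
  sm <- summary(fit)
  ss_total <- sum((d$.y - mean(d$.y))^2)
  dr <- drop1(fit, test = "F")
  terms_tbl <- tibble::tibble(
    term = predictors,
    estimate = unname(coef(fit)[-1L]),
    t = sm$coefficients[-1L, "t value"],
    p_value = sm$coefficients[-1L, "Pr(>|t|)"],
    eta_sq_partial = dr$`Sum of Sq`[-1L] / ss_total
  )
  fstat <- sm$fstatistic
  model_tbl <- tibble::tibble(
    F = unname(fstat[1L]), df1 = unname(fstat[2L]), df2 = unname(fstat[3L]),
    p_value = pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    r_squared = sm$r.squared, n = nrow(d)
  )
  list(terms = terms_tbl, model = model_tbl)
}

#' Orthogonal polynomial contrasts over ordered conditions
#'
#' Tests linear, quadratic and cubic trends of subject x condition latent
#' scores across the ordered conditions, in a least-squares model with
#' subject indicator covariates. The contrast weights are the standard
#' orthogonal polynomial weights (zero-sum, mutually orthogonal).
#'
#' @param scores Subject x condition numeric matrix (conditions ordered).
#' @param max_degree Highest polynomial order tested (3 by default).
#' @return A tibble per order: `order`, `estimate` (contrast coefficient),
#'   `F`, `df1`, `df2`, `p_value`, `eta_sq_partial`.
#' @export
polynomial_contrasts <- function(scores, max_degree = 3) {
  n_cond <- ncol(scores)
  stopifnot(n_cond >= 3, max_degree < n_cond)
  W <- contr.poly(n_cond)[, seq_len(max_degree), drop = FALSE]
  long <- tibble::tibble(
    score = as.vector(scores),
    subject = factor(rep(seq_len(nrow(scores)), times = n_cond)),
    cond = rep(seq_len(n_cond), each = nrow(scores))
  )
  for (j in seq_len(max_degree)) long[[paste0("poly", j)]] <- W[long$cond, j]
  rhs <- paste(c("subject", paste0("poly", seq_len(max_degree))),
               collapse = " + ")
  fit <- lm(stats::as.formula(paste("score ~", rhs)), data = long)
  dr <- drop1(fit, test = "F")
  ss_total <- sum((long$score - mean(long$score))^2)
  rows <- paste0("poly", seq_len(max_degree))
  tibble::tibble(
    order = c("linear", "quadratic", "cubic",
              paste0("degree_", 4:9))[seq_len(max_degree)],
    estimate = unname(coef(fit)[rows]),
    F = dr[rows, "F value"],
    df1 = dr[rows, "Df"],
    df2 = fit$df.residual,
    p_value = dr[rows, "Pr(>F)"],
    eta_sq_partial = dr[rows, "Sum of Sq"] / ss_total
  )
}

#' Plot a PLS result
#'
#' Task PLS: per-condition brain scores (subject lines plus the mean) for
#' the first latent variable. Behavioral PLS: brain versus behavior scores.
#'
#' @param object A `pls_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, ...) {
  if (object$kind == "task") {
    sc <- object$brain_scores[, , 1L]
    df <- tibble::as_tibble(sc, .name_repair = ~ paste0("c", seq_along(.x))) |>
      dplyr::mutate(subject = dplyr::row_number()) |>
      tidyr::pivot_longer(-"subject", names_to = "condition",
                          values_to = "score")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$score)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.2) +
      ggplot2::stat_summary(fun = mean, geom = "point", size = 3) +
      ggplot2::labs(x = NULL, y = "brain score (LV1)")
  } else {
    df <- tibble::tibble(brain = object$brain_scores[, 1L],
                         behavior = object$behavior_scores[, 1L])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$brain, y = .data$behavior)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "brain score (LV1)", y = "behavior score (LV1)")
  }
}
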