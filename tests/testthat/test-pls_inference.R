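test_that("task PLS recovers a two-condition mean difference as a single LV", {
  set.seed(1)
  n_sub <- 12; n_vox <- 40
  d <- rnorm(n_vox)
  brain <- array(rnorm(n_sub * 2 * n_vox, sd = 0.01), c(n_sub, 2, n_vox))
  brain[, 1, ] <- brain[, 1, ] + rep(d / 2, each = n_sub)
  brain[, 2, ] <- brain[, 2, ] - rep(d / 2, each = n_sub)
  pls <- task_pls(brain)
  expect_gt(abs(cor(pls$saliences[, 1], d)), 0.999)
  # the mean-centered 2-condition matrix has rank 1: a single LV survives
  expect_equal(length(pls$singular_values), 1L)
  # brain scores are plain projections of the subject data
  expect_equal(pls$brain_scores[3, , 1],
               drop(brain[3, , ] %*% pls$saliences[, 1]))
  expect_error(task_pls(brain[, 1, , drop = FALSE]), "conditions")
})

test_that("the SVD reconstruction reproduces the cross matrix", {
  set.seed(2)
  brain <- matrix(rnorm(20 * 30), 20, 30)
  behavior <- cbind(rnorm(20), rnorm(20))
  pls <- behavioral_pls(brain, behavior, rank = FALSE)
  R <- cor(behavior, brain)
  recon <- Reduce(`+`, lapply(seq_along(pls$singular_values), function(l) {
    pls$singular_values[l] * pls$weights[, l] %o% pls$saliences[, l]
  }))
  expect_equal(recon, R, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("behavioral PLS is rank-invariant and finds planted structure", {
  set.seed(3)
  n <- 40; n_vox <- 100
  behavior <- rnorm(n)
  pattern <- c(rep(1, 25), rep(0, 75))
  pattern <- pattern / sqrt(sum(pattern^2))
  brain <- outer(behavior, pattern) * 8 + matrix(rnorm(n * n_vox), n)
  pls <- behavioral_pls(brain, behavior)
  expect_gt(abs(cor(pls$saliences[, 1], pattern)), 0.9)
  expect_gt(abs(pls$latent_cor[1]), 0.5)

  # invariance to monotone behavior transforms under ranking
  pls2 <- behavioral_pls(brain, exp(3 * behavior))
  expect_equal(pls2$singular_values, pls$singular_values, tolerance = 1e-10)

  # duplicated behavior column gives one dominant LV
  pls3 <- behavioral_pls(brain, cbind(behavior, behavior + 1e-9))
  sv <- c(pls3$singular_values, 0)
  expect_gt(sv[1], 100 * sv[2])
  expect_error(behavioral_pls(brain, rep(1, n)), "Constant")
})

test_that("permutation p values respect their bounds and detect planted effects", {
  set.seed(4)
  n <- 30
  behavior <- rnorm(n)
  brain <- outer(behavior, rep(1, 50)) * 3 + matrix(rnorm(n * 50), n)
  pls <- behavioral_pls(brain, behavior)
  pls <- permutation_test(pls, n_perm = 199, seed = 1)
  expect_equal(pls$p_perm[1], 1 / 200)
  # determinism
  pls2 <- permutation_test(behavioral_pls(brain, behavior), n_perm = 199, seed = 1)
  expect_identical(pls2$p_perm, pls$p_perm)

  # null data: p is not extreme
  null <- behavioral_pls(matrix(rnorm(n * 50), n), rnorm(n))
  null <- permutation_test(null, n_perm = 199, seed = 2)
  expect_gt(null$p_perm[1], 0.01)
  expect_lte(max(null$p_perm), 1)
})

test_that("task PLS permutation is calibrated under a condition-exchangeable null", {
  set.seed(9)
  pvals <- replicate(60, {
    brain <- array(rnorm(10 * 3 * 25), c(10, 3, 25))
    p <- permutation_test(task_pls(brain), n_perm = 120)$p_perm[1]
  })
  expect_gt(mean(pvals < 0.05), 0)   # not degenerate at 0 detections...
  expect_lt(mean(pvals < 0.05), 0.2) # ...and not wildly anticonservative
})

test_that("bootstrap salience ratios mark planted voxels and are sign-stable", {
  set.seed(5)
  n <- 30
  behavior <- rnorm(n)
  pattern <- c(rep(1, 20), rep(0, 60))
  brain <- outer(behavior, pattern) * 4 + matrix(rnorm(n * 80, sd = 0.5), n)
  pls <- behavioral_pls(brain, behavior)
  pls <- bootstrap_bsr(pls, n_boot = 300, seed = 2)
  expect_gt(mean(abs(pls$bsr[pattern > 0, 1]) > 3), 0.9)
  expect_lt(mean(abs(pls$bsr[pattern == 0, 1]) > 3), 0.2)
  expect_true(pls$n_boot_used > 290)

  # flipping the behavior sign flips saliences/BSR but not the mask
  pls_f <- bootstrap_bsr(behavioral_pls(brain, -behavior), n_boot = 300, seed = 2)
  expect_equal(pls_f$bsr_mask[, 1], pls$bsr_mask[, 1])
})

test_that("cluster thresholding respects size and connectivity", {
  vol <- array(FALSE, c(10, 10, 10))
  vol[1:2, 1:4, 1:3] <- TRUE            # 24 voxels -> removed
  out <- cluster_threshold(vol, min_size = 25)
  expect_equal(nrow(out$clusters), 0)
  expect_false(any(out$mask))

  vol[1:2, 1:4, 1:3] <- TRUE
  vol[3, 1, 1] <- TRUE                  # 25 voxels, face-connected -> kept
  out2 <- cluster_threshold(vol, min_size = 25)
  expect_equal(out2$clusters$size, 25)

  # two face-touching blobs merge into one cluster
  vol2 <- array(FALSE, c(10, 10, 10))
  vol2[1:3, 1:3, 1:3] <- TRUE
  vol2[4:6, 1:3, 1:3] <- TRUE
  out3 <- cluster_threshold(vol2, min_size = 25)
  expect_equal(nrow(out3$clusters), 1)
  expect_equal(out3$clusters$size, 54)

  # diagonal-only contact does not merge under 6-connectivity
  vol3 <- array(FALSE, c(10, 10, 10))
  vol3[1:3, 1:3, 1:3] <- TRUE
  vol3[4:6, 4:6, 1:3] <- TRUE
  out4 <- cluster_threshold(vol3, min_size = 25)
  expect_equal(nrow(out4$clusters), 2)
})

test_that("Cook's screening flags gross outliers and scales with the threshold", {
  set.seed(6)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30, sd = 0.1)
  y[7] <- 10
  x[7] <- -3
  flagged <- cooks_screen(x, y)
  expect_true(7 %in% flagged)
  # raising the threshold can only shrink the set
  f2 <- cooks_screen(x, y, threshold = 1)
  expect_true(all(f2 %in% flagged))
  # exact fit: no observations flagged
  expect_equal(length(cooks_screen(1:20, 2 * (1:20) + 3)), 0)
})

test_that("spatially matched latents are linear projections", {
  set.seed(7)
  sal <- rnorm(50)
  B1 <- matrix(rnorm(10 * 50), 10)
  B2 <- matrix(rnorm(10 * 50), 10)
  s1 <- spatially_matched_latent(sal, B1)
  expect_equal(spatially_matched_latent(sal, B1 + B2), s1 +
                 spatially_matched_latent(sal, B2), tolerance = 1e-12)
  # orthogonal measure projects to zero
  ortho <- matrix(rep(pracma_null <- rnorm(50) -
                        sal * sum(rnorm(50) * sal) / sum(sal^2), 2),
                  2, byrow = TRUE)
  ortho <- ortho - outer(drop(ortho %*% sal) / sum(sal^2), sal)
  expect_equal(drop(spatially_matched_latent(sal, ortho)), c(0, 0),
               tolerance = 1e-10)
  expect_error(spatially_matched_latent(sal, B1[, 1:20]), "Voxel")
})

test_that("latent regression is exact on linear data and calibrated under the null", {
  d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 2 * d$x1 - d$x2 + 3
  fit <- suppressWarnings(latent_regression(d, "y", c("x1", "x2"), rank = FALSE))
  expect_equal(fit$model$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$terms$estimate, c(2, -1), tolerance = 1e-8)
  # semi-partial eta^2 sums to <= 1 and is positive
  expect_true(all(fit$terms$eta_sq_partial > 0))

  set.seed(8)
  rate <- mean(replicate(300, {
    d <- tibble::tibble(y = rnorm(25), x1 = rnorm(25), x2 = rnorm(25))
    latent_regression(d, "y", c("x1", "x2"))$terms$p_value[1]
  }) < 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("polynomial contrasts isolate the generating trend", {
  set.seed(10)
  n_sub <- 20
  lin <- matrix(rep(seq(2, -2, length.out = 5), each = n_sub), n_sub) +
    matrix(rnorm(n_sub * 5, sd = 0.1), n_sub)
  res <- polynomial_contrasts(lin)
  expect_equal(res$order, c("linear", "quadratic", "cubic"))
  expect_lt(res$p_value[1], 1e-10)
  expect_gt(res$eta_sq_partial[1], 10 * (res$eta_sq_partial[2] +
                                           res$eta_sq_partial[3]))

  ushape <- matrix(rep(c(2, 0, -1, 0, 2), each = n_sub), n_sub) +
    matrix(rnorm(n_sub * 5, sd = 0.1), n_sub)
  res2 <- polynomial_contrasts(ushape)
  expect_equal(res2$order[which.max(res2$eta_sq_partial)], "quadratic")

  # contrast weights: zero-sum and mutually orthogonal by construction
  W <- contr.poly(5)[, 1:3]
  expect_equal(colSums(W), rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(crossprod(W), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})
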