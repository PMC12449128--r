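test_that("prior initialization follows the prior-width parameter", {
  b <- init_belief(1)
  expect_equal(belief_moments(b)$mean, 0.5)
  expect_equal(belief_moments(b)$variance, 1 / 12)
  b2 <- init_belief(2.45)
  expect_equal(b2$alpha, 2.45)
  expect_equal(b2$beta, 2.45)
  expect_error(init_belief(0.5), "rho")
})

test_that("belief updates are conjugate and evidence weighting behaves", {
  b <- update_belief(init_belief(1), 3, 2)
  expect_equal(c(b$alpha, b$beta), c(4, 3))
  expect_equal(belief_moments(b)$mean, 4 / 7)

  b2 <- update_belief(init_belief(1), 9, 0, delta = 0.5)
  expect_equal(c(b2$alpha, b2$beta), c(4, 1))   # 9^0.5 = 3, 0^0.5 = 0

  b3 <- update_belief(belief(2, 2), 0, 0, delta = 1)
  expect_equal(c(b3$alpha, b3$beta), c(2, 2))
  # the 0^0 convention: an empty count contributes nothing at delta = 0
  b4 <- update_belief(belief(2, 2), 0, 5, delta = 0)
  expect_equal(c(b4$alpha, b4$beta), c(2, 3))
})

test_that("belief moments match the closed form and concentrate", {
  m <- belief_moments(belief(4, 3))
  expect_equal(m$mean, 4 / 7)
  expect_equal(m$variance, 12 / (49 * 8))
  expect_lt(belief_moments(belief(100, 100))$variance,
            belief_moments(belief(1, 1))$variance)
})

test_that("conjugate updating matches grid-based Bayes", {
  # independent oracle: discretize p on a fine grid, multiply the beta prior
  # density by binomial likelihoods, renormalize, take moments
  grid_bayes <- function(rho, draws) {
    p <- seq(1e-6, 1 - 1e-6, length.out = 10001)
    w <- stats::dbeta(p, rho, rho)
    for (i in seq_len(nrow(draws))) {
      n <- draws$n_blue[i] + draws$n_red[i]
      w <- w * stats::dbinom(draws$n_blue[i], n, p)
    }
    w <- w / sum(w)
    mu <- sum(w * p)
    c(mean = mu, variance = sum(w * (p - mu)^2))
  }
  set.seed(5)
  for (r in 1:20) {
    rho <- runif(1, 1, 8)
    sizes <- sample(c(1, 5, 9), 5, replace = TRUE)
    draws <- tibble::tibble(n_blue = rbinom(5, sizes, runif(1, 0.1, 0.9)))
    draws$n_red <- sizes - draws$n_blue
    spec <- observer_spec("bayes_rho_sigma", rho = rho, sigma = 0.1)
    traj <- trial_trajectory(spec, draws)
    oracle <- grid_bayes(rho, draws)
    expect_equal(traj$mean[6], unname(oracle["mean"]), tolerance = 1e-4)
    expect_equal(traj$variance[6], unname(oracle["variance"]), tolerance = 1e-4)
  }
})

test_that("trial trajectories are additive, shrink variance, and are exchangeable", {
  draws <- tibble::tibble(n_blue = c(5, 1, 0, 3, 1), n_red = c(0, 4, 1, 2, 3))
  spec <- observer_spec("bayes_rho_sigma", rho = 1, sigma = 0.1)
  traj <- trial_trajectory(spec, draws)
  expect_equal(nrow(traj), 6)
  expect_equal(traj$alpha[6], 1 + sum(draws$n_blue))
  expect_equal(traj$beta[6], 1 + sum(draws$n_red))
  # alpha + beta strictly increases; the variance bound strictly decreases
  tot <- traj$alpha + traj$beta
  expect_true(all(diff(tot) > 0))
  expect_true(all(diff(1 / (4 * (tot + 1))) < 0))
  # permuting sample order leaves the final state unchanged at delta = 1
  perm <- trial_trajectory(spec, draws[c(3, 1, 5, 2, 4), ])
  expect_equal(perm$mean[6], traj$mean[6])

  expect_error(
    trial_trajectory(observer_spec("rescorla_wagner", learning_rate = 0.5,
                                   sigma = 0.1), draws),
    "Bayesian")
})

test_that("a larger prior width shrinks the posterior mean toward 0.5", {
  draws <- tibble::tibble(n_blue = c(9, 5, 1, 9, 5), n_red = c(0, 0, 0, 0, 0))
  dev <- vapply(c(1, 2, 5, 20), function(rho) {
    spec <- observer_spec("bayes_rho_sigma", rho = rho, sigma = 0.1)
    abs(trial_trajectory(spec, draws)$mean[6] - 0.5)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("Rescorla-Wagner updates follow the delta rule", {
  draws <- tibble::tibble(n_blue = c(9, 0), n_red = c(0, 9))
  expect_equal(rw_trajectory(0.5, draws[1, ]), c(0.5, 0.75))
  expect_equal(rw_trajectory(0, draws), c(0.5, 0.5, 0.5))
  expect_equal(rw_trajectory(1, draws)[3], 0)   # equals the last sample
  expect_error(rw_trajectory(1.2, draws), "learning_rate")
})

test_that("response likelihoods match closed forms", {
  spec <- observer_spec("bayes_rho_sigma", rho = 1, sigma = 0.1)
  state <- belief(1, 1)
  # at the mean with sigma 0.1, the truncation mass is ~1
  expect_equal(response_loglik(spec, state, 0.5),
               dnorm(0, log = TRUE) - log(0.1), tolerance = 1e-6)
  # maximal at the belief mean
  lls <- response_loglik(spec, belief(4, 4), seq(0, 1, 0.05))
  expect_equal(seq(0, 1, 0.05)[which.max(lls)], 0.5)

  # uniform final beta: every interior response bin has probability 0.01
  dspec <- observer_spec("bayes_rho_draw", rho = 1)
  expect_equal(response_loglik(dspec, belief(1, 1), 0.37), log(0.01))
  expect_error(response_loglik(
    observer_spec("bayes_rho_sigma", rho = 1, sigma = 0.1), state, 1.5))
})

test_that("the truncated-normal response density integrates to one", {
  x <- seq(0, 1, length.out = 20001)
  for (m in c(0.05, 0.5, 0.95)) {
    for (s in c(0.05, 0.1, 0.3)) {
      dens <- exp(beliefvar:::log_dtruncnorm01(x, m, s))
      integral <- sum((dens[-1] + dens[-length(x)]) / 2) * diff(x[1:2])
      expect_equal(integral, 1, tolerance = 1e-6)
    }
  }
})

test_that("dataset likelihood is additive and matches quadrature", {
  sess <- small_session()
  dspec <- observer_spec("bayes_rho_draw", rho = 1)
  one <- sess[sess$trial_id == 1, ]
  # force a flat final belief with an artificial zero-count trial
  flat <- one
  flat$n_blue <- 0L; flat$n_red <- 0L
  flat$reported_estimate <- 0.42
  expect_equal(dataset_negloglik(dspec, flat), -log(0.01))

  spec <- observer_spec("bayes_rho_sigma", rho = 2, sigma = 0.08)
  behav <- simulate_responses(spec, sess, seed = 3)
  nll <- dataset_negloglik(spec, behav)
  doubled <- dplyr::bind_rows(
    behav, dplyr::mutate(behav, trial_id = trial_id + max(trial_id)))
  expect_equal(dataset_negloglik(spec, doubled), 2 * nll, tolerance = 1e-10)

  # quadrature oracle for the draw-family bin probabilities
  dbehav <- simulate_responses(dspec, sess, seed = 4)
  nll_pkg <- dataset_negloglik(dspec, dbehav)
  prep <- beliefvar:::prepare_trials(dbehav)
  a <- 1 + rowSums(prep$Bmat); b <- 1 + rowSums(prep$Rmat)
  nll_quad <- -sum(vapply(seq_along(a), function(i) {
    lo <- max(0, prep$reported[i] - 0.005)
    hi <- min(1, prep$reported[i] + 0.005)
    log(stats::integrate(stats::dbeta, lo, hi, shape1 = a[i], shape2 = b[i],
                         rel.tol = 1e-10)$value)
  }, numeric(1)))
  expect_equal(nll_pkg, nll_quad, tolerance = 1e-6)
})

test_that("uncertainty trajectories agree with per-trial trajectories", {
  sess <- small_session()
  traj <- uncertainty_trajectories(sess, rho = 2)
  spec <- observer_spec("bayes_rho_sigma", rho = 2, sigma = 0.1)
  for (tid in c(1, 5)) {
    draws <- sess[sess$trial_id == tid, c("n_blue", "n_red")]
    ref <- trial_trajectory(spec, draws)
    got <- traj[traj$trial_id == tid, ]
    expect_equal(got$post_var[order(got$sample_index)], ref$variance[-1])
  }
  expect_equal(unique(traj$prior_var), belief_moments(init_belief(2))$variance)
})
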