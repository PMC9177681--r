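test_that("beta log-density matches an independent density evaluation", {
  # uniform beta at theta = 0.5, nu = 2
  expect_equal(beta_logpdf(0.5, 1, nu = 2), 0)
  expect_equal(beta_logpdf(0.5, 0, nu = 2), 0)
  # gamma-function oracle through the distribution function machinery
  for (case in list(c(0.8, 1, 10), c(0.3, 0, 4), c(0.9, 1, 0.7))) {
    th <- case[1]; y <- case[2]; nu <- case[3]
    yhat <- min(max(y, 1e-4), 1 - 1e-4)
    expect_equal(beta_logpdf(th, y, nu),
                 dbeta(yhat, th * nu, (1 - th) * nu, log = TRUE),
                 tolerance = 1e-12)
  }
  # symmetry of the beta family
  expect_equal(beta_logpdf(0.8, 1, 5), beta_logpdf(0.2, 0, 5))
  expect_error(beta_logpdf(0.5, 1, nu = -1), "positive")
})

test_that("model accuracy sums trial negative log-likelihoods", {
  y <- c(1, 0, 1)
  expect_equal(model_accuracy(rep(0.5, 3), y, nu = 2), 0)
  expect_equal(model_accuracy(0.8, 1, nu = 5),
               -beta_logpdf(0.8, 1, 5))
  # moving beliefs toward the outcomes improves (lowers) accuracy
  set.seed(2)
  yy <- rbinom(50, 1, 0.5)
  far <- rep(0.5, 50)
  near <- ifelse(yy == 1, 0.8, 0.2)
  expect_lt(model_accuracy(near, yy, nu = 4),
            model_accuracy(far, yy, nu = 4))
  expect_error(model_accuracy(c(0.5, 0.5), c(1, 0, 1), 2), "misaligned")
})

test_that("MAP fit recovers a persistent RW learner", {
  # sticky outcome sequence: a high learning rate (track the previous
  # outcome) is the best explanation; note that alpha exactly 1 is not
  # optimal under the beta response model, whose density sinks again for
  # beliefs at the clamp bound
  set.seed(8)
  y <- rep(rep(c(1L, 0L), 6), times = sample(8:16, 12, replace = TRUE))
  y <- y[1:120]
  f <- fit_model(y, "rw", "state", seed = 1)
  expect_gt(f$params$alpha, 0.1)
  expect_true(f$converged)
  # and it clearly beats a non-learning account of the same data
  flat <- model_accuracy(rep(0.5, 120), y, f$nu)
  expect_lt(f$accuracy, flat)
})

test_that("fit objective decomposes into accuracy minus log-prior", {
  d <- small_design(seed = 2)
  ag <- simulate_agent(d, "hgf2", "state", list(omega = -2),
                       suppression = 0.05, seed = 3)
  f <- fit_model(ag$data$outcome, "hgf2", "state",
                 items = ag$data$item_id, seed = 4)
  pr <- default_priors("hgf2")
  logprior <- sum(dnorm(f$par_transformed, pr$mean, pr$sd, log = TRUE))
  expect_equal(f$objective, f$accuracy - logprior, tolerance = 1e-6)
  # the MAP optimum is never worse than the prior mean (first start)
  prior_theta <- filter_beliefs(ag$data$outcome, "hgf2", "state",
                                list(omega = -3))$muhat
  obj_at_prior <- model_accuracy(prior_theta, ag$data$outcome, 1) -
    sum(dnorm(pr$mean, pr$mean, pr$sd, log = TRUE))
  expect_lte(f$objective, obj_at_prior + 1e-8)
})

test_that("unpredictable ratings freeze beliefs near one half", {
  # a mean-0.5 sequence with no learnable structure: the fit slows belief
  # updating (omega at or below the prior mean) and the belief trajectory
  # stays uninformative around 0.5
  y <- rep(c(0L, 1L), 72)
  f <- fit_model(y, "hgf2", "state", seed = 5)
  expect_lte(f$params$omega, -3)
  expect_true(all(abs(f$trajectory$muhat - 0.5) < 0.1))
  # the prior-stuck flag reflects the fitted perceptual parameters
  expect_identical(f$prior_stuck,
                   abs(f$par_transformed[["omega"]] - (-3)) < 1e-2)
})

test_that("refitting identical data with the same seed is deterministic", {
  d <- small_design(seed = 6)
  ag <- simulate_agent(d, "hgf2", "item", list(omega = -2),
                       suppression = 0.05, seed = 7)
  f1 <- fit_model(ag$data$outcome, "hgf2", "item",
                  items = ag$data$item_id, seed = 11)
  f2 <- fit_model(ag$data$outcome, "hgf2", "item",
                  items = ag$data$item_id, seed = 11)
  expect_identical(f1$par_transformed, f2$par_transformed)
  expect_identical(f1$accuracy, f2$accuracy)
})

test_that("fits work for every model and source on one dataset", {
  d <- small_design(seed = 9)
  ag <- simulate_agent(d, "hgf2", "combined", list(omega = -2),
                       suppression = 0.05, seed = 10)
  for (model in c("hgf2", "kf", "rw")) {
    for (source in c("state", "item", "combined")) {
      f <- fit_model(ag$data$outcome, model, source,
                     items = ag$data$item_id, n_starts = 2, seed = 12)
      expect_true(is.finite(f$accuracy))
      expect_s3_class(f, "tnt_fit")
      expect_true(all(f$trajectory$muhat > 0 & f$trajectory$muhat < 1))
    }
  }
})
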