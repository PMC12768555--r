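# Shared fixtures: moderate-size calibration fits reused across blocks.
h0_fit <- fit_beta_regression(
  simulate_cohort(hypothesis_spec("h0", "fixed"), 3000, seed = 401),
  seed = 402
)
h1_fit <- fit_beta_regression(
  simulate_cohort(hypothesis_spec("h1", "fixed"), 3000, seed = 403),
  seed = 404
)

test_that("parameter recovery: credible intervals cover known truth", {
  set.seed(510)
  truth <- c(b0 = 1.0, b1 = -0.5, phi = 30)
  cohort <- model_generated_cohort(5000, truth["b0"], truth["b1"],
                                   truth["phi"])
  # weakly-informative priors so recovery isolates likelihood and sampler
  # correctness rather than prior shrinkage
  fit <- fit_beta_regression(cohort, seed = 511,
                             priors = prior_spec(beta0_sd = 2, beta1_sd = 1))
  expect_true(fit$converged)
  s <- posterior_summary(fit)
  for (i in 1:3) {
    expect_gte(truth[i], s$`l-95% CI`[i])
    expect_lte(truth[i], s$`u-95% CI`[i])
  }
  # point estimates land near the truth at this sample size
  expect_equal(s$Estimate[1], 1.0, tolerance = 0.1)
  expect_equal(s$Estimate[2], -0.5, tolerance = 0.1)
})

test_that("posterior agrees with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  set.seed(520)
  cohort <- model_generated_cohort(800, -0.5, 0.3, 20)
  fit <- fit_beta_regression(cohort, seed = 521)
  model_string <- "
    model {
      for (i in 1:n) {
        y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
        logit(mu[i]) <- b0 + b1 * h[i]
      }
      b0 ~ dnorm(-0.5, pow(0.5, -2))
      b1 ~ dnorm(0, pow(0.1, -2))
      phi ~ dgamma(5, 1)
    }"
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(y = squeeze_unit(cohort$ratio), h = cohort$h_bits,
                n = nrow(cohort)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 99),
    n.chains = 1, quiet = TRUE
  )
  stats::update(jm, 1000, progress.bar = "none")
  post <- rjags::coda.samples(jm, c("b0", "b1", "phi"), 4000,
                              progress.bar = "none")[[1]]
  jags_mean <- colMeans(post)
  s <- posterior_summary(fit)
  # agreement within a few posterior sds of each other
  expect_equal(s$Estimate[1], unname(jags_mean["b0"]),
               tolerance = 3 * s$Est.Error[1] / abs(s$Estimate[1]))
  expect_equal(s$Estimate[2], unname(jags_mean["b1"]),
               tolerance = 3 * s$Est.Error[2] / abs(s$Estimate[2]))
  expect_equal(s$Estimate[3], unname(jags_mean["phi"]),
               tolerance = 3 * s$Est.Error[3] / s$Estimate[3])
})

test_that("prior predictive mass stays away from the unit boundaries", {
  set.seed(530)
  pr <- prior_spec()
  b0 <- rnorm(4000, pr$beta0_mean, pr$beta0_sd)
  b1 <- rnorm(4000, pr$beta1_mean, pr$beta1_sd)
  phi <- rgamma(4000, pr$phi_shape, rate = pr$phi_rate)
  h <- runif(4000, 0.5, 2.5)
  mu <- plogis(b0 + b1 * h)
  y <- rbeta(4000, mu * phi, (1 - mu) * phi)
  expect_lt(mean(y < 0.01 | y > 0.99), 0.05)
})

test_that("slope signs separate the null from the conditioning regime", {
  for (s in 1:2) {
    f0 <- fit_beta_regression(
      simulate_cohort(hypothesis_spec("h0", "fixed"), 2000, seed = 540 + s),
      seed = 560 + s
    )
    f1 <- fit_beta_regression(
      simulate_cohort(hypothesis_spec("h1", "fixed"), 2000, seed = 580 + s),
      seed = 600 + s
    )
    expect_gt(posterior_summary(f0)$Estimate[2], 0)
    expect_lt(posterior_summary(f1)$Estimate[2], 0)
  }
})

test_that("fit validates its inputs", {
  expect_error(fit_beta_regression(data.frame()), "empty")
  bad <- data.frame(participant_id = 1:2, h_bits = c(1, 2),
                    mi_bits = 0, ratio = c(0.5, 1.2))
  expect_error(fit_beta_regression(bad), "\\[0, 1\\]")
  boundary <- data.frame(participant_id = 1:3, h_bits = 1:3,
                         mi_bits = 0, ratio = c(0, 1, 0))
  expect_error(fit_beta_regression(boundary), "boundary")
  inner <- data.frame(participant_id = 1:3, h_bits = 1:3,
                      mi_bits = 0, ratio = c(0, 0.5, 1))
  expect_error(fit_beta_regression(inner, squeeze = "none"), "boundary")
})

test_that("log predictive density behaves like a density", {
  # identical participants get identical values
  ll <- log_pointwise_likelihood(h0_fit, c(1.8, 1.8), c(0.1, 0.1))
  expect_equal(ll[1], ll[2])
  expect_true(all(is.finite(ll)))
  # boundary ratios are clamped to a finite value
  expect_true(is.finite(log_pointwise_likelihood(h0_fit, 1.8, 0)))
  expect_true(is.finite(log_pointwise_likelihood(h0_fit, 1.8, 1)))
  # the null posterior prefers small ratios over near-1 ratios
  expect_gt(log_pointwise_likelihood(h0_fit, 1.8, 0.12),
            log_pointwise_likelihood(h0_fit, 1.8, 0.99))
  # plug-in mode tracks the predictive mode closely at large n
  lp_pred <- log_pointwise_likelihood(h0_fit, 1.8, 0.12)
  lp_plug <- log_pointwise_likelihood(h0_fit, 1.8, 0.12, method = "plugin")
  expect_equal(lp_pred, lp_plug, tolerance = 0.05)
})

test_that("classification assigns strong conditioners to h1", {
  models <- list(h0 = h0_fit, h1 = h1_fit)
  strong <- classify_participant(1.5, 0.9, models)
  expect_gt(strong$log_bf10, 0)
  expect_equal(strong$best_fit, "h1")
  weak <- classify_participant(1.8, 0.05, models)
  expect_lt(weak$log_bf10, 0)
  expect_equal(weak$best_fit, "h0")
  # identical models: exact tie, broken toward the null
  tie <- classify_participant(1.8, 0.3, list(h0 = h0_fit, h1 = h0_fit))
  expect_equal(tie$log_bf10, 0)
  expect_equal(tie$best_fit, "h0")
})

test_that("classification validates inputs", {
  expect_error(classify_cohort(data.frame(), list(h0 = h0_fit, h1 = h1_fit)),
               "no participants")
  s <- data.frame(participant_id = 1, h_bits = 1.8, ratio = 0.1)
  expect_error(classify_cohort(s, list(h0_fit)), "named list")
})

test_that("aggregate Bayes factors sum in log space", {
  cls <- data.frame(participant_id = 1:3, log_bf10 = c(0, 0, 0))
  agg <- aggregate_bayes_factor(cls)
  expect_equal(agg$bf10, 1)
  one <- data.frame(participant_id = 1, log_bf10 = -2.5)
  expect_equal(aggregate_bayes_factor(one)$log_bf10, -2.5)
  # strongly negative sums display as the decisive "0"
  many <- data.frame(participant_id = 1:100, log_bf10 = rep(-3, 100))
  agg2 <- aggregate_bayes_factor(many)
  expect_equal(agg2$display, "0")
  expect_equal(agg2$log_bf10, -300)
  expect_error(aggregate_bayes_factor(data.frame()), "no classifications")
})

test_that("null cohorts yield an aggregate Bayes factor below one", {
  cohort <- simulate_cohort(hypothesis_spec("h0", "fixed"), 100, seed = 620)
  cls <- classify_cohort(cohort, list(h0 = h0_fit, h1 = h1_fit))
  expect_lt(aggregate_bayes_factor(cls)$bf10, 1)
})

test_that("posterior summaries expose ordered intervals and diagnostics", {
  s <- posterior_summary(h0_fit)
  expect_equal(s$parameter, c("Intercept", "H(C)", "phi"))
  expect_true(all(s$`l-95% CI` <= s$Estimate))
  expect_true(all(s$Estimate <= s$`u-95% CI`))
  expect_true(all(h0_fit$draws[, 3] > 0))
  expect_true(all(h0_fit$diagnostics$rhat <= 1.01))
  expect_true(all(h0_fit$diagnostics$ess >= 400))
  s2 <- posterior_summary(h0_fit, digits = 2)
  expect_equal(s2$Estimate, round(s$Estimate, 2))
})
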