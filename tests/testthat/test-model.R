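test_that("model data preparation centres time and codes factors by treatment", {
  rec <- sim_model_records(1)
  dat <- prepare_model_data(rec, period = 1,
                            spec = model_spec(~ centered_day * disturbance,
                                              ~ centered_day * disturbance))
  expect_lt(abs(mean(dat$X[, "centered_day"])), 1e-12)
  expect_identical(colnames(dat$X),
                   c("(Intercept)", "centered_day", "disturbanceD",
                     "centered_day:disturbanceD"))
  # U and L are reference levels
  u_rows <- dat$records$disturbance_at_sampling == "U"
  expect_true(all(dat$X[u_rows, "disturbanceD"] == 0))
  expect_error(
    prepare_model_data(rec[rec$disturbance_at_sampling == "U", ], period = 1,
                       spec = model_spec(~ centered_day * disturbance,
                                         ~centered_day)),
    "single observed level"
  )
  rec2 <- rec
  rec2$index <- rep(c("bray_curtis", "sorensen"), length.out = nrow(rec2))
  expect_error(prepare_model_data(rec2, period = 1), "mixes")
  expect_silent(prepare_model_data(rec2, period = 1, index = "sorensen",
                                   spec = model_spec(~ centered_day * disturbance,
                                                     ~centered_day)))
})

test_that("period selection keeps only that period's records", {
  rec <- sim_model_records(2)
  rec$period[rec$day > 14] <- 2L
  dat <- prepare_model_data(rec, period = 1,
                            spec = model_spec(~centered_day, ~centered_day))
  expect_true(all(dat$records$day <= 14))
  expect_lt(abs(mean(dat$records$centered_day)), 1e-12)
})

test_that("the sampler retains exactly chains x (iterations - warmup) draws", {
  cfg <- mcmc_config(chains = 2, iterations_per_chain = 400, warmup = 250,
                     seed = 1)
  expect_equal(retained_draws(cfg), 300)
  fit <- quick_fit(sim_model_records(3), seed = 3)
  expect_equal(nrow(fit$draws), retained_draws(quick_mcmc(3)))
  expect_equal(length(fit$chain), nrow(fit$draws))
  expect_true(all(c("mu_(Intercept)", "mu_centered_day", "sigma_(Intercept)",
                    "sigma_centered_day", "tau_comparison") %in%
                    colnames(fit$draws)))
  expect_equal(dim(fit$log_lik), c(nrow(fit$draws), length(fit$data$y)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_equal(retained_draws(mcmc_config()), 8000)
})

test_that("group slopes are exact linear combinations of coefficient draws", {
  fit <- quick_fit(sim_model_records(4), seed = 4,
                   spec = model_spec(~ centered_day * disturbance,
                                     ~ centered_day * disturbance))
  sl <- derive_group_slopes(fit)
  draws <- attr(sl, "draws")
  # reference group (U) slope = bare centered_day coefficient, draw by draw
  expect_equal(unname(draws$mu[, "U"]),
               unname(fit$draws[, "mu_centered_day"]))
  # (D) - (U) = interaction coefficient, draw by draw
  expect_equal(unname(draws$mu[, "D"] - draws$mu[, "U"]),
               unname(fit$draws[, "mu_centered_day:disturbanceD"]))
  expect_equal(unname(draws$sigma[, "U"]),
               unname(fit$draws[, "sigma_centered_day"]))
  # summaries are ordered credible intervals
  expect_true(all(sl$mu$ci95_lo <= sl$mu$ci80_lo))
  expect_true(all(sl$mu$ci80_lo <= sl$mu$ci50_lo))
  expect_true(all(sl$mu$ci50_lo <= sl$mu$ci50_hi))
})

test_that("slopes computed by coding arithmetic match a re-referenced refit", {
  rec <- sim_model_records(5, beta_t = 0.012)
  fit <- quick_fit(rec, seed = 5)
  sl <- derive_group_slopes(fit)
  # refit with D as the reference level: its bare slope must match the
  # original D-group slope within MCMC error
  rec_flip <- rec
  rec_flip$disturbance_at_sampling <-
    ifelse(rec$disturbance_at_sampling == "U", "D", "U")
  fit_flip <- quick_fit(rec_flip, seed = 5)
  sl_flip <- derive_group_slopes(fit_flip)
  d_orig <- sl$mu[sl$mu$disturbance == "D", ]
  d_flip <- sl_flip$mu[sl_flip$mu$disturbance == "U", ]
  mc_se <- 2 * (d_orig$sd + d_flip$sd) / sqrt(nrow(fit$draws))
  expect_lt(abs(d_orig$mean - d_flip$mean), 10 * mc_se + 0.002)
})

test_that("null data give slope posteriors consistent with zero", {
  rec <- sim_model_records(6, beta_t = 0, gamma_t = 0, n_pairs = 4)
  fit <- quick_fit(rec, seed = 6)
  td <- tidy(fit)
  for (term in c("mu_centered_day", "sigma_centered_day")) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate), 2 * row$std.error)
  }
})

test_that("known slopes are recovered from model-simulated data", {
  rec <- sim_model_records(7, beta_t = 0.01, gamma_t = -0.05)
  fit <- quick_fit(rec, seed = 7,
                   spec = model_spec(~ centered_day * disturbance,
                                     ~centered_day))
  td <- tidy(fit)
  bt <- td[td$term == "mu_centered_day", ]
  gt <- td[td$term == "sigma_centered_day", ]
  expect_lt(abs(bt$estimate - 0.01), 3 * bt$std.error)
  expect_lt(abs(gt$estimate - (-0.05)), 3 * gt$std.error)
})

test_that("prior-predictive draws are finite with positive sigma", {
  dat <- prepare_model_data(sim_model_records(8), period = 1,
                            spec = model_spec(~ centered_day * disturbance,
                                              ~centered_day))
  pp <- prior_predictive(dat, n_draws = 500, seed = 1)
  expect_true(all(is.finite(pp$y_rep)))
  expect_true(all(pp$sigma > 0))
})

test_that("tidy and glance report coherent fit summaries", {
  fit <- quick_fit(sim_model_records(9), seed = 9)
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, length(fit$data$y))
  expect_equal(gl$n_draws, nrow(fit$draws))
  expect_true(is.finite(gl$elpd_waic))
})
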