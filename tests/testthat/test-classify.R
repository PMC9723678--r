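test_that("the quadrant rule reproduces the published worked examples", {
  # disturbed period 1: similarity rising, spread shrinking
  expect_equal(classify_assembly(0.011, -0.054), "selection")
  # undisturbed period 1: similarity falling, spread growing
  expect_equal(classify_assembly(-0.015, 0.061), "drift")
  # previously-disturbed period 2: flat similarity, shrinking spread
  expect_equal(classify_assembly(0.00050, -0.028), "selection")
  # disturbed period 2
  expect_equal(classify_assembly(0.0092, -0.044), "selection")
})

test_that("boundaries and mixed cases follow the strict sigma inequality", {
  expect_equal(classify_assembly(-0.001, -0.001), "mixed")
  expect_equal(classify_assembly(0, -0.01), "selection")  # mu >= 0 inclusive
  expect_equal(classify_assembly(0.01, 0), "mixed")       # sigma = 0 is not < 0
  expect_equal(classify_assembly(-0.01, 0), "mixed")      # nor > 0
  expect_equal(classify_assembly(0.02, 0.02), "mixed")
  expect_equal(classify_assembly(c(0.01, -0.01), c(-0.1, 0.1)),
               c("selection", "drift"))
  expect_error(classify_assembly(NaN, 0.1), "finite")
  expect_error(classify_assembly(1, c(1, 2)), "equal length")
})

test_that("quadrant probabilities sum to one and match degenerate draws", {
  qp <- quadrant_probabilities(rep(0.01, 100), rep(-0.02, 100))
  expect_equal(qp$p_selection, 1)
  expect_equal(qp$p_drift + qp$p_converge_spread + qp$p_diverge_tighten, 0)
  set.seed(5)
  mu <- rnorm(100000)
  sg <- rnorm(100000)
  qp2 <- quadrant_probabilities(mu, sg)
  expect_equal(sum(unlist(qp2)), 1, tolerance = 1e-9)
  se <- sqrt(0.25 * 0.75 / 100000)
  expect_true(all(abs(unlist(qp2) - 0.25) < 3 * se))
  expect_error(quadrant_probabilities(1:3, 1:4), "paired")
})

test_that("point-estimate labels agree with the dominant posterior quadrant", {
  set.seed(6)
  for (i in 1:10) {
    mu <- rnorm(2000, rnorm(1, 0, 0.02), 0.01)
    sg <- rnorm(2000, rnorm(1, 0, 0.05), 0.02)
    qp <- quadrant_probabilities(mu, sg)
    probs <- c(selection = qp$p_selection, drift = qp$p_drift,
               mixed = qp$p_converge_spread + qp$p_diverge_tighten)
    top <- names(probs)[which.max(probs)]
    label <- classify_assembly(mean(mu), mean(sg))
    if (max(probs) > 0.5 && top %in% c("selection", "drift")) {
      # point estimates inside a dominant quadrant agree with it
      in_quadrant <- switch(top,
        selection = mean(mu) >= 0 && mean(sg) < 0,
        drift = mean(mu) < 0 && mean(sg) > 0)
      if (in_quadrant) expect_equal(label, top)
    }
  }
})

test_that("assembly calls pair mean and sigma groups and report probabilities", {
  fit <- quick_fit(sim_model_records(15, beta_t = 0.01, gamma_t = -0.05),
                   seed = 15,
                   spec = model_spec(~ centered_day * disturbance,
                                     ~ centered_day * disturbance))
  calls <- assembly_calls(derive_group_slopes(fit))
  expect_equal(nrow(calls), 2)
  expect_true(all(c("delta_mu_mean", "delta_sigma_mean", "label",
                    "p_selection", "p_drift") %in% names(calls)))
  psum <- calls$p_selection + calls$p_drift + calls$p_converge_spread +
    calls$p_diverge_tighten
  expect_equal(psum, rep(1, 2), tolerance = 1e-9)
  expect_true(all(calls$label %in% c("selection", "drift", "mixed")))
  # strong simulated convergence signal lands in the selection quadrant
  expect_gt(max(calls$p_selection), 0.9)
  report <- assembly_report(calls)
  expect_true(any(grepl("label", report)))
  plt <- plot_assembly_quadrants(calls)
  expect_s3_class(plt, "ggplot")
})
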