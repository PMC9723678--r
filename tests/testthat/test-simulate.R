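one_taxon <- function(mu = 2.5, n0 = 1000) {
  tibble::tibble(taxon_id = "OTU_1", growth_rate = mu, initial_abundance = n0)
}

test_that("deterministic continuous culture converges to the washout fixed point", {
  sch <- regime_schedule("UUL", carrying_capacity = 1e5,
                         continuous_dilution_rate = 1,
                         crossover_day = 28, total_days = 40)
  traj <- simulate_microcosm(one_taxon(2.5, 1000), sch, step = 0.05,
                             demographic_drift = FALSE)
  n_end <- traj$states[1, length(traj$times)]
  # dN/dt = 0 at N = K (1 - D / mu) = 0.6 K
  expect_equal(n_end, 0.6 * 1e5, tolerance = 1e-3)
})

test_that("drift-free skeleton matches adaptive ODE integration within 1%", {
  sch <- regime_schedule("UUL", carrying_capacity = 5e4,
                         continuous_dilution_rate = 1,
                         crossover_day = 9, total_days = 10)
  traj <- simulate_microcosm(one_taxon(2.5, 500), sch, step = 0.01,
                             demographic_drift = FALSE)
  ode_fit <- deSolve::ode(
    y = c(n = 500), times = seq(0, 10, 0.5),
    func = function(t, y, p) list(y * (2.5 * (1 - y / 5e4) - 1))
  )
  at <- match(ode_fit[, "time"], round(traj$times, 8))
  rel_err <- abs(traj$states[1, at] - ode_fit[, "n"]) / ode_fit[, "n"]
  expect_lt(max(rel_err), 0.01)
})

test_that("each 1:50 dilution removes 49/50 of each taxon in expectation", {
  # near-zero growth isolates the binomial survival draws: inoculation
  # dilution then the day-2 pulse give E[N(2.5)] = N0 / 50^2
  sch <- regime_schedule("DDL", carrying_capacity = 1e12,
                         pulse_fraction = 1 / 50, pulse_interval = 2,
                         crossover_day = 2, total_days = 2.5)
  n0 <- 250000
  post <- vapply(1:2000, function(s) {
    traj <- simulate_microcosm(one_taxon(1e-8, n0), sch, step = 0.5,
                               seed = s, demographic_drift = TRUE,
                               microcosm_id = paste0("m", s))
    traj$states[1, traj$times == 2.5]
  }, numeric(1))
  se <- stats::sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - n0 / 2500), 3 * se)
})

test_that("neutral bottlenecks keep expected relative abundance constant", {
  sch <- regime_schedule("DDL", carrying_capacity = 1e12,
                         pulse_fraction = 1 / 50, pulse_interval = 2,
                         crossover_day = 2, total_days = 2.5)
  taxa <- tibble::tibble(taxon_id = c("a", "b"), growth_rate = c(1e-8, 1e-8),
                         initial_abundance = c(7e6, 3e6))
  rel <- vapply(1:1000, function(s) {
    traj <- simulate_microcosm(taxa, sch, step = 0.5, seed = s,
                               microcosm_id = paste0("m", s))
    st <- traj$states[, traj$times == 2.5]
    st[1] / sum(st)
  }, numeric(1))
  se <- stats::sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - 0.7), 3 * se + 1e-4)
})

test_that("growth between pulses is near-exponential when N << K", {
  sch <- regime_schedule("DDL", carrying_capacity = 1e9,
                         pulse_fraction = 1 / 50, pulse_interval = 2,
                         crossover_day = 1, total_days = 2)
  traj <- simulate_microcosm(one_taxon(2.5, 10000), sch, step = 0.05,
                             demographic_drift = FALSE)
  realised <- traj$states[1, traj$times == 1.5] / traj$states[1, traj$times == 0.5]
  expect_equal(realised, exp(2.5), tolerance = 0.05)
})

test_that("trajectories are reproducible and non-negative integers under drift", {
  sch <- regime_schedule("UDL", carrying_capacity = 5e3, crossover_day = 4,
                         total_days = 8)
  taxa <- taxon_profiles(8, total_abundance = 5e3, seed = 2)
  t1 <- simulate_microcosm(taxa, sch, seed = 11, microcosm_id = "m1")
  t2 <- simulate_microcosm(taxa, sch, seed = 11, microcosm_id = "m1")
  t3 <- simulate_microcosm(taxa, sch, seed = 12, microcosm_id = "m1")
  expect_identical(t1$states, t2$states)
  expect_false(identical(t1$states, t3$states))
  expect_true(all(t1$states >= 0))
  expect_true(all(t1$states == round(t1$states)))
})

test_that("an extinct community stays at zero without error", {
  sch <- regime_schedule("UUL", carrying_capacity = 100, crossover_day = 2,
                         total_days = 4)
  traj <- simulate_microcosm(one_taxon(2.5, 0), sch, seed = 1)
  expect_true(all(traj$states == 0))
})

test_that("between-replicate similarity is non-increasing in time under neutral drift", {
  sch <- regime_schedule("UUL", carrying_capacity = 5e3, crossover_day = 20,
                         total_days = 21)
  taxa <- taxon_profiles(20, total_abundance = 5e3, seed = 5)
  states <- lapply(1:6, function(r) {
    simulate_microcosm(taxa, sch, seed = 7, microcosm_id = paste0("r", r))
  })
  mean_bc <- function(day) {
    pairs <- utils::combn(6, 2)
    mean(apply(pairs, 2, function(p) {
      bray_curtis_similarity(
        states[[p[1]]]$states[, states[[p[1]]]$times == day],
        states[[p[2]]]$states[, states[[p[2]]]$times == day]
      )
    }))
  }
  expect_gt(mean_bc(2), mean_bc(20))
})

test_that("read sampling is multinomial at the requested depth", {
  expect_equal(sample_reads(c(0, 42, 0), depth = 10000, seed = 1),
               c(0L, 10000L, 0L))
  x <- sample_reads(c(3, 1, 7, 2), depth = 5000, seed = 2)
  expect_equal(sum(x), 5000)
  expect_error(sample_reads(c(0, 0), 100), "extinct")
  expect_error(sample_reads(c(1, 2), 0), "depth")
  # binomial moments: 70/30 community at depth 10,000
  counts <- vapply(1:1000, function(s) {
    sample_reads(c(70, 30), 10000, seed = s)[1]
  }, integer(1))
  se <- sqrt(10000 * 0.7 * 0.3) / sqrt(1000)
  expect_lt(abs(mean(counts) - 7000), 3 * se)
})

test_that("simulated experiments match the manifest and reproduce from seed", {
  sim <- tiny_experiment(seed = 4)
  expect_equal(ncol(sim$counts) - 1, nrow(sim$metadata))
  expect_identical(setdiff(names(sim$counts), "otu_id"),
                   sim$metadata$sample_id)
  sim2 <- tiny_experiment(seed = 4)
  expect_identical(sim$counts, sim2$counts)
  spec <- design_spec(regimes = "UUL", sampling_days = c(2, 4))
  expect_error(
    simulate_experiment(spec, taxon_profiles(3), schedules = list()),
    "No schedule"
  )
})

test_that("environmental noise perturbs trajectories without breaking integerness", {
  sch <- regime_schedule("UUL", carrying_capacity = 5e3, crossover_day = 4,
                         total_days = 6)
  taxa <- taxon_profiles(6, total_abundance = 5e3, seed = 3)
  t_env <- simulate_microcosm(taxa, sch, seed = 9, env_noise_sd = 0.3,
                              microcosm_id = "m")
  t_plain <- simulate_microcosm(taxa, sch, seed = 9, microcosm_id = "m")
  expect_false(identical(t_env$states, t_plain$states))
  expect_true(all(t_env$states >= 0 & t_env$states == round(t_env$states)))
})
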