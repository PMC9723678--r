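# Shared fixtures: everything is generated in code at test time.

# Small triplicate experiment for structural tests.
tiny_experiment <- function(seed = 1, n_taxa = 12,
                            regimes = c("UDL", "DUL"),
                            sampling_days = c(2, 6, 10)) {
  spec <- design_spec(regimes = regimes, replicates_per_regime = 3,
                      sampling_days = sampling_days, inoculum_samples = 0,
                      crossover_day = max(sampling_days),
                      total_days = max(sampling_days) + 1)
  taxa <- taxon_profiles(n_taxa = n_taxa, total_abundance = 2e4, seed = seed)
  sim <- simulate_experiment(spec, taxa, default_schedules(spec, k_low = 2e4),
                             seed = seed,
                             read_depth = list(mean = 5000, sd = 0, min = 1000))
  sim
}

# Similarity records simulated directly FROM the distributional model: the
# ground-truth generator for recovery and calibration checks.
# 3 pairs x 14 days x 2 disturbance regimes by default.
sim_model_records <- function(seed, beta_t = 0.01, gamma_t = -0.05,
                              beta_0 = 0.6, gamma_0 = log(0.05),
                              beta_disturbance = 0.05, tau = 0.03,
                              days = seq(2, 28, 2), n_pairs = 3) {
  set.seed(seed)
  grid <- tidyr::expand_grid(disturbance_at_sampling = c("U", "D"),
                             pair = seq_len(n_pairs), day = days)
  grid$comparison_id <- paste0(grid$disturbance_at_sampling, ":p", grid$pair)
  grid$regime_code <- paste0(grid$disturbance_at_sampling,
                             grid$disturbance_at_sampling, "L")
  grid$capacity <- "L"
  grid$period <- 1L
  grid$index <- "bray_curtis"
  grid$centered_day <- grid$day - mean(grid$day)
  b <- stats::rnorm(2 * n_pairs, 0, tau)
  names(b) <- unique(grid$comparison_id)
  mu <- beta_0 + beta_t * grid$centered_day +
    beta_disturbance * (grid$disturbance_at_sampling == "D") +
    b[grid$comparison_id]
  sig <- exp(gamma_0 + gamma_t * grid$centered_day)
  grid$similarity <- stats::rnorm(nrow(grid), mu, sig)
  grid
}

quick_mcmc <- function(seed = 1, retained = 1000) {
  mcmc_config(chains = 2, iterations_per_chain = 500 + retained / 2,
              warmup = 500, seed = seed)
}

quick_fit <- function(records, seed = 1,
                      spec = model_spec(~ centered_day * disturbance,
                                        ~centered_day), ...) {
  dat <- prepare_model_data(records, period = 1, spec = spec)
  suppressWarnings(fit_distributional_model(dat, quick_mcmc(seed),
                                            rhat_action = "none", ...))
}

# A count table whose columns are exact copies across replicates.
copied_replicate_table <- function() {
  m <- matrix(c(5, 3, 2, 0), nrow = 4, ncol = 6,
              dimnames = list(paste0("OTU_", 1:4),
                              c("AAL_r1_d02", "AAL_r2_d02", "AAL_r3_d02",
                                "AAL_r1_d04", "AAL_r2_d04", "AAL_r3_d04")))
  m[, 4:6] <- c(1, 1, 4, 4)
  md <- tibble::tibble(
    sample_id = colnames(m),
    microcosm_id = rep(paste0("AAL_r", 1:3), 2),
    regime_code = "UUL",
    disturbance_at_sampling = "U",
    capacity = "L",
    replicate = rep(1:3, 2),
    day = rep(c(2, 4), each = 3),
    period = 1L
  )
  list(counts = count_table(m), metadata = md)
}
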