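#' Taxon profiles for the microcosm simulator
#'
#' Builds the per-taxon parameter table the simulator consumes: an id, an
#' intrinsic growth rate, and an initial abundance (individuals in the
#' inoculum). Under the neutral scenario every taxon grows at the same rate
#' (default 2.5 per day) so only demographic drift differentiates replicates;
#' under the selection scenario growth rates are drawn log-normally around
#' that rate, giving fitness differences that deterministically favour the
#' fastest growers.
#'
#' @param n_taxa Number of taxa.
#' @param mean_growth_rate Community mean intrinsic growth rate (per day).
#' @param growth_rate_cv Coefficient of variation of growth rates across taxa;
#'   0 gives the neutral scenario.
#' @param total_abundance Total inoculum size (individuals).
#' @param abundance_sdlog Log-scale spread of the initial rank-abundance
#'   distribution.
#' @param seed Integer seed.
#' @return A tibble with columns `taxon_id`, `growth_rate`, `initial_abundance`.
#' @export
taxon_profiles <- function(n_taxa = 100,
                           mean_growth_rate = 2.5,
                           growth_rate_cv = 0,
                           total_abundance = 1e5,
                           abundance_sdlog = 1.5,
                           seed = 1) {
  if (n_taxa < 1) abort("`n_taxa` must be >= 1.")
  if (mean_growth_rate <= 0) abort("`mean_growth_rate` must be positive.")
  if (growth_rate_cv < 0) abort("`growth_rate_cv` must be >= 0.")
  with_seed(child_seed(seed, "taxa"), {
    w <- rlnorm(n_taxa, meanlog = 0, sdlog = abundance_sdlog)
    n0 <- as.integer(round(total_abundance * w / sum(w)))
    if (growth_rate_cv > 0) {
      sdlog <- sqrt(log(1 + growth_rate_cv^2))
      mu <- rlnorm(n_taxa, meanlog = log(mean_growth_rate) - sdlog^2 / 2,
                   sdlog = sdlog)
    } else {
      mu <- rep(mean_growth_rate, n_taxa)
    }
    tibble(
      taxon_id = sprintf("OTU_%04d", seq_len(n_taxa)),
      growth_rate = mu,
      initial_abundance = n0
    )
  })
}

validate_taxa <- function(taxa) {
  stopifnot(is.data.frame(taxa))
  need <- c("taxon_id", "growth_rate", "initial_abundance")
  miss <- setdiff(need, names(taxa))
  if (length(miss)) abort(paste0("`taxa` is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(taxa) == 0) abort("`taxa` must contain at least one taxon.")
  if (any(taxa$growth_rate <= 0)) abort("All growth rates must be positive.")
  if (any(taxa$initial_abundance < 0)) abort("Initial abundances must be non-negative.")
  invisible(taxa)
}

#' Dilution schedule for one cultivation regime
#'
#' Encodes how a microcosm is diluted over the experiment. An undisturbed
#' period receives medium continuously at `continuous_dilution_rate` (default
#' 1 per day); a disturbed period is instead pulsed, every `pulse_interval`
#' days, by a dilution that leaves each cell with survival probability
#' `pulse_fraction` (default 1/50). The regime switches at `crossover_day`.
#' Microcosms that are disturbed in period 1 are additionally 1:50 diluted at
#' inoculation (day 0), as in the crossover design this schedule models.
#'
#' @param regime_code Three-letter code, e.g. `"UDH"`: period-1 regime,
#'   period-2 regime, capacity level.
#' @param carrying_capacity Community carrying capacity K (individuals).
#' @param continuous_dilution_rate Washout rate during undisturbed periods
#'   (per day).
#' @param pulse_fraction Survival fraction at each pulse.
#' @param pulse_interval Days between pulses.
#' @param crossover_day Day after which the regime switches.
#' @param total_days Experiment length (days).
#' @return A `regime_schedule` list.
#' @export
regime_schedule <- function(regime_code,
                            carrying_capacity,
                            continuous_dilution_rate = 1,
                            pulse_fraction = 1 / 50,
                            pulse_interval = 2,
                            crossover_day = 28,
                            total_days = 50) {
  if (!grepl("^[UD][UD]", regime_code)) {
    abort("`regime_code` must start with two letters from {U, D}.")
  }
  if (carrying_capacity <= 0) abort("`carrying_capacity` must be positive.")
  if (continuous_dilution_rate < 0) abort("`continuous_dilution_rate` must be >= 0.")
  if (pulse_fraction <= 0 || pulse_fraction > 1) abort("`pulse_fraction` must be in (0, 1].")
  if (pulse_interval <= 0) abort("`pulse_interval` must be positive.")
  if (crossover_day >= total_days) abort("`crossover_day` must be < `total_days`.")
  structure(
    list(
      regime_code = regime_code,
      period1 = substr(regime_code, 1, 1),
      period2 = substr(regime_code, 2, 2),
      carrying_capacity = carrying_capacity,
      continuous_dilution_rate = continuous_dilution_rate,
      pulse_fraction = pulse_fraction,
      pulse_interval = pulse_interval,
      crossover_day = crossover_day,
      total_days = total_days
    ),
    class = "regime_schedule"
  )
}

#' Default schedules for a 2 x 2 crossover design
#'
#' One [regime_schedule()] per regime code, with the high carrying capacity
#' five times the low one (mirroring the 5-fold nutrient contrast).
#'
#' @param spec A [design_spec()].
#' @param k_low Low carrying capacity (individuals).
#' @param k_high High carrying capacity; default `5 * k_low`.
#' @param ... Passed to [regime_schedule()].
#' @return Named list of schedules, one per regime code in `spec`.
#' @export
default_schedules <- function(spec = design_spec(), k_low = 1e5,
                              k_high = 5 * k_low, ...) {
  scheds <- lapply(spec$regimes, function(code) {
    k <- if (substr(code, 3, 3) == "H") k_high else k_low
    regime_schedule(code, carrying_capacity = k,
                    crossover_day = spec$crossover_day,
                    total_days = spec$total_days, ...)
  })
  setNames(scheds, spec$regimes)
}

pulse_times <- function(schedule) {
  out <- numeric(0)
  if (schedule$period1 == "D" && schedule$pulse_interval <= schedule$crossover_day) {
    out <- c(out, seq(schedule$pulse_interval, schedule$crossover_day,
                      by = schedule$pulse_interval))
  }
  first2 <- schedule$crossover_day + schedule$pulse_interval
  if (schedule$period2 == "D" && first2 <= schedule$total_days) {
    out <- c(out, seq(first2, schedule$total_days,
                      by = schedule$pulse_interval))
  }
  out
}

#' Simulate one microcosm
#'
#' Discrete-time stochastic logistic community dynamics under a dilution
#' schedule. Each step of length `step` days the deterministic skeleton
#' updates every taxon as
#' `n_i <- n_i * exp(step * (mu_i * (1 - N / K) - D))`,
#' where `N` is the community total, `K` the carrying capacity and `D` the
#' continuous dilution rate in force (0 during pulsed periods). With
#' demographic drift enabled the realised abundance is then drawn as
#' `Poisson(mean)`, making stochasticity density-dependent; at each pulse
#' time every taxon's survivors are drawn binomially with probability
#' `pulse_fraction`. The state is recorded at every step, before any pulse
#' scheduled at that instant — matching sampling of disturbed communities
#' right before the dilution.
#'
#' Besides demographic (Poisson) noise, an optional environmental noise term
#' perturbs each taxon's per-step growth by a multiplicative log-normal
#' factor with standard deviation `env_noise_sd * sqrt(step)` — a diffusion
#' of log-abundances emulating micro-environmental fluctuation. At realistic
#' community sizes demographic noise alone is far weaker than the
#' replicate-to-replicate fluctuation real microcosms show, so this term
#' carries most of the fitness-independent stochasticity when enabled; it is
#' off by default.
#'
#' @param taxa A [taxon_profiles()] tibble.
#' @param schedule A [regime_schedule()].
#' @param step Time step (days); must divide the pulse interval.
#' @param seed Integer seed.
#' @param demographic_drift If `FALSE`, run the deterministic skeleton only
#'   (abundances stay real-valued; pulses multiply by `pulse_fraction`).
#' @param env_noise_sd Environmental noise intensity (per sqrt-day) on each
#'   taxon's growth rate; 0 disables it.
#' @param microcosm_id Label stored with the trajectory.
#' @return An `abundance_trajectory`: list with `times` (days), `states`
#'   (taxa x times matrix), `taxon_id`, `microcosm_id`.
#' @export
simulate_microcosm <- function(taxa, schedule, step = 0.05, seed = 1,
                               demographic_drift = TRUE,
                               env_noise_sd = 0,
                               microcosm_id = schedule$regime_code) {
  validate_taxa(taxa)
  stopifnot(inherits(schedule, "regime_schedule"))
  if (step <= 0) abort("`step` must be positive.")
  ratio <- schedule$pulse_interval / step
  if (abs(ratio - round(ratio)) > 1e-8) {
    abort("`step` must divide the pulse interval.")
  }
  n_steps <- round(schedule$total_days / step)
  times <- (0:n_steps) * step
  pulse_idx <- round(pulse_times(schedule) / step)
  crossover_step <- schedule$crossover_day / step

  mu <- taxa$growth_rate
  k <- schedule$carrying_capacity
  n <- as.numeric(taxa$initial_abundance)
  states <- matrix(0, nrow = nrow(taxa), ncol = n_steps + 1)

  with_seed(child_seed(seed, microcosm_id), {
    # Disturbed-at-start microcosms are 1:50 diluted upon inoculation.
    if (schedule$period1 == "D") {
      n <- if (demographic_drift) {
        as.numeric(rbinom(length(n), round(n), schedule$pulse_fraction))
      } else {
        n * schedule$pulse_fraction
      }
    }
    states[, 1] <- n
    is_pulse <- logical(n_steps + 1)
    is_pulse[pulse_idx + 1] <- TRUE
    for (s in seq_len(n_steps)) {
      # period of the interval (t_{s-1}, t_s]
      in_period1 <- (s - 1) < crossover_step
      mode <- if (in_period1) schedule$period1 else schedule$period2
      d_rate <- if (mode == "U") schedule$continuous_dilution_rate else 0
      total <- sum(n)
      growth <- step * (mu * (1 - total / k) - d_rate)
      if (env_noise_sd > 0) {
        growth <- growth + rnorm(length(n), 0, env_noise_sd * sqrt(step))
      }
      mean_next <- n * exp(growth)
      n <- if (demographic_drift) as.numeric(rpois(length(n), mean_next)) else mean_next
      states[, s + 1] <- n
      if (is_pulse[s + 1]) {
        n <- if (demographic_drift) {
          as.numeric(rbinom(length(n), round(n), schedule$pulse_fraction))
        } else {
          n * schedule$pulse_fraction
        }
      }
    }
  })
  structure(
    list(times = times, states = states, taxon_id = taxa$taxon_id,
         microcosm_id = microcosm_id),
    class = "abundance_trajectory"
  )
}

#' @export
as_tibble.abundance_trajectory <- function(x, ...) {
  tibble(
    microcosm_id = x$microcosm_id,
    taxon_id = rep(x$taxon_id, times = length(x$times)),
    day = rep(x$times, each = length(x$taxon_id)),
    abundance = as.vector(x$states)
  )
}

trajectory_state <- function(traj, day) {
  i <- which.min(abs(traj$times - day))
  if (abs(traj$times[i] - day) > 1e-6) {
    abort(sprintf("Day %s is not on the trajectory's time grid.", format(day)))
  }
  traj$states[, i]
}

#' Sample sequencing reads from a community
#'
#' Emulates amplicon sequencing: `depth` reads are drawn multinomially with
#' probabilities proportional to taxon abundances.
#'
#' @param abundances Non-negative abundance vector with positive total.
#' @param depth Number of reads.
#' @param seed Integer seed.
#' @return Integer vector of read counts summing to `depth`.
#' @export
sample_reads <- function(abundances, depth, seed = 1) {
  if (any(abundances < 0)) abort("`abundances` must be non-negative.")
  if (sum(abundances) <= 0) {
    abort("Cannot sequence an extinct community: all abundances are zero.")
  }
  if (depth < 1) abort("`depth` must be >= 1.")
  with_seed(child_seed(seed, "reads"), {
    as.integer(rmultinom(1, size = depth, prob = abundances))
  })
}

draw_read_depth <- function(read_depth, seed) {
  m <- read_depth$mean
  s <- read_depth$sd
  if (s <= 0) return(as.integer(round(m)))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  with_seed(seed, {
    d <- 0
    while (d < read_depth$min) d <- rlnorm(1, meanlog, sdlog)
    as.integer(round(d))
  })
}

#' Simulate a full sequencing experiment
#'
#' Composes [build_design()], [simulate_microcosm()] and [sample_reads()]:
#' every microcosm in the design is simulated under its regime's schedule,
#' each manifest sample is sequenced from the trajectory state at its
#' sampling day (disturbed microcosms are thereby sampled right before the
#' pulse), and inoculum samples are sequenced directly from the initial
#' abundance vector. Read depths are log-normal (defaults: mean 63,460,
#' SD 31,411) truncated below so every sample survives a 10,000-read
#' rarefaction. Fully reproducible from `seed`: each microcosm and sample
#' derives its own child seed, independent of iteration order.
#'
#' @param spec A [design_spec()].
#' @param taxa A [taxon_profiles()] tibble.
#' @param schedules Named list of [regime_schedule()]s, one per regime code.
#' @param seed Integer seed.
#' @param read_depth List with `mean`, `sd`, `min` of the per-sample read
#'   depth distribution.
#' @param step Simulation time step (days).
#' @param demographic_drift Enable demographic noise (see
#'   [simulate_microcosm()]).
#' @param env_noise_sd Environmental noise intensity (see
#'   [simulate_microcosm()]).
#' @return List with `counts` (count-table tibble: `otu_id` plus one column
#'   per sample) and `metadata` (the design manifest).
#' @export
simulate_experiment <- function(spec, taxa, schedules = default_schedules(spec),
                                seed = 1,
                                read_depth = list(mean = 63460, sd = 31411, min = 10000),
                                step = 0.05,
                                demographic_drift = TRUE,
                                env_noise_sd = 0) {
  validate_taxa(taxa)
  miss <- setdiff(spec$regimes, names(schedules))
  if (length(miss)) {
    abort(paste0("No schedule supplied for regime(s): ", paste(miss, collapse = ", ")))
  }
  manifest <- build_design(spec)
  trajs <- list()
  for (code in spec$regimes) {
    for (r in seq_len(spec$replicates_per_regime)) {
      id <- paste0(code, "_r", r)
      trajs[[id]] <- simulate_microcosm(
        taxa, schedules[[code]], step = step, seed = seed,
        demographic_drift = demographic_drift, env_noise_sd = env_noise_sd,
        microcosm_id = id
      )
    }
  }
  counts <- matrix(0L, nrow = nrow(taxa), ncol = nrow(manifest),
                   dimnames = list(taxa$taxon_id, manifest$sample_id))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    abund <- if (row$microcosm_id == "inoculum") {
      taxa$initial_abundance
    } else {
      trajectory_state(trajs[[row$microcosm_id]], row$day)
    }
    sseed <- child_seed(seed, row$sample_id)
    depth <- draw_read_depth(read_depth, sseed)
    counts[, i] <- sample_reads(abund, depth, seed = sseed)
  }
  list(
    counts = count_table(counts),
    metadata = manifest
  )
}
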