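#' Experimental design specification
#'
#' Describes a dilution-disturbance crossover experiment: which cultivation
#' regimes are run, how many replicate microcosms each has, on which days the
#' communities are sampled, and how many inoculum samples are taken at day 0.
#'
#' Regime codes are three letters: the disturbance regime in period 1
#' (`U` continuous dilution, `D` pulsed 1:50 dilution), the regime in period 2
#' after the crossover, and the carrying-capacity level (`H` or `L`). The
#' default design is the 2 x 2 factorial crossover: `UDH`, `UDL`, `DUH`, `DUL`,
#' three replicates each, 17 sampling days over 50 days, plus 2 inoculum
#' samples, for 206 samples in total.
#'
#' @param regimes Character vector of regime codes.
#' @param replicates_per_regime Number of replicate microcosms per regime.
#' @param sampling_days Strictly increasing numeric vector of sampling days.
#' @param inoculum_samples Number of day-0 inoculum samples.
#' @param crossover_day Day after which the disturbance regime switches.
#' @param total_days Length of the experiment in days.
#' @return A `design_spec` list.
#' @export
#' @examples
#' spec <- design_spec()
#' nrow(build_design(spec)) # 206
design_spec <- function(regimes = c("UDH", "UDL", "DUH", "DUL"),
                        replicates_per_regime = 3,
                        sampling_days = default_sampling_days(),
                        inoculum_samples = 2,
                        crossover_day = 28,
                        total_days = 50) {
  if (length(regimes) == 0) {
    abort("`regimes` must contain at least one regime code.")
  }
  if (anyDuplicated(regimes)) {
    abort("`regimes` must be unique.")
  }
  bad <- !grepl("^[UD][UD][HL]$", regimes)
  if (any(bad)) {
    abort(paste0("Invalid regime code(s): ", paste(regimes[bad], collapse = ", "),
                 " (expected e.g. 'UDH': period-1 regime, period-2 regime, capacity)."))
  }
  if (length(sampling_days) == 0 || any(diff(sampling_days) <= 0)) {
    abort("`sampling_days` must be non-empty and strictly increasing.")
  }
  if (replicates_per_regime < 1) {
    abort("`replicates_per_regime` must be >= 1.")
  }
  if (inoculum_samples < 0) {
    abort("`inoculum_samples` must be >= 0.")
  }
  if (crossover_day >= total_days) {
    abort("`crossover_day` must be smaller than `total_days`.")
  }
  structure(
    list(
      regimes = regimes,
      replicates_per_regime = as.integer(replicates_per_regime),
      sampling_days = sampling_days,
      inoculum_samples = as.integer(inoculum_samples),
      crossover_day = crossover_day,
      total_days = total_days
    ),
    class = "design_spec"
  )
}

#' Default sampling days
#'
#' 17 days spread over the 50-day experiment at roughly 3-day intervals,
#' including the crossover day (28) and the final day (50).
#' @return Numeric vector of length 17.
#' @export
default_sampling_days <- function() {
  c(2, 5, 8, 11, 14, 17, 20, 23, 26, 28, 31, 34, 37, 40, 43, 46, 50)
}

#' Build the sample manifest for a design
#'
#' Expands a [design_spec()] into one manifest row per (regime, replicate,
#' sampling day), plus one row per inoculum sample. Each row records the
#' disturbance regime in force at that day (the first letter of the regime
#' code up to and including the crossover day, the second letter after it),
#' the capacity level, the cultivation period, and a stable microcosm id.
#' Inoculum rows carry `NA` design labels, day 0 and period 0.
#'
#' @param spec A [design_spec()].
#' @return A tibble with columns `sample_id`, `microcosm_id`, `regime_code`,
#'   `disturbance_at_sampling`, `capacity`, `replicate`, `day`, `period`.
#' @export
build_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- tidyr::expand_grid(
    regime_code = spec$regimes,
    replicate = seq_len(spec$replicates_per_regime),
    day = spec$sampling_days
  )
  manifest <- grid %>%
    mutate(
      microcosm_id = paste0(.data$regime_code, "_r", .data$replicate),
      period = ifelse(.data$day <= spec$crossover_day, 1L, 2L),
      disturbance_at_sampling = ifelse(
        .data$period == 1L,
        substr(.data$regime_code, 1, 1),
        substr(.data$regime_code, 2, 2)
      ),
      capacity = substr(.data$regime_code, 3, 3),
      sample_id = sprintf("%s_d%02d", .data$microcosm_id, as.integer(round(.data$day)))
    ) %>%
    select("sample_id", "microcosm_id", "regime_code",
           "disturbance_at_sampling", "capacity", "replicate", "day", "period")
  if (spec$inoculum_samples > 0) {
    inoc <- tibble(
      sample_id = sprintf("inoculum_%d", seq_len(spec$inoculum_samples)),
      microcosm_id = "inoculum",
      regime_code = NA_character_,
      disturbance_at_sampling = NA_character_,
      capacity = NA_character_,
      replicate = NA_integer_,
      day = 0,
      period = 0L
    )
    manifest <- bind_rows(inoc, manifest)
  }
  manifest
}

#' Continuous-rate equivalent of a pulsed dilution
#'
#' A pulse that leaves a survival fraction f every `interval` days removes
#' biomass at the same average rate as continuous dilution at
#' `-log(f) / interval` per day. The study's 1:50 pulse every 2nd day is
#' equivalent to roughly 2 per day.
#'
#' @param pulse_fraction Survival fraction at each pulse (e.g. 1/50).
#' @param pulse_interval Days between pulses.
#' @return Equivalent continuous dilution rate (per day).
#' @export
#' @examples
#' pulse_equivalent_rate(1 / 50, 2) # ~1.96 day^-1
pulse_equivalent_rate <- function(pulse_fraction, pulse_interval) {
  if (pulse_fraction <= 0 || pulse_fraction > 1) {
    abort("`pulse_fraction` must be in (0, 1].")
  }
  if (pulse_interval <= 0) abort("`pulse_interval` must be positive.")
  -log(pulse_fraction) / pulse_interval
}
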