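#' Model specification for the assembly regression
#'
#' The assembly model is a distributional regression: replicate similarity
#' `y` is Normal with both its mean and its standard deviation depending on
#' covariates,
#' `y ~ Normal(X beta + b_pair, g^-1(Z gamma))`, `b_pair ~ Normal(0, tau)`.
#' `mean_formula` builds `X` (default: all interactions of centred day,
#' disturbance and capacity up to 3-way); `sigma_formula` builds `Z`
#' (default: centred day by disturbance); the random intercept is per
#' replicate comparison. Factors use treatment coding with reference levels
#' `U` (undisturbed) and `L` (low capacity), so the reference group's daily
#' slope is the bare `centered_day` coefficient. The link `g` for sigma is
#' log by default; the slope-sign classification is invariant to any
#' monotone link.
#'
#' @param mean_formula RHS formula for the mean; must involve `centered_day`.
#' @param sigma_formula RHS formula for the (link-scale) standard deviation.
#' @param group Name of the grouping column for the random intercept.
#' @param sigma_link `"log"` (default) or `"identity"`.
#' @param prior_scale_multiplier Multiplier for the weakly-informative prior
#'   scales (see [fit_distributional_model()]).
#' @return A `model_spec` list.
#' @export
model_spec <- function(mean_formula = ~ centered_day * disturbance * capacity,
                       sigma_formula = ~ centered_day * disturbance,
                       group = "comparison_id",
                       sigma_link = c("log", "identity"),
                       prior_scale_multiplier = 2.5) {
  sigma_link <- match.arg(sigma_link)
  if (!"centered_day" %in% all.vars(mean_formula)) {
    abort("`mean_formula` must include `centered_day`.")
  }
  structure(
    list(mean_formula = mean_formula, sigma_formula = sigma_formula,
         group = group, sigma_link = sigma_link,
         prior_scale_multiplier = prior_scale_multiplier),
    class = "model_spec"
  )
}

#' MCMC configuration
#'
#' Defaults follow the analysis this package implements: 4 chains of 4,000
#' iterations each with 2,000 discarded as warm-up, retaining 8,000 posterior
#' draws. `target_acceptance` is part of the interface for Hamiltonian Monte
#' Carlo backends; the Gibbs sampler used here has no acceptance-rate tuning
#' and ignores it.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations_per_chain Total iterations per chain.
#' @param warmup Warm-up iterations discarded per chain.
#' @param target_acceptance HMC target acceptance probability (unused by the
#'   Gibbs backend; kept for interface compatibility).
#' @param seed Integer seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iterations_per_chain = 4000,
                        warmup = 2000, target_acceptance = 0.99, seed = 1) {
  if (chains < 2) abort("`chains` must be >= 2.")
  if (warmup >= iterations_per_chain) {
    abort("`warmup` must be smaller than `iterations_per_chain`.")
  }
  structure(
    list(chains = as.integer(chains),
         iterations_per_chain = as.integer(iterations_per_chain),
         warmup = as.integer(warmup),
         target_acceptance = target_acceptance,
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

#' Retained posterior draws implied by a configuration
#' @param config An [mcmc_config()].
#' @return Integer: `chains * (iterations_per_chain - warmup)`.
#' @export
retained_draws <- function(config) {
  config$chains * (config$iterations_per_chain - config$warmup)
}

#' Prepare similarity records for model fitting
#'
#' Selects one cultivation period of one similarity index, recomputes
#' `centered_day` within the selected records (so its mean is exactly zero
#' over the data entering the fit), sets treatment-coded factors
#' (`disturbance`: U reference, `capacity`: L reference), and builds the
#' design matrices for the mean and sigma models plus the random-intercept
#' grouping.
#'
#' @param records A [replicate_similarity_series()] tibble.
#' @param period Cultivation period to model (1 or 2); `NULL` keeps all.
#' @param spec A [model_spec()].
#' @param index Similarity index to keep if `records` holds several.
#' @return An `assembly_model_data` list: `y`, `X`, `Z`, `group`, `records`,
#'   `spec`.
#' @export
prepare_model_data <- function(records, period = 1, spec = model_spec(),
                               index = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(index)) {
    records <- records %>% filter(.data$index == !!index)
  }
  if (length(unique(records$index)) > 1) {
    abort("`records` mixes similarity indices; pass `index` to pick one.")
  }
  if (!is.null(period)) {
    records <- records %>% filter(.data$period == !!period)
  }
  if (nrow(records) == 0) abort("No records left after period/index selection.")
  df <- records %>%
    mutate(
      centered_day = .data$day - mean(.data$day),
      disturbance = factor(.data$disturbance_at_sampling, levels = c("U", "D")),
      capacity = factor(.data$capacity, levels = c("L", "H"))
    )
  used <- union(all.vars(spec$mean_formula), all.vars(spec$sigma_formula))
  for (v in intersect(used, c("disturbance", "capacity"))) {
    if (length(unique(as.character(df[[v]]))) < 2) {
      abort(paste0("Factor `", v, "` has a single observed level in the data; ",
                   "drop it from the model formulas."))
    }
  }
  x <- model.matrix(spec$mean_formula, df)
  z <- model.matrix(spec$sigma_formula, df)
  grp <- factor(df[[spec$group]])
  structure(
    list(y = df$similarity, X = x, Z = z, group = grp,
         records = df, spec = spec),
    class = "assembly_model_data"
  )
}
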