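#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembly-model fit
#'
#' One row per model parameter with posterior mean, SD, central credible
#' interval, split R-hat and effective sample size.
#'
#' @param x An `assembly_fit`.
#' @param conf_level Credible-interval mass; default 0.95.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`, `ess`.
#' @method tidy assembly_fit
#' @export
tidy.assembly_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  tibble(
    term = colnames(x$draws),
    estimate = apply(x$draws, 2, mean),
    std.error = apply(x$draws, 2, sd),
    conf.low = apply(x$draws, 2, quantile, probs = a, names = FALSE),
    conf.high = apply(x$draws, 2, quantile, probs = 1 - a, names = FALSE)
  ) %>%
    left_join(x$diagnostics %>% select(term = "parameter", "rhat", "ess"),
              by = "term")
}

#' Glance at an assembly-model fit
#'
#' @param x An `assembly_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `n_groups`, `n_draws`, `n_chains`,
#'   `max_rhat`, `min_ess`, `elpd_waic`.
#' @method glance assembly_fit
#' @export
glance.assembly_fit <- function(x, ...) {
  tibble(
    n_obs = length(x$data$y),
    n_groups = nlevels(x$data$group),
    n_draws = nrow(x$draws),
    n_chains = x$config$chains,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    elpd_waic = waic(x$log_lik)$elpd
  )
}

#' @method tidy group_slopes
#' @export
tidy.group_slopes <- function(x, ...) {
  bind_rows(
    x$mu %>% mutate(quantity = "delta_mu"),
    x$sigma %>% mutate(quantity = "delta_sigma")
  ) %>% select("quantity", dplyr::everything())
}

#' @export
print.assembly_fit <- function(x, ...) {
  cat("Hierarchical distributional regression of replicate similarity\n")
  cat(sprintf("  observations: %d  pairs: %d  draws: %d (%d chains)\n",
              length(x$data$y), nlevels(x$data$group), nrow(x$draws),
              x$config$chains))
  cat(sprintf("  max split R-hat: %.3f\n",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  print(tidy(x) %>% filter(!startsWith(.data$term, "b[")), ...)
  invisible(x)
}
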