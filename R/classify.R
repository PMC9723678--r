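#' Classify community assembly from slope signs
#'
#' The quadrant rule: assembly is dominated by **selection** when the daily
#' slope of expected replicate similarity is non-negative and the daily
#' slope of its standard deviation is strictly negative
#' (`delta_mu >= 0, delta_sigma < 0` — replicates converge and tighten);
#' by **drift** when the mean slope is negative and the sigma slope strictly
#' positive (`delta_mu < 0, delta_sigma > 0` — replicates diverge and
#' spread); and **mixed** otherwise. A sigma slope of exactly zero is
#' classified as mixed: the verbal rule ("non-positive") and its inline
#' notation ("< 0") disagree on this boundary, and the strict inequality is
#' implemented. The sign of `delta_sigma` is invariant to the monotone link
#' used for the sigma model, so the label does not depend on that choice.
#'
#' @param delta_mu Daily slope(s) of the expected replicate similarity.
#' @param delta_sigma Daily slope(s) of the (link-scale) standard deviation.
#' @return Character vector: `"selection"`, `"drift"`, or `"mixed"`.
#' @export
#' @examples
#' classify_assembly(0.011, -0.054) # selection
#' classify_assembly(-0.015, 0.061) # drift
classify_assembly <- function(delta_mu, delta_sigma) {
  if (length(delta_mu) != length(delta_sigma)) {
    abort("`delta_mu` and `delta_sigma` must have equal length.")
  }
  if (any(!is.finite(delta_mu)) || any(!is.finite(delta_sigma))) {
    abort("Slope estimates must be finite.")
  }
  dplyr::case_when(
    delta_mu >= 0 & delta_sigma < 0 ~ "selection",
    delta_mu < 0 & delta_sigma > 0 ~ "drift",
    TRUE ~ "mixed"
  )
}

#' Posterior mass in each slope-sign quadrant
#'
#' An uncertainty-aware complement to the point-estimate rule of
#' [classify_assembly()]: the fraction of paired posterior draws falling in
#' each of the four (sign of `delta_mu`, sign of `delta_sigma`) quadrants.
#'
#' @param mu_draws,sigma_draws Equal-length paired posterior slope draws
#'   from one fit.
#' @return One-row tibble: `p_selection` (mu >= 0, sigma < 0), `p_drift`
#'   (mu < 0, sigma >= 0), `p_converge_spread` (mu >= 0, sigma >= 0),
#'   `p_diverge_tighten` (mu < 0, sigma < 0). The four sum to 1.
#' @export
quadrant_probabilities <- function(mu_draws, sigma_draws) {
  if (length(mu_draws) != length(sigma_draws)) {
    abort("Slope draws must be paired (equal length, same fit).")
  }
  tibble(
    p_selection = mean(mu_draws >= 0 & sigma_draws < 0),
    p_drift = mean(mu_draws < 0 & sigma_draws >= 0),
    p_converge_spread = mean(mu_draws >= 0 & sigma_draws >= 0),
    p_diverge_tighten = mean(mu_draws < 0 & sigma_draws < 0)
  )
}

#' Assembly calls for every experimental group
#'
#' Pairs each mean-slope group with its sigma-slope group (matched on the
#' design columns the two models share, e.g. disturbance), labels it with
#' [classify_assembly()] applied to the posterior mean slopes, and appends
#' the posterior quadrant probabilities computed from the paired draws.
#'
#' @param slopes A [derive_group_slopes()] object.
#' @return Tibble: group columns, `delta_mu_mean`, `delta_mu_sd`,
#'   `delta_sigma_mean`, `delta_sigma_sd`, `label`, and the four quadrant
#'   probabilities.
#' @export
assembly_calls <- function(slopes) {
  stopifnot(inherits(slopes, "group_slopes"))
  draws <- attr(slopes, "draws")
  mu <- slopes$mu
  sg <- slopes$sigma
  shared <- intersect(setdiff(names(mu), c("group", "mean", "sd",
                                           grep("^ci", names(mu), value = TRUE))),
                      setdiff(names(sg), c("group", "mean", "sd",
                                           grep("^ci", names(sg), value = TRUE))))
  purrr::map_dfr(seq_len(nrow(mu)), function(i) {
    match_row <- if (length(shared)) {
      hits <- rep(TRUE, nrow(sg))
      for (v in shared) hits <- hits & sg[[v]] == mu[[v]][i]
      which(hits)
    } else {
      seq_len(nrow(sg))
    }
    if (length(match_row) != 1) {
      abort("Could not pair a mean-slope group with a unique sigma-slope group.")
    }
    md <- draws$mu[, mu$group[i]]
    sd_ <- draws$sigma[, sg$group[match_row]]
    bind_cols(
      mu[i, c("group", shared), drop = FALSE],
      tibble(
        delta_mu_mean = mu$mean[i], delta_mu_sd = mu$sd[i],
        delta_sigma_mean = sg$mean[match_row], delta_sigma_sd = sg$sd[match_row],
        label = classify_assembly(mu$mean[i], sg$mean[match_row])
      ),
      quadrant_probabilities(md, sd_)
    )
  })
}

#' Plain-text assembly report
#'
#' @param calls An [assembly_calls()] tibble.
#' @return Character vector of report lines (also printed).
#' @export
assembly_report <- function(calls) {
  lines <- c(
    "Community assembly calls (quadrant rule on posterior mean slopes)",
    strrep("-", 66),
    sprintf("%-12s  %12s  %12s  %-9s  %11s",
            "group", "d_mu/day", "d_sigma/day", "label", "P(label)"),
    vapply(seq_len(nrow(calls)), function(i) {
      p <- switch(calls$label[i],
                  selection = calls$p_selection[i],
                  drift = calls$p_drift[i],
                  NA_real_)
      sprintf("%-12s  %12.4g  %12.4g  %-9s  %11s",
              calls$group[i], calls$delta_mu_mean[i], calls$delta_sigma_mean[i],
              calls$label[i],
              if (is.na(p)) "-" else sprintf("%.2f", p))
    }, character(1))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Quadrant plot of assembly calls
#'
#' Places each group's posterior mean slopes in the
#' (`delta_mu`, `delta_sigma`) plane, with the drift quadrant (upper left)
#' and selection half-plane (lower, `delta_sigma < 0`, `delta_mu >= 0`)
#' shaded, and 1-SD error bars.
#'
#' @param calls An [assembly_calls()] tibble.
#' @return A ggplot.
#' @export
plot_assembly_quadrants <- function(calls) {
  rng_x <- max(abs(calls$delta_mu_mean) + calls$delta_mu_sd) * 1.2
  rng_y <- max(abs(calls$delta_sigma_mean) + calls$delta_sigma_sd) * 1.2
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$delta_mu_mean,
                                      y = .data$delta_sigma_mean)) +
    ggplot2::annotate("rect", xmin = -rng_x, xmax = 0, ymin = 0, ymax = rng_y,
                      fill = "darkgreen", alpha = 0.15) +
    ggplot2::annotate("rect", xmin = 0, xmax = rng_x, ymin = -rng_y, ymax = 0,
                      fill = "deeppink", alpha = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$delta_sigma_mean - .data$delta_sigma_sd,
      ymax = .data$delta_sigma_mean + .data$delta_sigma_sd), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$delta_mu_mean - .data$delta_mu_sd,
      xmax = .data$delta_mu_mean + .data$delta_mu_sd), height = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 3) +
    ggplot2::labs(x = "Change in replicate similarity (per day)",
                  y = "Change in similarity SD (link scale, per day)",
                  colour = "Assembly") +
    ggplot2::theme_minimal()
}
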