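#' Predictive-density model comparison
#'
#' Estimates each fit's expected log pointwise predictive density (elpd) by
#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#' (PSIS-LOO) and ranks the models. When the Pareto-tail diagnostic fails
#' for a model (any shape estimate k > 0.7, meaning the importance weights
#' are too heavy-tailed to smooth reliably), that model falls back to WAIC
#' with a warning. All fits must share the identical observation set.
#'
#' @param fits Named list of [fit_distributional_model()] objects.
#' @return Tibble ranked by `elpd`: `model`, `elpd`, `se_elpd`, `p_eff`,
#'   `method`, `max_pareto_k`, `elpd_diff`, `se_diff` (paired difference to
#'   the top model).
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  y0 <- fits[[1]]$data$y
  for (f in fits) {
    stopifnot(inherits(f, "assembly_fit"))
    if (length(f$data$y) != length(y0) || any(f$data$y != y0)) {
      abort("All fits must be on the identical observation set.")
    }
  }
  per <- purrr::map(fits, function(f) {
    res <- psis_loo(f$log_lik)
    if (res$max_k > 0.7) {
      warn(sprintf("Pareto k diagnostic failed (max k = %.2f); using WAIC.",
                   res$max_k))
      w <- waic(f$log_lik)
      list(pointwise = w$pointwise, elpd = w$elpd, se = w$se,
           p_eff = w$p_eff, method = "waic", max_k = res$max_k)
    } else {
      res
    }
  })
  out <- purrr::imap_dfr(per, function(r, nm) {
    tibble(model = nm, elpd = r$elpd, se_elpd = r$se, p_eff = r$p_eff,
           method = r$method, max_pareto_k = r$max_k)
  }) %>% arrange(dplyr::desc(.data$elpd))
  best <- out$model[1]
  out %>% mutate(
    elpd_diff = .data$elpd - out$elpd[1],
    se_diff = unname(vapply(.data$model, function(m) {
      d <- per[[m]]$pointwise - per[[best]]$pointwise
      sqrt(length(d) * var(d))
    }, numeric(1)))
  )
}

#' PSIS-LOO for a pointwise log-likelihood matrix
#'
#' @param log_lik Draws x observations matrix of pointwise log-likelihoods.
#' @return List: `pointwise` elpd contributions, `elpd`, `se`, `p_eff`,
#'   `pareto_k` per observation, `max_k`, `method`.
#' @export
psis_loo <- function(log_lik) {
  s <- nrow(log_lik)
  n <- ncol(log_lik)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  lpd_i <- apply(log_lik, 2, log_sum_exp) - log(s)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-log_lik[, i])
    k_i[i] <- sm$k
    lw <- sm$log_weights
    elpd_i[i] <- log_sum_exp(lw + log_lik[, i]) - log_sum_exp(lw)
  }
  list(
    pointwise = elpd_i,
    elpd = sum(elpd_i),
    se = sqrt(n * var(elpd_i)),
    p_eff = sum(lpd_i - elpd_i),
    pareto_k = k_i,
    max_k = max(k_i),
    method = "psis_loo"
  )
}

#' WAIC for a pointwise log-likelihood matrix
#' @inheritParams psis_loo
#' @return List: `pointwise`, `elpd`, `se`, `p_eff`.
#' @export
waic <- function(log_lik) {
  s <- nrow(log_lik)
  lpd_i <- apply(log_lik, 2, log_sum_exp) - log(s)
  p_i <- apply(log_lik, 2, var)
  elpd_i <- lpd_i - p_i
  list(pointwise = elpd_i, elpd = sum(elpd_i),
       se = sqrt(ncol(log_lik) * var(elpd_i)), p_eff = sum(p_i))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one vector of log importance ratios. Returns smoothed,
# max-normalised log weights and the generalized-Pareto shape estimate.
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (m < 5) {
    return(list(log_weights = lw, k = Inf))
  }
  ord <- order(lw)
  tail_idx <- ord[(s - m + 1):s]
  cutoff <- lw[ord[s - m]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exceed <= 0) || sd(exceed) == 0) {
    return(list(log_weights = lw, k = -Inf))
  }
  fit <- gpd_fit(sort(exceed))
  k <- fit$k
  if (is.finite(k)) {
    # replace the tail by expected order statistics of the fitted GPD
    pp <- (seq_len(m) - 0.5) / m
    smoothed <- log(exp(cutoff) + qgpd(pp, fit$k, fit$sigma))
    lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  }
  list(log_weights = lw, k = k)
}

# Zhang & Stephens (2009) profile-likelihood fit of the generalized Pareto
# distribution, with the small-sample shape regularisation used for PSIS.
gpd_fit <- function(x) {
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w_j <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), numeric(1))
  theta_hat <- sum(theta * w_j)
  # convert to the standard tail-shape convention (xi > 0 = heavy tail)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # regularise k towards 0.5 (weak prior, stabilises small tails)
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) {
    -sigma * log1p(-p)
  } else {
    sigma * ((1 - p)^(-k) - 1) / k
  }
}
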