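#' Multi-rarefaction normalisation
#'
#' Normalises a count table by averaging many rarefied datasets: for each
#' sample, `n_rep` independent subsamples of exactly `depth` reads are drawn
#' without replacement (multivariate hypergeometric) and averaged
#' elementwise. Every output column sums to exactly `depth`; output values
#' are real-valued and deliberately not re-rounded, since rounding would
#' break that column-sum invariant. Samples with fewer than `depth` total
#' reads are dropped with a warning.
#'
#' @param tbl A count-table tibble of integer counts.
#' @param depth Rarefaction depth (reads per sample); default 10,000.
#' @param n_rep Number of rarefied datasets to average; default 1,000.
#' @param seed Integer seed.
#' @return A count-table tibble of averaged rarefied counts.
#' @export
rarefy_mean <- function(tbl, depth = 10000, n_rep = 1000, seed = 1) {
  tbl <- validate_count_table(tbl)
  if (depth <= 0) abort("`depth` must be positive.")
  if (n_rep <= 0) abort("`n_rep` must be positive.")
  m <- counts_matrix(tbl)
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("rarefy_mean() requires integer counts.")
  }
  m <- round(m)
  totals <- colSums(m)
  shallow <- totals < depth
  if (all(shallow)) abort("Every sample is shallower than the rarefaction depth.")
  if (any(shallow)) {
    warn(sprintf("Dropping %d sample(s) below depth %d: %s",
                 sum(shallow), depth,
                 paste(colnames(m)[shallow], collapse = ", ")))
    m <- m[, !shallow, drop = FALSE]
  }
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m),
                dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    with_seed(child_seed(seed, "rarefy", colnames(m)[j]), {
      out[, j] <- rowMeans(rmvhyper(m[, j], depth, n_rep))
    })
  }
  count_table(out)
}

# n_rep draws from the multivariate hypergeometric: sample `depth` reads
# without replacement from an urn with `counts[i]` reads of taxon i.
# Sequential conditional hypergeometrics, vectorised over replicates.
rmvhyper <- function(counts, depth, n_rep) {
  s <- length(counts)
  out <- matrix(0, nrow = s, ncol = n_rep)
  need <- rep(depth, n_rep)
  rest <- sum(counts)
  for (i in seq_len(s)) {
    if (counts[i] == 0) next
    rest <- rest - counts[i]
    x <- rhyper(n_rep, counts[i], rest, need)
    out[i, ] <- x
    need <- need - x
    if (all(need == 0)) break
  }
  out
}

#' Hill diversity
#'
#' Effective number of taxa of order `q`: with relative abundances `p_i` over
#' taxa with nonzero counts, `(sum p_i^q)^(1/(1-q))` for `q != 1` and
#' `exp(-sum p_i log p_i)` at `q = 1`. Order 0 is richness, order 1 the
#' exponential of Shannon entropy, order 2 the inverse Simpson concentration.
#'
#' @param counts Non-negative abundance vector, not all zero.
#' @param q Diversity order, `>= 0`.
#' @return Effective number of taxa, in `[1, S]`.
#' @export
#' @examples
#' hill_diversity(c(50, 30, 20), 2) # 1 / (0.25 + 0.09 + 0.04)
hill_diversity <- function(counts, q) {
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  if (sum(counts) <= 0) abort("Hill diversity is undefined for an all-zero community.")
  if (q < 0) abort("`q` must be >= 0.")
  p <- counts[counts > 0] / sum(counts)
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Per-sample Hill diversity of a count table
#'
#' @param tbl A count-table tibble.
#' @param q Vector of diversity orders; default 0, 1, 2.
#' @return Long tibble with columns `sample_id`, `q`, `diversity`.
#' @export
hill_diversity_table <- function(tbl, q = c(0, 1, 2)) {
  m <- counts_matrix(tbl)
  purrr::map_dfr(q, function(qq) {
    tibble(
      sample_id = colnames(m),
      q = qq,
      diversity = apply(m, 2, hill_diversity, q = qq)
    )
  })
}
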