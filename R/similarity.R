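#' Pairwise community similarity indices
#'
#' `bray_curtis_similarity()` is the abundance-based index
#' `1 - sum|x_i - y_i| / sum(x_i + y_i)`; `sorensen_similarity()` is its
#' presence/absence counterpart `2a / (2a + b + c)` with `a` shared taxa and
#' `b`, `c` the taxa unique to each sample. Both lie in `[0, 1]`, are
#' symmetric, and are invariant to rescaling both vectors by the same
#' positive constant.
#'
#' @param x,y Equal-length non-negative abundance vectors, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis_similarity(c(6, 2, 0), c(2, 2, 4)) # 0.5
#' sorensen_similarity(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 1)) # 4/7
bray_curtis_similarity <- function(x, y) {
  check_similarity_input(x, y)
  1 - sum(abs(x - y)) / sum(x + y)
}

#' @rdname bray_curtis_similarity
#' @export
sorensen_similarity <- function(x, y) {
  check_similarity_input(x, y)
  bray_curtis_similarity(as.numeric(x > 0), as.numeric(y > 0))
}

check_similarity_input <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x < 0) || any(y < 0)) abort("Abundances must be non-negative.")
  if (sum(x) + sum(y) <= 0) {
    abort("Similarity is undefined when both communities are empty.")
  }
  invisible(TRUE)
}

similarity_fun <- function(index) {
  switch(index,
    bray_curtis = bray_curtis_similarity,
    sorensen = sorensen_similarity,
    abort(paste0("Unknown similarity index: ", index))
  )
}

#' Replicate-pair similarity time series
#'
#' The response variable of the assembly model: for every regime and sampling
#' day, the community similarity between all unordered pairs of replicate
#' microcosms. With triplicates this gives exactly three comparisons per
#' regime-day. Pair identifiers are stable across days (sorted replicate
#' labels), and `centered_day` is the day minus the mean day of the records
#' within the same period — the covariate the model is fitted on.
#'
#' @param tbl A count-table tibble (typically the averaged-rarefied table).
#' @param metadata Paired metadata tibble; inoculum rows are ignored.
#' @param index `"bray_curtis"`, `"sorensen"`, or both.
#' @return Tibble with columns `comparison_id`, `regime_code`,
#'   `disturbance_at_sampling`, `capacity`, `day`, `period`, `centered_day`,
#'   `index`, `similarity`.
#' @export
replicate_similarity_series <- function(tbl, metadata,
                                        index = c("bray_curtis", "sorensen")) {
  tbl <- validate_count_table(tbl)
  metadata <- validate_metadata(metadata)
  check_paired(tbl, metadata)
  index <- match.arg(index, several.ok = TRUE)
  md <- metadata %>% filter(.data$microcosm_id != "inoculum")
  m <- counts_matrix(tbl)

  cells <- md %>% distinct(.data$regime_code, .data$day)
  recs <- purrr::pmap_dfr(cells, function(regime_code, day) {
    sub <- md %>% filter(.data$regime_code == !!regime_code, .data$day == !!day)
    if (nrow(sub) < 2) {
      warn(sprintf("Regime %s day %s has fewer than 2 replicates; skipped.",
                   regime_code, format(day)))
      return(tibble())
    }
    sub <- sub %>% arrange(.data$replicate)
    pairs <- utils::combn(seq_len(nrow(sub)), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      x <- m[, sub$sample_id[i]]
      y <- m[, sub$sample_id[j]]
      purrr::map_dfr(index, function(idx) {
        tibble(
          comparison_id = sprintf("%s:r%d-r%d", regime_code,
                                  sub$replicate[i], sub$replicate[j]),
          regime_code = regime_code,
          disturbance_at_sampling = sub$disturbance_at_sampling[1],
          capacity = sub$capacity[1],
          day = day,
          period = sub$period[1],
          index = idx,
          similarity = similarity_fun(idx)(x, y)
        )
      })
    })
  })
  if (nrow(recs) == 0) abort("No regime-day cell had two or more replicates.")
  recs %>%
    group_by(.data$index, .data$period) %>%
    mutate(centered_day = .data$day - mean(.data$day)) %>%
    ungroup() %>%
    select("comparison_id", "regime_code", "disturbance_at_sampling",
           "capacity", "day", "period", "centered_day", "index", "similarity") %>%
    arrange(.data$index, .data$regime_code, .data$day, .data$comparison_id)
}

#' Plot replicate-similarity trajectories
#'
#' @param records A [replicate_similarity_series()] tibble.
#' @return A ggplot: similarity against day, one panel per index, coloured by
#'   the disturbance regime at sampling.
#' @export
plot_similarity_series <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$day, y = .data$similarity,
                               colour = .data$disturbance_at_sampling,
                               group = .data$comparison_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(index ~ capacity) +
    ggplot2::labs(x = "Day", y = "Replicate similarity",
                  colour = "Disturbance") +
    ggplot2::theme_minimal()
}
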