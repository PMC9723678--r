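#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double-centring
#' of `-d^2 / 2`, eigendecomposition, and coordinates scaled by the square
#' root of each positive eigenvalue. Axes are ordered by eigenvalue;
#' negative eigenvalues (possible for semi-metric indices such as
#' Bray-Curtis) are reported but their axes omitted. No correction is
#' applied by default; `correction = "cailliez"` adds the Cailliez constant.
#'
#' @param d A square symmetric dissimilarity matrix (or `dist`) with zero
#'   diagonal and non-negative entries.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return List with `coordinates` (tibble: `sample_id`, `axis1`, `axis2`,
#'   ...), `eigenvalues` (all, including negatives), and
#'   `relative_eigenvalues` for the retained axes.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) abort("Dissimilarity matrix must be square.")
  if (max(abs(m - t(m))) > 1e-8) abort("Dissimilarity matrix must be symmetric.")
  if (any(m < 0)) abort("Dissimilarities must be non-negative.")
  if (any(abs(diag(m)) > 1e-8)) abort("Dissimilarity matrix must have a zero diagonal.")
  ids <- rownames(m) %||% paste0("sample_", seq_len(nrow(m)))
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for semi-metric indices and reported below
  fit <- suppressWarnings(
    cmdscale(stats::as.dist(m), k = nrow(m) - 1, eig = TRUE,
             add = (correction == "cailliez"))
  )
  pos <- which(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(pos))
  list(
    coordinates = bind_cols(tibble(sample_id = ids), as_tibble(coords)),
    eigenvalues = fit$eig,
    relative_eigenvalues = fit$eig[pos] / sum(fit$eig[pos])
  )
}

#' Permutational multivariate analysis of variance
#'
#' Tests whether groups of samples differ in composition and measures the
#' effect size as `R^2 = SS_between / SS_total` computed from the pairwise
#' dissimilarities. The p-value uses free label permutation with the
#' add-one correction `p = (1 + #{F* >= F}) / (1 + n_perm)`. Computation is
#' delegated to [vegan::adonis2()].
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param groups Group label per sample (>= 2 distinct levels, no empty
#'   groups).
#' @param n_perm Number of permutations; default 999.
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `pseudo_f`, `r_squared`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  if (length(groups) != nrow(m)) abort("`groups` must align with the matrix.")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("PERMANOVA needs at least two distinct groups.")
  }
  if (any(table(groups) == 0)) abort("Empty group level in `groups`.")
  df <- data.frame(grp = groups)
  fit <- with_seed(child_seed(seed, "permanova"), {
    vegan::adonis2(stats::as.dist(m) ~ grp, data = df, permutations = n_perm)
  })
  tibble(
    pseudo_f = fit$F[1],
    r_squared = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm
  )
}

#' All pairwise dissimilarities of a count table
#'
#' @param tbl A count-table tibble.
#' @param index `"bray_curtis"` or `"sorensen"`.
#' @return A symmetric dissimilarity matrix (1 - similarity) with sample ids.
#' @export
dissimilarity_matrix <- function(tbl, index = c("bray_curtis", "sorensen")) {
  index <- match.arg(index)
  m <- counts_matrix(tbl)
  f <- similarity_fun(index)
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- 1 - f(m[, i], m[, j])
    }
  }
  out
}
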