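#' Count-table construction and validation
#'
#' A count table is a tibble whose first column, `otu_id`, holds unique taxon
#' identifiers and whose remaining columns hold one sample each: non-negative
#' counts (integers before normalisation, reals after rarefaction averaging).
#'
#' @param x A taxa x samples matrix with rownames (taxon ids) and colnames
#'   (sample ids), or a data frame already in count-table layout.
#' @return A validated count-table tibble.
#' @export
count_table <- function(x) {
  if (is.matrix(x)) {
    if ((is.null(rownames(x)) && nrow(x) > 0) || is.null(colnames(x))) {
      abort("Count matrix must have taxon rownames and sample colnames.")
    }
    ids <- rownames(x) %||% character(0)
    x <- bind_cols(tibble(otu_id = ids), as_tibble(x))
  }
  validate_count_table(as_tibble(x))
}

validate_count_table <- function(tbl) {
  if (!is.data.frame(tbl)) abort("A count table must be a data frame.")
  if (ncol(tbl) < 1 || names(tbl)[1] != "otu_id") {
    abort("The first column of a count table must be `otu_id`.")
  }
  if (anyDuplicated(tbl$otu_id)) {
    dup <- tbl$otu_id[duplicated(tbl$otu_id)][1]
    abort(paste0("Duplicate taxon id: ", dup))
  }
  if (anyDuplicated(names(tbl))) {
    dup <- names(tbl)[duplicated(names(tbl))][1]
    abort(paste0("Duplicate sample id: ", dup))
  }
  for (j in setdiff(names(tbl), "otu_id")) {
    v <- tbl[[j]]
    if (!is.numeric(v)) abort(paste0("Sample column `", j, "` is not numeric."))
    if (anyNA(v)) abort(paste0("Sample column `", j, "` contains NA."))
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(sprintf("Negative count at taxon `%s`, sample `%s`.", tbl$otu_id[i], j))
    }
  }
  tbl
}

#' Extract the numeric taxa-by-samples matrix from a count table
#' @param tbl A count-table tibble.
#' @return Numeric matrix with taxon rownames and sample colnames.
#' @export
counts_matrix <- function(tbl) {
  tbl <- validate_count_table(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$otu_id
  m
}

#' Read / write a count table as TSV
#'
#' The on-disk format is a TSV with a header row of sample ids and a first
#' column `OTU_ID` of taxon ids. Lines starting with `#` are treated as
#' comments (provenance headers). Write-then-read round-trips integer tables
#' bit-exactly and real tables to full double precision.
#'
#' @param path File path.
#' @return `read_count_table()`: a count-table tibble.
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) == 0) abort(paste0("Empty count-table file: ", path))
  names(tbl)[1] <- "otu_id"
  tbl$otu_id <- as.character(tbl$otu_id)
  if (nrow(tbl) == 0) {
    # a header-only file carries no type information
    tbl <- mutate(tbl, across(-"otu_id", as.numeric))
  }
  validate_count_table(tbl)
}

#' @rdname read_count_table
#' @param tbl A count-table tibble.
#' @param provenance Optional character vector written as `#`-prefixed header
#'   lines.
#' @export
write_count_table <- function(tbl, path, provenance = NULL) {
  tbl <- validate_count_table(tbl)
  out <- tbl
  names(out)[1] <- "OTU_ID"
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read / write sample metadata as CSV
#'
#' Columns: `sample_id`, `microcosm_id`, `regime_code`,
#' `disturbance_at_sampling` (D/U), `capacity` (H/L), `replicate`, `day`,
#' `period`. Inoculum rows may carry `NA` design labels.
#'
#' @param path File path.
#' @return `read_sample_metadata()`: a metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble.
#' @param provenance Optional `#`-prefixed header lines.
#' @export
write_sample_metadata <- function(metadata, path, provenance = NULL) {
  metadata <- validate_metadata(metadata)
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_csv(metadata, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(metadata, path, progress = FALSE)
  }
  invisible(path)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "microcosm_id", "regime_code",
            "disturbance_at_sampling", "capacity", "replicate", "day", "period")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    abort(paste0("Metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) abort("Metadata sample ids must be unique.")
  if (any(md$day < 0, na.rm = TRUE)) abort("`day` must be >= 0.")
  non_inoc <- md$microcosm_id != "inoculum"
  bad_d <- non_inoc & !md$disturbance_at_sampling %in% c("D", "U")
  if (any(bad_d)) abort("`disturbance_at_sampling` must be 'D' or 'U'.")
  bad_c <- non_inoc & !md$capacity %in% c("H", "L")
  if (any(bad_c)) abort("`capacity` must be 'H' or 'L'.")
  as_tibble(md)
}

check_paired <- function(tbl, metadata) {
  samples <- setdiff(names(tbl), "otu_id")
  if (!setequal(samples, metadata$sample_id)) {
    abort("Count-table samples and metadata sample ids do not match 1:1.")
  }
  invisible(TRUE)
}

#' Remove samples from a paired count table and metadata
#'
#' Drops the samples matched by `rule` — either a predicate on metadata
#' fields (an expression, e.g. `day == 2`) or an explicit character vector of
#' sample ids — from both the table and the metadata, keeping them aligned.
#' Typical use: excluding a first sampling day on which the community was
#' still adapting to culture conditions.
#'
#' @param tbl A count-table tibble.
#' @param metadata The paired metadata tibble.
#' @param rule A bare predicate expression on metadata columns, or a
#'   character vector of sample ids. `NULL` removes nothing.
#' @return List with filtered `counts` and `metadata`.
#' @export
#' @examples
#' sim <- simulate_experiment(design_spec(regimes = "UDL", sampling_days = c(2, 5)),
#'                            taxon_profiles(5, seed = 1), seed = 1)
#' filter_samples(sim$counts, sim$metadata, day == 2)
filter_samples <- function(tbl, metadata, rule = NULL) {
  tbl <- validate_count_table(tbl)
  metadata <- validate_metadata(metadata)
  check_paired(tbl, metadata)
  q <- rlang::enquo(rule)
  if (rlang::quo_is_null(q)) {
    return(list(counts = tbl, metadata = metadata))
  }
  val <- try(rlang::eval_tidy(q, data = NULL), silent = TRUE)
  drop_ids <- if (!inherits(val, "try-error") && is.character(val)) {
    unknown <- setdiff(val, metadata$sample_id)
    if (length(unknown)) {
      abort(paste0("Unknown sample id(s): ", paste(unknown, collapse = ", ")))
    }
    val
  } else {
    hit <- rlang::eval_tidy(q, data = metadata)
    metadata$sample_id[which(hit)]
  }
  if (length(drop_ids) == nrow(metadata)) {
    abort("Exclusion rule matches every sample; refusing to empty the dataset.")
  }
  inform(sprintf("Removing %d of %d samples.", length(drop_ids), nrow(metadata)))
  keep_md <- metadata %>% filter(!.data$sample_id %in% drop_ids)
  keep_tbl <- tbl[, c("otu_id", keep_md$sample_id), drop = FALSE]
  list(counts = keep_tbl, metadata = keep_md)
}
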