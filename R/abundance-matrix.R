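#' Construct an abundance matrix object
#'
#' Container for the processed gene x sample abundance table: ln-transformed
#' scaled relative abundances, the detection mask (a cell is detected iff its
#' value is strictly positive) and per-sample metadata. All-zero gene rows
#' are dropped.
#'
#' @param values Numeric gene x sample matrix with dimnames.
#' @param metadata Tibble with one row per sample (`sample`, `site`,
#'   `treatment`, ...); row order must match the columns of `values`.
#' @return An `fmen_abundance` object.
#' @export
abundance_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!all(colnames(values) == metadata$sample)) {
    abort("metadata rows must match matrix columns (same samples, same order)")
  }
  if (any(values < 0)) abort("abundances must be non-negative")
  keep <- rowSums(values) > 0
  values <- values[keep, , drop = FALSE]
  structure(
    list(values = values, detected = values > 0,
         metadata = as_tibble(metadata)),
    class = "fmen_abundance"
  )
}

#' @export
print.fmen_abundance <- function(x, ...) {
  cat("<fmen_abundance> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  detected cells:", sum(x$detected), "\n")
  cat("  samples:", paste(head(colnames(x$values), 6), collapse = ", "),
      if (ncol(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.fmen_abundance <- function(x) dim(x$values)

#' Tidy an abundance matrix into long form
#'
#' @param x An `fmen_abundance`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `abundance`, `detected`
#'   plus the sample metadata.
#' @export
tidy.fmen_abundance <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample",
                        values_to = "abundance") %>%
    mutate(detected = .data$abundance > 0) %>%
    left_join(x$metadata, by = "sample")
}

#' Per-site detected gene sets for one treatment
#'
#' Site-level presence is defined after the replicate-consistency filter: a
#' gene is present at a site if it is detected (positive abundance) in any
#' replicate of that site's group — the filter has already zeroed groups
#' with fewer than the required replicate support.
#'
#' @param abund An `fmen_abundance`.
#' @param treatment Treatment label to subset on, or `NULL` for all samples.
#' @return Named list of gene-id character vectors, one per site.
#' @export
site_gene_sets <- function(abund, treatment = NULL) {
  md <- abund$metadata
  if (!is.null(treatment)) md <- filter(md, .data$treatment == !!treatment)
  sites <- sort(unique(md$site))
  lapply(setNames(sites, sites), function(s) {
    smp <- md$sample[md$site == s]
    rownames(abund$values)[
      rowSums(abund$detected[, smp, drop = FALSE]) > 0]
  })
}
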