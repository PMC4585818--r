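#' Intensity-weighted diversity indices per sample
#'
#' For each sample, the detected genes' abundances are turned into
#' proportions `p_i` of the sample total, from which richness (number of
#' detected genes), the Shannon index `H' = -sum(p_i * ln(p_i))` (nats) and
#' the inverse Simpson index `1/D = 1 / sum(p_i^2)` are computed. By default
#' the proportions are taken from the ln-transformed abundances the pipeline
#' hands downstream; set `use_pre_ln = TRUE` to back-transform to the scaled
#' relative abundances first.
#'
#' @param abund An [abundance_matrix()].
#' @param samples Sample ids to compute (default all).
#' @param use_pre_ln Use `exp(a) - 1` (the pre-log scaled abundance) as the
#'   intensity instead of the ln-transformed value.
#' @return A tibble: `sample`, `richness`, `shannon`, `inv_simpson`, joined
#'   with the sample metadata.
#' @examples
#' d <- synth_dataset(synth_config(n_genes = 40, n_modules = 0, seed = 5))
#' diversity_indices(preprocess_spots(d$spots, d$metadata))
#' @export
diversity_indices <- function(abund, samples = NULL, use_pre_ln = FALSE) {
  stopifnot(inherits(abund, "fmen_abundance"))
  vals <- abund$values
  if (use_pre_ln) vals <- exp(vals) - 1
  if (is.null(samples)) samples <- colnames(vals)
  res <- purrr::map_dfr(samples, function(s) {
    x <- vals[, s]
    x <- x[x > 0]
    if (length(x) == 0) abort(paste0("sample ", s, " has no detected genes"))
    p <- x / sum(x)
    tibble(sample = s, richness = length(x),
           shannon = -sum(p * log(p)), inv_simpson = 1 / sum(p^2))
  })
  out <- left_join(res, abund$metadata, by = "sample")
  class(out) <- c("fmen_diversity", class(out))
  out
}

#' Seven-region Venn partition of three gene sets
#'
#' Partitions the union of three named sets into the seven exclusive
#' regions of a three-set Venn diagram, with counts and percentages of the
#' union.
#'
#' @param sets Named list of exactly three character vectors.
#' @return A tibble with `region` (e.g. `"A"`, `"A&B"`, `"A&B&C"` built from
#'   the set names), `genes` (list-column), `count` and `pct_of_union`; the
#'   counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  if (length(sets) != 3) abort("`sets` must contain exactly three sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- c("A", "B", "C")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), ncol = 3, dimnames = list(NULL, names(sets)))
  }
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  res <- purrr::map_dfr(combos, function(idx) {
    inside <- rowSums(member[, idx, drop = FALSE]) == length(idx) &
      rowSums(member[, -idx, drop = FALSE]) == 0
    tibble(
      region = paste(names(sets)[idx], collapse = "&"),
      genes = list(universe[inside]),
      count = sum(inside)
    )
  })
  mutate(res, pct_of_union = if (length(universe) > 0) {
    100 * .data$count / length(universe)
  } else 0)
}

#' Core genes and the planting-increased core
#'
#' The core set of a treatment is the intersection of its per-site gene
#' sets. The "increased core" is the planting core minus the non-planting
#' core — genes that became ubiquitous under planting; the retained overlap
#' is the part of the non-planting core that persists in the planting core.
#'
#' @param planting_sets,nonplanting_sets Named lists of per-site gene-id
#'   vectors (see [site_gene_sets()]).
#' @return A list of class `fmen_core`: `core_planting`,
#'   `core_nonplanting`, `increased_core`, `overlap_core`, plus the two
#'   [venn_partition()] tibbles (only when exactly three sites are given;
#'   the core algebra itself works for any number of sites).
#' @export
core_and_increased_core <- function(planting_sets, nonplanting_sets) {
  core_p <- Reduce(intersect, planting_sets)
  core_np <- Reduce(intersect, nonplanting_sets)
  structure(
    list(
      core_planting = sort(core_p),
      core_nonplanting = sort(core_np),
      increased_core = sort(setdiff(core_p, core_np)),
      overlap_core = sort(intersect(core_p, core_np)),
      venn_planting = if (length(planting_sets) == 3) {
        venn_partition(planting_sets)
      },
      venn_nonplanting = if (length(nonplanting_sets) == 3) {
        venn_partition(nonplanting_sets)
      }
    ),
    class = "fmen_core"
  )
}

#' @export
print.fmen_core <- function(x, ...) {
  cat("<fmen_core>\n")
  cat("  non-planting core:", length(x$core_nonplanting), "genes\n")
  cat("  planting core:    ", length(x$core_planting), "genes",
      sprintf("(%d retained from non-planting, %d increased)\n",
              length(x$overlap_core), length(x$increased_core)))
  invisible(x)
}

#' Summarise core-gene counts and abundance shares by annotation
#'
#' Counts genes per functional category (and family) within a gene pool,
#' and computes each family's share of the summed abundance of its
#' category, for a focal pool (e.g. the core genes) against a background
#' pool (e.g. all detected genes). Unannotated genes are excluded with a
#' warning.
#'
#' @param core_genes Character vector: the focal gene pool.
#' @param annotation Tibble `gene`, `family`, `category`.
#' @param abund An [abundance_matrix()] supplying abundance totals, or
#'   `NULL` for counts only.
#' @param all_genes Background pool (default: all genes in `abund`, else all
#'   annotated genes).
#' @return A tibble with one row per category x family: gene counts in the
#'   focal pool, and (if abundances are given) `pct_abund_core` /
#'   `pct_abund_all`, the family's percentage of its category's summed
#'   abundance in each pool.
#' @export
category_summary <- function(core_genes, annotation, abund = NULL,
                             all_genes = NULL) {
  if (is.null(all_genes)) {
    all_genes <- if (!is.null(abund)) rownames(abund$values) else
      annotation$gene
  }
  unann <- setdiff(union(core_genes, all_genes), annotation$gene)
  if (length(unann) > 0) {
    warn(paste0(length(unann), " unannotated gene id(s) excluded: ",
                paste(head(unann, 5), collapse = ", "),
                if (length(unann) > 5) ", ..." else ""))
    core_genes <- setdiff(core_genes, unann)
    all_genes <- setdiff(all_genes, unann)
  }
  ann <- select(annotation, "gene", "family", "category")
  totals <- if (!is.null(abund)) {
    tibble(gene = rownames(abund$values), abund = rowSums(abund$values))
  } else {
    tibble(gene = annotation$gene, abund = NA_real_)
  }
  pool_share <- function(pool) {
    ann %>%
      filter(.data$gene %in% pool) %>%
      left_join(totals, by = "gene") %>%
      group_by(.data$category, .data$family) %>%
      summarise(n = n(), abund = sum(.data$abund), .groups = "drop_last") %>%
      mutate(pct_abund = 100 * .data$abund / sum(.data$abund)) %>%
      ungroup() %>%
      select(-"abund")
  }
  core_tab <- pool_share(core_genes) %>%
    rename(n_core = "n", pct_abund_core = "pct_abund")
  all_tab <- pool_share(all_genes) %>%
    rename(n_all = "n", pct_abund_all = "pct_abund")
  out <- dplyr::full_join(core_tab, all_tab, by = c("category", "family")) %>%
    arrange(.data$category, .data$family)
  out$n_core[is.na(out$n_core)] <- 0L
  out
}

#' Per-gene Pearson correlation screen against a sample variable
#'
#' Correlates each gene's abundance profile with a per-sample variable
#' (e.g. aboveground biomass), reporting Pearson r, the two-sided p-value
#' from the t transformation, and a Benjamini-Hochberg adjusted column.
#' Zero-variance genes (or a zero-variance variable) are excluded and
#' listed in the `excluded` attribute.
#'
#' @param abund An [abundance_matrix()].
#' @param variable Named numeric vector (names = sample ids) or the name of
#'   a metadata column.
#' @param alpha Significance level used for the `significant` flag
#'   (raw p), default 0.01.
#' @param detected_only Restrict each gene's correlation to the samples
#'   where it is detected (default `FALSE`: all samples with variable
#'   values).
#' @return A tibble `gene`, `n`, `r`, `p`, `p_adj`, `significant`, sorted by
#'   p; excluded gene ids in `attr(, "excluded")`.
#' @export
gene_variable_correlation <- function(abund, variable, alpha = 0.01,
                                      detected_only = FALSE) {
  stopifnot(inherits(abund, "fmen_abundance"))
  if (is.character(variable) && length(variable) == 1) {
    v <- setNames(abund$metadata[[variable]], abund$metadata$sample)
  } else {
    v <- variable[colnames(abund$values)]
  }
  if (any(is.na(v))) abort("variable values missing for some samples")
  if (length(v) < 3) abort("need >= 3 samples with variable values")
  if (sd(v) == 0) abort("variable has zero variance")

  excluded <- character()
  res <- purrr::map_dfr(rownames(abund$values), function(g) {
    x <- abund$values[g, ]
    keep <- if (detected_only) abund$detected[g, ] else rep(TRUE, length(x))
    x <- x[keep]; y <- v[keep]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      excluded <<- c(excluded, g)
      return(NULL)
    }
    r <- cor(x, y)
    df <- length(x) - 2
    tstat <- r * sqrt(df / (1 - r^2))
    tibble(gene = g, n = length(x), r = r,
           p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
  })
  res <- res %>%
    mutate(p_adj = stats::p.adjust(.data$p, "BH"),
           significant = .data$p < alpha) %>%
    arrange(.data$p)
  attr(res, "excluded") <- excluded
  res
}
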