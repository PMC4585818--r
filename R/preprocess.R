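#' Quality-control filter for spot-level records
#'
#' Removes poor-quality spots: those whose flag is in
#' `flag_codes_to_remove`, and those whose signal-to-noise ratio falls below
#' `snr_min`. The SNR boundary is inclusive (`snr >= snr_min` is kept);
#' reference-standard spots are subject to the same rule. Row order is
#' preserved.
#'
#' @param spots Spot tibble with at least `flag` and `snr` columns.
#' @param flag_codes_to_remove Integer flag codes to drop (default `c(1, 3)`).
#' @param snr_min Minimum SNR retained (default 2).
#' @return The filtered spot tibble.
#' @export
qc_filter <- function(spots, flag_codes_to_remove = c(1L, 3L),
                      snr_min = 2.0) {
  if (!is.data.frame(spots) || !all(c("flag", "snr") %in% names(spots))) {
    abort("`spots` must be a data frame with `flag` and `snr` columns")
  }
  if (snr_min < 0) abort("`snr_min` must be >= 0")
  out <- filter(spots, !.data$flag %in% flag_codes_to_remove,
                .data$snr >= snr_min)
  if (nrow(out) == 0) {
    abort("no spots survive quality control", class = "fmen_empty_qc")
  }
  out
}

#' Three-level reference-standard normalization
#'
#' Rescales signals multiplicatively at three successive levels using the
#' reference-standard spots co-spotted in every sub-grid:
#' 1. each sub-grid of a slide is scaled so its mean reference signal equals
#'    the slide-wide mean reference signal;
#' 2. each technical-replicate slide of a sample is scaled so its mean
#'    reference signal equals the mean over that sample's slides;
#' 3. each sample is scaled so its mean reference signal equals the global
#'    mean over all samples.
#'
#' @param spots Spot tibble with `slide`, `subgrid`, `sample`, `signal`,
#'   `is_reference` columns.
#' @return The spot tibble with rescaled `signal`.
#' @export
normalize_spots <- function(spots) {
  need <- c("slide", "subgrid", "sample", "signal", "is_reference")
  if (!all(need %in% names(spots))) {
    abort(paste("`spots` must contain columns:", paste(need, collapse = ", ")))
  }
  ref <- filter(spots, .data$is_reference)
  if (nrow(ref) == 0) abort("no reference-standard spots present")
  grids <- distinct(spots, .data$slide, .data$subgrid)
  ref_grids <- distinct(ref, .data$slide, .data$subgrid)
  missing <- anti_join(grids, ref_grids, by = c("slide", "subgrid"))
  if (nrow(missing) > 0) {
    abort(paste0("sub-grids without reference spots: ",
                 paste(paste(missing$slide, missing$subgrid, sep = "/"),
                       collapse = ", ")))
  }

  scale_level <- function(sp, unit_cols, pool_cols) {
    refm <- sp %>%
      filter(.data$is_reference) %>%
      group_by(across(all_of(union(pool_cols, unit_cols)))) %>%
      summarise(unit_ref = mean(.data$signal), .groups = "drop") %>%
      group_by(across(all_of(pool_cols))) %>%
      mutate(pool_ref = mean(.data$unit_ref)) %>%
      ungroup()
    if (any(refm$unit_ref <= 0)) {
      abort("a normalization unit has non-positive mean reference signal")
    }
    refm <- mutate(refm, scaling = .data$pool_ref / .data$unit_ref)
    sp %>%
      left_join(select(refm, all_of(unit_cols), "scaling"), by = unit_cols) %>%
      mutate(signal = .data$signal * .data$scaling) %>%
      select(-"scaling")
  }

  spots %>%
    scale_level(c("slide", "subgrid"), "slide") %>%
    scale_level("slide", "sample") %>%
    mutate(.global = 1L) %>%
    scale_level("sample", ".global") %>%
    select(-".global")
}

#' Iterative outlier removal among repeated measurements
#'
#' Repeatedly removes values deviating from the current mean by strictly
#' more than `k` sample standard deviations, recomputing mean and SD each
#' round, until no value qualifies. With the sample SD (n - 1 denominator)
#' the maximum standardized deviation is (n - 1)/sqrt(n), so the rule is
#' inert for n <= 5 at k = 2; a single value and zero-variance sets are
#' returned unchanged.
#'
#' @param values Numeric vector of repeated signal measurements.
#' @param k Deviation multiplier (default 2).
#' @return The retained values, in original order.
#' @export
remove_outlier_replicates <- function(values, k = 2.0) {
  if (length(values) == 0) abort("`values` must contain at least one value")
  repeat {
    if (length(values) < 2) return(values)
    s <- sd(values)
    if (!is.finite(s) || s == 0) return(values)
    keep <- abs(values - mean(values)) <= k * s
    if (all(keep)) return(values)
    values <- values[keep]
  }
}

#' Gene detection call from positive probe counts
#'
#' A gene is called detected in a sample when its number of positive probes
#' reaches `max(min_spots, ceiling(fraction * total))`, i.e. at least a
#' fixed fraction of the gene's spotted probes, with an absolute floor.
#'
#' @param positive Integer vector of positive-probe counts.
#' @param total Integer vector of total probes per gene (recycled).
#' @param fraction Required fraction of probes (default 0.34).
#' @param min_spots Absolute floor on positive probes (default 2).
#' @return Logical vector of detection calls.
#' @export
detection_call <- function(positive, total, fraction = 0.34, min_spots = 2L) {
  if (any(total < 1)) abort("`total` must be >= 1")
  if (any(positive > total)) {
    abort("positive probe count exceeds total probe count")
  }
  positive >= pmax(min_spots, ceiling(fraction * total))
}

#' Replicate-consistency filter on group-level detection
#'
#' Within each replicate group (site x treatment), a gene's detections are
#' kept only if the gene is detected in at least `min_reps` biological
#' replicates of the group; otherwise it is zeroed across the whole group.
#'
#' @param detection Logical gene x sample matrix.
#' @param metadata Sample metadata tibble (`sample`, `site`, `treatment`).
#' @param min_reps Minimum supporting replicates (default 2).
#' @return Logical matrix of the same shape.
#' @export
replicate_consistency_filter <- function(detection, metadata, min_reps = 2L) {
  stopifnot(is.matrix(detection))
  groups <- paste(metadata$site, metadata$treatment, sep = "_")
  for (g in unique(groups)) {
    cols <- metadata$sample[groups == g]
    if (length(cols) == 0) abort("replicate group with zero replicates")
    sub <- detection[, cols, drop = FALSE]
    fail <- rowSums(sub) < min_reps
    detection[fail, cols] <- FALSE
  }
  detection
}

#' Scaled relative abundance with natural-log transform
#'
#' Per sample, signals are converted to relative abundances, amplified by
#' the mean of the per-sample signal totals, incremented by one and
#' natural-log transformed: `a_ij = ln(s_ij / sum_i(s_ij) * meanTotal + 1)`.
#' Zeros map exactly to zero, so detection status is preserved.
#'
#' @param signals Non-negative gene x sample matrix with dimnames.
#' @param metadata Sample metadata tibble matching the columns.
#' @return An [abundance_matrix()].
#' @export
relative_abundance_transform <- function(signals, metadata) {
  stopifnot(is.matrix(signals))
  totals <- colSums(signals)
  if (any(totals <= 0)) {
    abort(paste("all-zero sample column(s):",
                paste(colnames(signals)[totals <= 0], collapse = ", ")))
  }
  mean_total <- mean(totals)
  scaled <- sweep(signals, 2, totals, `/`) * mean_total
  abundance_matrix(log(scaled + 1), metadata)
}

#' Full spot-to-abundance preprocessing pipeline
#'
#' Runs the fixed stage order: quality control, three-level normalization,
#' iterative outlier removal among technical-replicate measurements per
#' probe, collapse of technical replicates by their mean, gene detection
#' calls, replicate-consistency filtering, and the scaled relative-abundance
#' / ln transform. Gene-level signal per sample is the mean over that gene's
#' positive probes.
#'
#' @param spots Spot-level tibble as produced by [synth_dataset()] (columns
#'   `slide`, `subgrid`, `gene`, `probe_id`, `sample`, `tech_rep`, `signal`,
#'   `flag`, `snr`, `is_reference`).
#' @param metadata Sample metadata tibble.
#' @param snr_min,flag_codes_to_remove QC parameters, see [qc_filter()].
#' @param outlier_k See [remove_outlier_replicates()].
#' @param detect_fraction,detect_min_spots See [detection_call()].
#' @param min_reps See [replicate_consistency_filter()].
#' @return An [abundance_matrix()].
#' @examples
#' d <- synth_dataset(synth_config(n_genes = 30, n_modules = 0, seed = 3))
#' a <- preprocess_spots(d$spots, d$metadata)
#' dim(a)
#' @export
preprocess_spots <- function(spots, metadata,
                             snr_min = 2.0,
                             flag_codes_to_remove = c(1L, 3L),
                             outlier_k = 2.0,
                             detect_fraction = 0.34,
                             detect_min_spots = 2L,
                             min_reps = 2L) {
  total_probes <- spots %>%
    filter(!.data$is_reference) %>%
    distinct(.data$gene, .data$probe_id) %>%
    count(.data$gene, name = "total")

  clean <- qc_filter(spots, flag_codes_to_remove, snr_min) %>%
    normalize_spots()

  ## outlier loop over repeated (technical-replicate) measurements,
  ## then collapse to one value per probe x sample
  probe_level <- clean %>%
    filter(!.data$is_reference) %>%
    group_by(.data$gene, .data$probe_id, .data$sample) %>%
    summarise(
      signal = mean(remove_outlier_replicates(.data$signal, k = outlier_k)),
      .groups = "drop"
    )

  calls <- probe_level %>%
    count(.data$gene, .data$sample, name = "positive") %>%
    left_join(total_probes, by = "gene") %>%
    mutate(detected = detection_call(.data$positive, .data$total,
                                     detect_fraction, detect_min_spots)) %>%
    filter(.data$detected)

  gene_level <- probe_level %>%
    semi_join(calls, by = c("gene", "sample")) %>%
    group_by(.data$gene, .data$sample) %>%
    summarise(signal = mean(.data$signal), .groups = "drop")

  genes <- sort(unique(gene_level$gene))
  sig <- matrix(0, nrow = length(genes), ncol = nrow(metadata),
                dimnames = list(genes, metadata$sample))
  sig[cbind(gene_level$gene, gene_level$sample)] <- gene_level$signal

  det <- replicate_consistency_filter(sig > 0, metadata, min_reps)
  sig[!det] <- 0
  sig <- sig[rowSums(sig) > 0, , drop = FALSE]
  if (nrow(sig) == 0) abort("no genes survive preprocessing")
  relative_abundance_transform(sig, metadata)
}
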