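#' Configuration for the synthetic functional gene array generator
#'
#' Builds and validates the parameter set describing a GeoChip-like
#' hybridization experiment: a factorial field design (sites x two planting
#' treatments x biological replicates), technical replicate slides carrying
#' sub-grids with a common reference-standard probe, treatment-dependent gene
#' presence, and block-correlated gene abundance modules hidden inside the
#' planting core.
#'
#' Gene presence is laid out per site x treatment group:
#' * a `core_frac_nonplanting` fraction of genes is present everywhere under
#'   both treatments (the non-planting core), except for a
#'   `core_dropout_frac` fraction of those which lose one planted site and so
#'   drop out of the planting core;
#' * an additional `extra_core_frac_planting` fraction is present in all
#'   sites but only under planting (the "increased core" pool, from which the
#'   correlated modules are drawn);
#' * a `site_unique_frac` fraction is confined to a single site;
#' * the remainder is scattered, present in each group independently with
#'   probability `presence_prob_planting` or `presence_prob_nonplanting`.
#'
#' Per-sample log-intensities of module genes share a latent Gaussian factor
#' so that their pairwise Pearson correlation across planted samples is
#' approximately `within_module_correlation`; genes in different modules are
#' independent.
#'
#' @param n_sites Number of field sites (default 3).
#' @param n_bio_reps Biological replicate plots per site x treatment.
#' @param n_tech_reps Technical replicate slides hybridized per sample.
#' @param n_genes Number of genes on the array.
#' @param n_probes_per_gene Probes spotted per gene.
#' @param n_subgrids Sub-grids per slide; each carries one reference-standard
#'   spot.
#' @param core_frac_nonplanting Fraction of genes in the non-planting core.
#' @param extra_core_frac_planting Fraction of genes added to the core by
#'   planting.
#' @param core_dropout_frac Fraction of the non-planting core that fails to
#'   carry over into the planting core.
#' @param site_unique_frac Fraction of genes confined to one site.
#' @param presence_prob_planting,presence_prob_nonplanting Per-group presence
#'   probability for scattered genes under each treatment.
#' @param n_modules,module_size Number and size of correlated gene modules
#'   (drawn from the planting-only core pool).
#' @param within_module_correlation Target pairwise correlation of
#'   log-abundance within a module, in \[0, 1).
#' @param signal_lognormal_mu,signal_lognormal_sigma Log-normal parameters of
#'   gene base intensities (fluorescence units).
#' @param bio_sd Standard deviation of per-sample biological variation on the
#'   log-intensity scale.
#' @param subgrid_bias_sd,tech_bias_sd,sample_bias_sd Log-scale SDs of the
#'   multiplicative sub-grid, technical-replicate and sample biases that the
#'   normalization stage is expected to remove.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise per spot.
#' @param flag_rate Probability that a spot is flagged poor-quality (flag 1
#'   or 3).
#' @param low_snr_rate Probability that a present-gene spot draws a
#'   signal-to-noise ratio below 2.
#' @param seed Integer seed; fixes every emitted byte.
#'
#' @return A validated `fmen_synth_config` list.
#' @seealso [synth_dataset()]
#' @export
synth_config <- function(n_sites = 3,
                         n_bio_reps = 3,
                         n_tech_reps = 3,
                         n_genes = 500,
                         n_probes_per_gene = 4,
                         n_subgrids = 4,
                         core_frac_nonplanting = 0.25,
                         extra_core_frac_planting = 0.25,
                         core_dropout_frac = 0.025,
                         site_unique_frac = 0.15,
                         presence_prob_planting = 0.55,
                         presence_prob_nonplanting = 0.35,
                         n_modules = 3,
                         module_size = 30,
                         within_module_correlation = 0.9,
                         signal_lognormal_mu = 7,
                         signal_lognormal_sigma = 1,
                         bio_sd = 1,
                         subgrid_bias_sd = 0.25,
                         tech_bias_sd = 0.15,
                         sample_bias_sd = 0.2,
                         noise_cv = 0.1,
                         flag_rate = 0.05,
                         low_snr_rate = 0.05,
                         seed = 1L) {
  cfg <- list(
    n_sites = n_sites, n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
    n_genes = n_genes, n_probes_per_gene = n_probes_per_gene,
    n_subgrids = n_subgrids,
    core_frac_nonplanting = core_frac_nonplanting,
    extra_core_frac_planting = extra_core_frac_planting,
    core_dropout_frac = core_dropout_frac,
    site_unique_frac = site_unique_frac,
    presence_prob_planting = presence_prob_planting,
    presence_prob_nonplanting = presence_prob_nonplanting,
    n_modules = n_modules, module_size = module_size,
    within_module_correlation = within_module_correlation,
    signal_lognormal_mu = signal_lognormal_mu,
    signal_lognormal_sigma = signal_lognormal_sigma,
    bio_sd = bio_sd,
    subgrid_bias_sd = subgrid_bias_sd, tech_bias_sd = tech_bias_sd,
    sample_bias_sd = sample_bias_sd,
    noise_cv = noise_cv, flag_rate = flag_rate, low_snr_rate = low_snr_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_sites", "n_bio_reps", "n_tech_reps", "n_genes",
              "n_probes_per_gene", "n_subgrids")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(paste0("`", nm, "` must be >= 1"))
  }
  if (cfg$n_modules < 0 || cfg$module_size < 0) {
    abort("`n_modules` and `module_size` must be non-negative")
  }
  props <- c("core_frac_nonplanting", "extra_core_frac_planting",
             "core_dropout_frac", "site_unique_frac",
             "presence_prob_planting", "presence_prob_nonplanting",
             "flag_rate", "low_snr_rate")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(paste0("`", nm, "` must be a proportion in [0, 1]"))
    }
  }
  if (within_module_correlation < 0 || within_module_correlation >= 1) {
    abort("`within_module_correlation` must lie in [0, 1)")
  }
  n_extra_core <- round(cfg$extra_core_frac_planting * cfg$n_genes)
  if (cfg$n_modules * cfg$module_size > n_extra_core) {
    abort(paste0(
      "module genes (", cfg$n_modules * cfg$module_size,
      ") exceed the planting-only core pool (", n_extra_core,
      "); shrink modules or raise `extra_core_frac_planting`"
    ))
  }
  structure(cfg, class = "fmen_synth_config")
}

#' Generate a synthetic spot-level functional gene array dataset
#'
#' Simulates the full measurement chain of a functional gene microarray
#' study with known ground truth: per-group gene presence (treatment effects
#' on richness), latent-factor gene modules, probe affinities, sub-grid /
#' technical-replicate / sample multiplicative biases, measurement noise,
#' poor-quality flags and low-SNR spots, plus a reference-standard spot in
#' every sub-grid for the normalization stage to anchor on. Environmental
#' variables are baseline + treatment effect + site effect + Gaussian noise.
#'
#' @param config A [synth_config()].
#' @return A list with elements
#' * `spots`: spot-level tibble (slide, subgrid, gene, probe, sample, site,
#'   treatment, bio_rep, tech_rep, signal, flag, snr, is_reference),
#' * `annotation`: gene, family, category, organism,
#' * `metadata`: sample, site, treatment, bio_rep,
#' * `env`: sample x environmental-variable tibble,
#' * `truth`: ground-truth list (`core_genes_nonplanting`,
#'   `core_genes_planting`, `site_unique_genes`, `module_membership`,
#'   `presence`, `env_effects`).
#' @examples
#' d <- synth_dataset(synth_config(n_genes = 40, n_modules = 0, seed = 7))
#' dplyr::count(d$spots, .data$sample)
#' @export
synth_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "fmen_synth_config"))
  withr::with_seed(config$seed, synth_dataset_impl(config))
}

synth_dataset_impl <- function(cfg) {
  sites <- paste0("S", seq_len(cfg$n_sites))
  treatments <- c("planting", "nonplanting")
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  metadata <- tidyr::expand_grid(
    site = sites, treatment = treatments,
    bio_rep = seq_len(cfg$n_bio_reps)
  ) %>%
    mutate(sample = paste(.data$site, .data$treatment, .data$bio_rep,
                          sep = "_")) %>%
    select("sample", "site", "treatment", "bio_rep")

  ## ---- gene roles ------------------------------------------------------
  n_core_np <- round(cfg$core_frac_nonplanting * cfg$n_genes)
  n_extra <- round(cfg$extra_core_frac_planting * cfg$n_genes)
  n_unique <- round(cfg$site_unique_frac * cfg$n_genes)
  if (n_core_np + n_extra + n_unique > cfg$n_genes) {
    abort("core, extra-core and site-unique fractions exceed 1")
  }
  idx <- seq_len(cfg$n_genes)
  core_np_genes <- genes[idx <= n_core_np]
  extra_core_genes <- genes[idx > n_core_np & idx <= n_core_np + n_extra]
  unique_genes <- genes[idx > n_core_np + n_extra &
                          idx <= n_core_np + n_extra + n_unique]
  scattered_genes <- genes[idx > n_core_np + n_extra + n_unique]

  n_drop <- round(cfg$core_dropout_frac * n_core_np)
  dropout_genes <- if (n_drop > 0) sample(core_np_genes, n_drop) else character()

  ## presence[gene, group]: group = site x treatment
  groups <- tidyr::expand_grid(site = sites, treatment = treatments) %>%
    mutate(group = paste(.data$site, .data$treatment, sep = "_"))
  pres <- matrix(FALSE, nrow = cfg$n_genes, ncol = nrow(groups),
                 dimnames = list(genes, groups$group))
  pres[core_np_genes, ] <- TRUE
  pres[extra_core_genes, groups$treatment == "planting"] <- TRUE
  if (n_drop > 0) {
    planted_cols <- which(groups$treatment == "planting")
    for (g in dropout_genes) {
      pres[g, sample(planted_cols, 1)] <- FALSE
    }
  }
  site_unique_genes <- setNames(vector("list", cfg$n_sites), sites)
  if (length(unique_genes) > 0) {
    home <- sample(sites, length(unique_genes), replace = TRUE)
    for (i in seq_along(unique_genes)) {
      pres[unique_genes[i], groups$site == home[i]] <- TRUE
    }
    site_unique_genes <- lapply(setNames(sites, sites),
                                function(s) unique_genes[home == s])
  }
  if (length(scattered_genes) > 0) {
    ## nested draws: one uniform per gene x site shared by both treatments,
    ## so with presence_prob_planting >= presence_prob_nonplanting every
    ## unplanted occurrence persists under planting and the treatment core
    ## relation (planting core contains the non-planting core up to the
    ## designed dropout) holds structurally, not just in expectation
    u <- matrix(runif(length(scattered_genes) * cfg$n_sites),
                nrow = length(scattered_genes),
                dimnames = list(scattered_genes, sites))
    for (gi in seq_len(nrow(groups))) {
      p_tr <- if (groups$treatment[gi] == "planting") {
        cfg$presence_prob_planting
      } else cfg$presence_prob_nonplanting
      pres[scattered_genes, groups$group[gi]] <-
        u[, groups$site[gi]] < p_tr
    }
  }

  ## ---- module structure ------------------------------------------------
  module_membership <- tibble(gene = character(), module = character())
  if (cfg$n_modules > 0 && cfg$module_size > 0) {
    module_genes <- extra_core_genes[seq_len(cfg$n_modules * cfg$module_size)]
    module_membership <- tibble(
      gene = module_genes,
      module = rep(sprintf("M%d", seq_len(cfg$n_modules)),
                   each = cfg$module_size)
    )
  }

  ## ---- latent per-sample log-intensity --------------------------------
  n_samples <- nrow(metadata)
  base_log <- rnorm(cfg$n_genes, cfg$signal_lognormal_mu,
                    cfg$signal_lognormal_sigma)
  names(base_log) <- genes
  rho <- cfg$within_module_correlation
  z <- matrix(rnorm(cfg$n_genes * n_samples), nrow = cfg$n_genes,
              dimnames = list(genes, metadata$sample))
  if (nrow(module_membership) > 0) {
    for (m in unique(module_membership$module)) {
      mg <- module_membership$gene[module_membership$module == m]
      factor_m <- rnorm(n_samples)
      z[mg, ] <- sqrt(rho) * matrix(factor_m, nrow = length(mg),
                                    ncol = n_samples, byrow = TRUE) +
        sqrt(1 - rho) * z[mg, , drop = FALSE]
    }
  }
  log_intensity <- base_log + cfg$bio_sd * z

  ## ---- array geometry --------------------------------------------------
  probes <- tidyr::expand_grid(gene = genes,
                               probe = seq_len(cfg$n_probes_per_gene)) %>%
    mutate(probe_id = paste0(.data$gene, "_p", .data$probe),
           subgrid = (row_number() - 1L) %% cfg$n_subgrids + 1L)
  probe_affinity <- setNames(exp(rnorm(nrow(probes), 0, 0.2)),
                             probes$probe_id)
  ref_intensity <- 5000

  slides <- tidyr::expand_grid(sample = metadata$sample,
                               tech_rep = seq_len(cfg$n_tech_reps)) %>%
    mutate(slide = paste(.data$sample, "t", .data$tech_rep, sep = ""))

  sample_bias <- setNames(exp(rnorm(n_samples, 0, cfg$sample_bias_sd)),
                          metadata$sample)
  tech_bias <- setNames(exp(rnorm(nrow(slides), 0, cfg$tech_bias_sd)),
                        slides$slide)
  subgrid_bias <- tidyr::expand_grid(slide = slides$slide,
                                     subgrid = seq_len(cfg$n_subgrids)) %>%
    mutate(bias = exp(rnorm(n(), 0, cfg$subgrid_bias_sd)))

  ## ---- spot table ------------------------------------------------------
  spots <- tidyr::expand_grid(slide = slides$slide, probe_id = probes$probe_id)
  spots <- spots %>%
    left_join(slides, by = "slide") %>%
    left_join(select(probes, "probe_id", "gene", "probe", "subgrid"),
              by = "probe_id") %>%
    left_join(metadata, by = "sample") %>%
    left_join(subgrid_bias, by = c("slide", "subgrid"))

  grp <- paste(spots$site, spots$treatment, sep = "_")
  present <- pres[cbind(spots$gene, grp)]
  true_log <- log_intensity[cbind(spots$gene, spots$sample)]
  clean <- exp(true_log) * probe_affinity[spots$probe_id]
  background <- exp(rnorm(nrow(spots), 3, 0.5))
  signal_true <- ifelse(present, clean, background)
  bias <- spots$bias * tech_bias[spots$slide] * sample_bias[spots$sample]
  noise <- if (cfg$noise_cv > 0) {
    pmax(1 + rnorm(nrow(spots), 0, cfg$noise_cv), 0.01)
  } else 1
  signal <- signal_true * bias * noise

  flag <- ifelse(runif(nrow(spots)) < cfg$flag_rate,
                 sample(c(1L, 3L), nrow(spots), replace = TRUE), 0L)
  snr <- ifelse(present,
                ifelse(runif(nrow(spots)) < cfg$low_snr_rate,
                       runif(nrow(spots), 0, 1.9),
                       exp(rnorm(nrow(spots), log(10), 0.4)) + 2),
                runif(nrow(spots), 0, 1.9))

  gene_spots <- spots %>%
    mutate(signal = signal, flag = flag, snr = round(snr, 3),
           is_reference = FALSE) %>%
    select("slide", "subgrid", "gene", "probe", "probe_id", "sample",
           "site", "treatment", "bio_rep", "tech_rep", "signal", "flag",
           "snr", "is_reference")

  ref_spots <- subgrid_bias %>%
    left_join(slides, by = "slide") %>%
    left_join(metadata, by = "sample") %>%
    mutate(
      gene = "REF", probe = 0L,
      probe_id = paste0("REF_", .data$subgrid),
      signal = ref_intensity * .data$bias * tech_bias[.data$slide] *
        sample_bias[.data$sample] *
        (if (cfg$noise_cv > 0) {
          pmax(1 + rnorm(n(), 0, cfg$noise_cv), 0.01)
        } else 1),
      flag = 0L, snr = 50, is_reference = TRUE
    ) %>%
    select("slide", "subgrid", "gene", "probe", "probe_id", "sample",
           "site", "treatment", "bio_rep", "tech_rep", "signal", "flag",
           "snr", "is_reference")

  spot_table <- bind_rows(gene_spots, ref_spots) %>%
    arrange(.data$slide, .data$subgrid, .data$probe_id) %>%
    mutate(signal = round(.data$signal, 4))

  ## ---- annotation ------------------------------------------------------
  categories <- c("C degradation", "N cycling", "P cycling", "S cycling",
                  "Metal resistance", "Organic remediation")
  families_by_cat <- list(
    `C degradation` = c("amyA", "ara", "xylA", "chi", "lip", "vanA"),
    `N cycling` = c("amoA", "nirK", "nosZ", "nifH", "ureC", "napA"),
    `P cycling` = c("ppk", "ppx"),
    `S cycling` = c("dsrA", "sox"),
    `Metal resistance` = c("merA", "arsC"),
    `Organic remediation` = c("benA", "catB")
  )
  cat_of_gene <- sample(categories, cfg$n_genes, replace = TRUE,
                        prob = c(0.3, 0.25, 0.12, 0.12, 0.11, 0.1))
  fam_of_gene <- vapply(cat_of_gene,
                        function(cc) sample(families_by_cat[[cc]], 1), "")
  annotation <- tibble(
    gene = genes, family = unname(fam_of_gene), category = cat_of_gene,
    organism = paste0("organism_", sample(200, cfg$n_genes, replace = TRUE))
  )

  ## ---- environmental table --------------------------------------------
  env_effects <- tibble(
    variable = c("pH", "TK", "NH4N", "MSM", "AGB", "SPAD", "AR", "RH"),
    baseline = c(6.5, 15, 8, 20, 0, 0, 800, 65),
    treatment_effect = c(-0.3, 1.5, 3, 5, 120, 40, 0, 0),
    site_sd = c(0.8, 4, 2, 4, 10, 4, 250, 8),
    noise_sd = c(0.1, 0.5, 0.8, 1.5, 12, 3, 0, 0)
  )
  site_effects <- matrix(rnorm(cfg$n_sites * nrow(env_effects)),
                         nrow = cfg$n_sites,
                         dimnames = list(sites, env_effects$variable))
  env <- metadata
  for (i in seq_len(nrow(env_effects))) {
    v <- env_effects$variable[i]
    env[[v]] <- env_effects$baseline[i] +
      env_effects$treatment_effect[i] * (env$treatment == "planting") +
      env_effects$site_sd[i] * site_effects[env$site, v] +
      rnorm(nrow(env), 0, env_effects$noise_sd[i])
    env[[v]] <- round(env[[v]], 4)
  }
  env <- select(env, -"site", -"treatment", -"bio_rep")

  ## ---- ground truth ----------------------------------------------------
  core_by_treatment <- lapply(setNames(treatments, treatments), function(tr) {
    cols <- groups$group[groups$treatment == tr]
    genes[rowSums(pres[, cols, drop = FALSE]) == length(cols)]
  })
  truth <- list(
    core_genes_nonplanting = core_by_treatment$nonplanting,
    core_genes_planting = core_by_treatment$planting,
    site_unique_genes = site_unique_genes,
    module_membership = module_membership,
    presence = pres,
    env_effects = env_effects
  )

  list(spots = spot_table, annotation = annotation, metadata = metadata,
       env = env, truth = truth)
}

#' Seven-region Venn partition of the ground-truth gene presence
#'
#' Derives, for one treatment, the per-site detected gene sets implied by the
#' generator's presence masks and partitions their union into the seven
#' regions of a three-set Venn diagram.
#'
#' @param truth The `truth` element of a [synth_dataset()] result.
#' @param treatment `"planting"` or `"nonplanting"`.
#' @return A tibble as returned by [venn_partition()].
#' @export
ground_truth_venn <- function(truth, treatment = "planting") {
  pres <- truth$presence
  cols <- grep(paste0("_", treatment, "$"), colnames(pres), value = TRUE)
  if (length(cols) != 3) {
    abort("ground-truth Venn partition requires exactly three sites")
  }
  sets <- lapply(setNames(cols, sub(paste0("_", treatment), "", cols)),
                 function(cc) rownames(pres)[pres[, cc]])
  venn_partition(sets)
}
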