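#' Run the full analysis pipeline on a (synthetic) dataset
#'
#' Chains every stage: data simulation (unless a dataset is supplied),
#' spot-to-abundance preprocessing, diversity indices, Venn/core gene
#' reports, the Mantel screen of community structure against environmental
#' variables, and per-treatment RMT network inference with topology and
#' module summaries. Each treatment's network is built from that
#' treatment's samples and core gene set; failures are re-thrown with the
#' failing stage named while earlier outputs are retained in the error
#' condition.
#'
#' @param config A [synth_config()] describing the simulated study; ignored
#'   when `dataset` is given.
#' @param dataset Optional precomputed [synth_dataset()] result (or real
#'   data in the same shape).
#' @param n_perm Mantel permutations (default 999).
#' @param conditioning Variables conditioned on in the Mantel screen
#'   (default the climate pair `c("AR", "RH")`; `NULL` for simple Mantel).
#' @param scan_args List of arguments forwarded to [scan_threshold()].
#' @param seed Seed for the Mantel permutation streams (the generator has
#'   its own seed in `config`).
#' @return A list of class `fmen_pipeline` with elements `dataset`,
#'   `abundance`, `diversity`, `core`, `mantel`, `networks` (per treatment:
#'   `scan`, `network`, `modules`, `tables`), `comparison`, and `topology`
#'   (a Table-4-style tibble).
#' @examples
#' \donttest{
#' res <- run_pipeline(synth_config(n_genes = 120, n_modules = 2,
#'                                  module_size = 15, seed = 11),
#'                     n_perm = 99)
#' res$topology
#' }
#' @export
run_pipeline <- function(config = synth_config(), dataset = NULL,
                         n_perm = 999, conditioning = c("AR", "RH"),
                         scan_args = list(), seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "fmen_stage_failure", stage = name, parent = e)
    })
  }

  if (is.null(dataset)) {
    dataset <- stage("simulate", synth_dataset(config))
  }
  abund <- stage("preprocess",
                 preprocess_spots(dataset$spots, dataset$metadata))
  divers <- stage("diversity", diversity_indices(abund))
  core <- stage("core", core_and_increased_core(
    site_gene_sets(abund, "planting"),
    site_gene_sets(abund, "nonplanting")
  ))
  mantel_tab <- stage("mantel", {
    d_comm <- bray_curtis(abund)
    mantel_screen(d_comm, dataset$env, conditioning = conditioning,
                  n_perm = n_perm, seed = seed)
  })

  networks <- list()
  for (tr in c("nonplanting", "planting")) {
    networks[[tr]] <- stage(paste0("network_", tr), {
      genes <- if (tr == "planting") core$core_planting else
        core$core_nonplanting
      smp <- abund$metadata$sample[abund$metadata$treatment == tr]
      sim <- gene_similarity(abund, genes = genes, samples = smp)
      scan <- do.call(scan_threshold, c(list(sim), scan_args))
      net <- build_network(sim, scan$chosen_st)
      mods <- network_modules(net)
      list(sim = sim, scan = scan, network = net, modules = mods,
           tables = network_tables(net, sim, mods, dataset$annotation))
    })
  }

  comparison <- stage("compare", compare_networks(
    networks$nonplanting$network, networks$planting$network,
    dataset$annotation
  ))

  topology <- purrr::map_dfr(names(networks), function(tr) {
    nw <- networks[[tr]]
    glance(nw$network) %>%
      mutate(treatment = tr, modularity = nw$modules$modularity,
             n_modules = nw$modules$n_modules, .before = 1)
  })

  structure(
    list(dataset = dataset, abundance = abund, diversity = divers,
         core = core, mantel = mantel_tab, networks = networks,
         comparison = comparison, topology = topology),
    class = "fmen_pipeline"
  )
}

#' @export
print.fmen_pipeline <- function(x, ...) {
  cat("<fmen_pipeline>\n")
  cat("  abundance:", nrow(x$abundance$values), "genes x",
      ncol(x$abundance$values), "samples\n")
  print(x$core)
  cat("  topology:\n")
  print(as.data.frame(x$topology), row.names = FALSE)
  invisible(x)
}

#' Write the pipeline report bundle as tab-separated files
#'
#' Emits the summary tables of a [run_pipeline()] result: diversity,
#' Venn/core counts, core gene lists, the Mantel table, the topology table
#' and per-network edge/node tables.
#'
#' @param result An `fmen_pipeline`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "fmen_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(select(result$diversity, "sample", "richness", "shannon",
            "inv_simpson"), "diversity.tsv")
  wr(select(result$core$venn_planting, -"genes"), "venn_planting.tsv")
  wr(select(result$core$venn_nonplanting, -"genes"), "venn_nonplanting.tsv")
  writeLines(result$core$core_planting,
             file.path(out_dir, "core_planting.txt"))
  writeLines(result$core$core_nonplanting,
             file.path(out_dir, "core_nonplanting.txt"))
  writeLines(result$core$increased_core,
             file.path(out_dir, "increased_core.txt"))
  paths <- c(paths, file.path(out_dir, c("core_planting.txt",
                                         "core_nonplanting.txt",
                                         "increased_core.txt")))
  wr(result$mantel, "mantel.tsv")
  wr(result$topology, "topology.tsv")
  for (tr in names(result$networks)) {
    wr(result$networks[[tr]]$tables$edges, paste0("edges_", tr, ".tsv"))
    wr(result$networks[[tr]]$tables$nodes, paste0("nodes_", tr, ".tsv"))
  }
  invisible(paths)
}

#' End-to-end module recovery score on synthetic data
#'
#' Convenience wrapper used to validate the whole inference chain:
#' simulate, preprocess, compute the planted-sample similarity over the
#' planting core, scan for the RMT threshold, build the network, detect
#' modules, and score the detected partition against the generator's
#' ground-truth module labels with normalized mutual information
#' (restricted to the ground-truth module genes present in the network).
#'
#' @param config A [synth_config()] with `n_modules >= 2`.
#' @param scan_args Arguments forwarded to [scan_threshold()].
#' @return A list: `nmi`, `chosen_st`, `network`, `modules`,
#'   `n_truth_genes_in_network`.
#' @export
module_recovery <- function(config, scan_args = list()) {
  dataset <- synth_dataset(config)
  abund <- preprocess_spots(dataset$spots, dataset$metadata)
  core <- core_and_increased_core(site_gene_sets(abund, "planting"),
                                  site_gene_sets(abund, "nonplanting"))
  smp <- abund$metadata$sample[abund$metadata$treatment == "planting"]
  sim <- gene_similarity(abund, genes = core$core_planting, samples = smp)
  scan <- do.call(scan_threshold, c(list(sim), scan_args))
  net <- build_network(sim, scan$chosen_st)
  mods <- network_modules(net)

  truth <- dataset$truth$module_membership
  shared <- intersect(truth$gene, names(mods$membership))
  if (length(shared) < 2) abort("no ground-truth module genes in network")
  truth_lab <- as.integer(factor(truth$module[match(shared, truth$gene)]))
  found_lab <- as.integer(factor(mods$membership[shared]))
  nmi <- igraph::compare(truth_lab, found_lab, method = "nmi")
  list(nmi = nmi, chosen_st = scan$chosen_st, network = net,
       modules = mods, n_truth_genes_in_network = length(shared))
}
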