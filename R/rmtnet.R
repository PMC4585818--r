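#' Gene co-abundance similarity matrix
#'
#' Pairwise absolute Pearson correlation of gene abundance profiles across
#' samples, the similarity on which the random-matrix-theory threshold scan
#' operates. Constant genes (zero variance across the used samples) are
#' excluded and listed in the `excluded` attribute.
#'
#' @param abund An [abundance_matrix()] or gene x sample matrix.
#' @param genes Optional gene subset (e.g. a treatment core set).
#' @param samples Optional sample subset (e.g. planted samples only).
#' @return An `fmen_similarity` object: `mat` (symmetric, unit diagonal,
#'   entries in \[0, 1\]), `n_samples`.
#' @export
gene_similarity <- function(abund, genes = NULL, samples = NULL) {
  mat <- if (inherits(abund, "fmen_abundance")) abund$values else abund
  stopifnot(is.matrix(mat))
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(mat))
    mat <- mat[genes, , drop = FALSE]
  }
  if (!is.null(samples)) mat <- mat[, samples, drop = FALSE]
  if (ncol(mat) < 4) abort("need >= 4 samples for gene-gene correlation")
  sds <- apply(mat, 1, sd)
  excluded <- rownames(mat)[sds == 0]
  mat <- mat[sds > 0, , drop = FALSE]
  if (nrow(mat) < 2) abort("fewer than 2 non-constant genes")
  s <- abs(cor(t(mat)))
  diag(s) <- 1
  structure(list(mat = s, n_samples = ncol(mat), excluded = excluded),
            class = "fmen_similarity")
}

#' @export
print.fmen_similarity <- function(x, ...) {
  cat("<fmen_similarity> ", nrow(x$mat), " genes over ", x$n_samples,
      " samples\n", sep = "")
  invisible(x)
}

threshold_matrix <- function(s, st) {
  m <- s
  m[m < st] <- 0
  diag(m) <- 1
  keep <- rowSums(m > 0) > 1  # at least one retained off-diagonal entry
  m[keep, keep, drop = FALSE]
}

#' Unfold an eigenvalue spectrum
#'
#' Maps eigenvalues through a smoothed empirical cumulative spectral
#' function so that the transformed levels have unit mean spacing, the
#' standard preparation for nearest-neighbour spacing analysis. Degenerate
#' eigenvalues (gap below `degeneracy_tol`) are collapsed to a single
#' level; the smoothing is a cubic smoothing spline of the empirical CDF
#' with about `df` effective degrees of freedom, made monotone by a
#' running maximum.
#'
#' @param eigenvalues Numeric vector.
#' @param df Effective degrees of freedom of the smoothing spline
#'   (default 10).
#' @param degeneracy_tol Gap below which eigenvalues are treated as one
#'   level (default 1e-10).
#' @return List with `unfolded` (sorted) and `spacings` (consecutive
#'   differences; their mean is close to 1 when the fit is adequate).
#' @export
unfold_spectrum <- function(eigenvalues, df = 10, degeneracy_tol = 1e-10) {
  ev <- sort(eigenvalues)
  keep <- c(TRUE, diff(ev) >= degeneracy_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < 10) abort("too few distinct eigenvalues to unfold")
  cum <- seq_len(n) / n
  fit <- smooth.spline(ev, cum, df = min(df, n - 1))
  unfolded <- n * cummax(predict(fit, ev)$y)
  list(unfolded = unfolded, spacings = diff(unfolded))
}

#' Chi-square test of nearest-neighbour spacings against the Poisson form
#'
#' Tests whether the unfolded nearest-neighbour spacing distribution of a
#' symmetric matrix follows the Poisson (exponential, `exp(-d)`) law of
#' uncorrelated levels, as opposed to the level-repelling Wigner-Dyson form
#' of the Gaussian orthogonal ensemble. The spacings are rescaled to mean
#' one, binned into equal-probability exponential bins and compared with a
#' chi-square goodness-of-fit statistic; `poisson_like` is `TRUE` when the
#' Poisson form is not rejected at `alpha`.
#'
#' @param x Symmetric numeric matrix, or a precomputed numeric vector of
#'   eigenvalues.
#' @param n_bins Number of equal-probability bins (default 20; reduced so
#'   expected counts stay at least 5).
#' @param alpha Rejection level (default 0.05).
#' @param df Spline degrees of freedom for [unfold_spectrum()].
#' @return A list of class `fmen_nnsd`: `statistic`, `df`, `p_value`,
#'   `poisson_like`, `decision` (`"poisson-like"`/`"goe-like"`),
#'   `mean_spacing` (before rescaling), `n_levels`, `spacings`.
#' @examples
#' ev <- runif(300)                      # independent levels
#' nnsd_poisson_test(ev)$decision
#' @export
nnsd_poisson_test <- function(x, n_bins = 20, alpha = 0.05, df = 10) {
  ev <- if (is.matrix(x)) {
    if (max(abs(x - t(x))) > 1e-8) abort("matrix must be symmetric")
    eigen(x, symmetric = TRUE, only.values = TRUE)$values
  } else as.numeric(x)
  uf <- unfold_spectrum(ev, df = df)
  s <- uf$spacings
  mean_spacing <- mean(s)
  s <- s / mean_spacing
  m <- max(3, min(n_bins, floor(length(s) / 5)))
  edges <- -log(1 - seq_len(m - 1) / m)  # Exp(1) equal-probability cuts
  obs <- tabulate(findInterval(s, edges) + 1L, nbins = m)
  expd <- length(s) / m
  stat <- sum((obs - expd)^2 / expd)
  p <- pchisq(stat, df = m - 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = m - 1, p_value = p,
                 poisson_like = p > alpha,
                 decision = if (p > alpha) "poisson-like" else "goe-like",
                 mean_spacing = mean_spacing, n_levels = length(ev),
                 spacings = s),
            class = "fmen_nnsd")
}

#' @export
print.fmen_nnsd <- function(x, ...) {
  cat("<fmen_nnsd> ", x$decision, ": X2 = ", round(x$statistic, 2),
      " (df ", x$df, "), p = ", signif(x$p_value, 4), ", ", x$n_levels,
      " levels\n", sep = "")
  invisible(x)
}

#' Nearest-neighbour spacing test of a thresholded similarity matrix
#'
#' Applies a candidate threshold to the similarity matrix (off-diagonal
#' entries below `st` are zeroed, retained entries keep their similarity
#' value, unit diagonal), drops rows/columns with no retained off-diagonal
#' entry, and — if the retained order reaches `min_order` — runs
#' [nnsd_poisson_test()] on the spectrum.
#'
#' @param sim An `fmen_similarity`.
#' @param st Candidate threshold in (0, 1).
#' @param n_bins,alpha,df Passed to [nnsd_poisson_test()].
#' @param min_order Minimum retained matrix order for a valid test
#'   (default 50); below it the decision is `"insufficient-nodes"`.
#' @return A tibble row: `st`, `order`, `decision`, `statistic`, `p_value`,
#'   `mean_spacing`.
#' @export
nnsd_test <- function(sim, st, n_bins = 20, alpha = 0.05, df = 10,
                      min_order = 50) {
  stopifnot(inherits(sim, "fmen_similarity"))
  if (st <= 0 || st >= 1) abort("`st` must lie in (0, 1)")
  m <- threshold_matrix(sim$mat, st)
  if (nrow(m) < min_order) {
    return(tibble(st = st, order = nrow(m), decision = "insufficient-nodes",
                  statistic = NA_real_, p_value = NA_real_,
                  mean_spacing = NA_real_))
  }
  res <- tryCatch(nnsd_poisson_test(m, n_bins = n_bins, alpha = alpha,
                                    df = df),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(tibble(st = st, order = nrow(m), decision = "degenerate",
                  statistic = NA_real_, p_value = NA_real_,
                  mean_spacing = NA_real_))
  }
  tibble(st = st, order = nrow(m), decision = res$decision,
         statistic = res$statistic, p_value = res$p_value,
         mean_spacing = res$mean_spacing)
}

#' Scan similarity thresholds for the RMT transition
#'
#' Evaluates the nearest-neighbour spacing decision over a grid of
#' candidate thresholds and selects the lowest threshold whose spacing
#' distribution is Poisson-like and stays Poisson-like over a stability
#' window of the next `stability_window` testable grid points, so that an
#' isolated acceptance inside the Wigner-Dyson regime is never picked. With
#' `stability_window = Inf` the rule tightens to "Poisson-like at every
#' higher testable threshold"; the windowed default is more robust, because
#' heavily thresholded matrices can drift back and forth between regimes as
#' their dense blocks are eroded. Fails with the full trace attached (field
#' `scan_trace` of the error condition) when no such threshold exists.
#'
#' @param sim An `fmen_similarity`.
#' @param st_min,st_max,step Threshold grid (defaults 0.30 to 0.99 by
#'   0.01).
#' @param stability_window Number of consecutive higher testable grid
#'   points that must also be Poisson-like (default 1, i.e. the onset
#'   must be confirmed by the next testable grid point; `Inf` for the
#'   strict rule).
#' @inheritParams nnsd_test
#' @return A list of class `fmen_scan`: `chosen_st` and the per-threshold
#'   `trace` tibble.
#' @export
scan_threshold <- function(sim, st_min = 0.30, st_max = 0.99, step = 0.01,
                           n_bins = 20, alpha = 0.05, df = 10,
                           min_order = 50, stability_window = 1) {
  if (st_min <= 0 || st_max >= 1 || st_min >= st_max) {
    abort("threshold grid must satisfy 0 < st_min < st_max < 1")
  }
  grid <- seq(st_min, st_max, by = step)
  trace <- purrr::map_dfr(grid, function(st) {
    nnsd_test(sim, st, n_bins = n_bins, alpha = alpha, df = df,
              min_order = min_order)
  })
  testable <- trace$decision %in% c("poisson-like", "goe-like")
  ok <- trace$decision == "poisson-like"
  test_idx <- which(testable)
  stable <- logical(nrow(trace))
  for (i in which(ok)) {
    higher <- test_idx[test_idx > i]
    w <- head(higher, if (is.finite(stability_window)) stability_window else
      length(higher))
    stable[i] <- all(ok[w])
  }
  if (!any(stable)) {
    abort("no stable Poisson-like threshold found in the scan grid",
          class = "fmen_scan_failure",
          scan_trace = trace)
  }
  structure(list(chosen_st = trace$st[which(stable)[1]], trace = trace),
            class = "fmen_scan")
}

#' @export
print.fmen_scan <- function(x, ...) {
  cat("<fmen_scan> chosen S_t = ", x$chosen_st, " (",
      sum(x$trace$decision == "poisson-like"), " of ", nrow(x$trace),
      " grid points Poisson-like)\n", sep = "")
  invisible(x)
}

#' @rdname scan_threshold
#' @param x An `fmen_scan` object.
#' @param ... Unused.
#' @export
tidy.fmen_scan <- function(x, ...) x$trace

#' Build an ecological network at a similarity threshold
#'
#' Undirected simple graph with an edge wherever the gene-gene similarity
#' reaches the threshold; isolated nodes are removed. Topology follows the
#' standard summaries: network size `n`, total links `L`, average
#' connectivity `avgK = 2L/n`.
#'
#' @param sim An `fmen_similarity`.
#' @param st Threshold in (0, 1).
#' @return An `fmen_network`: `graph` (igraph), `st`, `nodes`,
#'   `n_original_genes`, `n`, `links`, `avg_k`, `degree`.
#' @export
build_network <- function(sim, st) {
  stopifnot(inherits(sim, "fmen_similarity"))
  if (st <= 0 || st >= 1) abort("`st` must lie in (0, 1)")
  adj <- sim$mat >= st
  diag(adj) <- FALSE
  if (!any(adj)) abort("no edges at this threshold", class = "fmen_empty_net")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  n <- igraph::vcount(g)
  L <- igraph::ecount(g)
  structure(
    list(graph = g, st = st, nodes = igraph::V(g)$name,
         n_original_genes = nrow(sim$mat), n = n, links = L,
         avg_k = 2 * L / n,
         degree = igraph::degree(g)),
    class = "fmen_network"
  )
}

#' @export
print.fmen_network <- function(x, ...) {
  cat("<fmen_network> S_t = ", x$st, ": ", x$n, " nodes, ", x$links,
      " links, avgK = ", round(x$avg_k, 2), " (", x$n_original_genes,
      " original genes)\n", sep = "")
  invisible(x)
}

#' Module detection by greedy modularity maximization
#'
#' Partitions the (unweighted) network into modules with deterministic
#' Newman-type greedy agglomeration and reports the modularity
#' `Q = sum_c (l_c/L - (d_c/2L)^2)`. Module counts are reported both
#' including and excluding singleton modules.
#'
#' @param net An `fmen_network`.
#' @return A list of class `fmen_modules`: `membership` (named integer
#'   vector), `modularity`, `n_modules`, `n_modules_nonsingleton`.
#' @export
network_modules <- function(net) {
  stopifnot(inherits(net, "fmen_network"))
  if (net$links < 1) abort("module detection needs >= 1 edge")
  comm <- igraph::cluster_fast_greedy(net$graph)
  ## pick the cut along the greedy merge tree that maximizes recomputed
  ## modularity; ties resolve to the fewest modules, so the result is
  ## deterministic even when merge heights tie
  k_min <- igraph::components(net$graph)$no
  k_grid <- seq(k_min, igraph::vcount(net$graph))
  q_at <- vapply(k_grid, function(k) {
    igraph::modularity(net$graph, igraph::cut_at(comm, no = k))
  }, numeric(1))
  best <- k_grid[which.max(q_at)]
  memb <- igraph::cut_at(comm, no = best)
  sizes <- table(memb)
  structure(
    list(membership = setNames(as.integer(memb), igraph::V(net$graph)$name),
         modularity = igraph::modularity(net$graph, memb),
         n_modules = length(sizes),
         n_modules_nonsingleton = sum(sizes > 1)),
    class = "fmen_modules"
  )
}

#' @export
print.fmen_modules <- function(x, ...) {
  cat("<fmen_modules> Q = ", round(x$modularity, 3), ", ", x$n_modules,
      " modules (", x$n_modules_nonsingleton, " non-singleton)\n", sep = "")
  invisible(x)
}

#' Compare two ecological networks
#'
#' Reports the shared node set with its fraction relative to each network
#' size and to their mean, and — given a gene annotation — the mean
#' connectivity of the shared nodes per gene family in each network.
#'
#' @param netA,netB `fmen_network` objects.
#' @param annotation Optional tibble `gene`, `family`, `category`.
#' @return A list: `shared_nodes`, `n_shared`, `frac_of_A`, `frac_of_B`,
#'   `frac_of_mean`, and `family_connectivity` (tibble `family`,
#'   `mean_k_A`, `mean_k_B`, `n_shared`) when annotated.
#' @export
compare_networks <- function(netA, netB, annotation = NULL) {
  shared <- intersect(netA$nodes, netB$nodes)
  out <- list(
    shared_nodes = shared,
    n_shared = length(shared),
    frac_of_A = length(shared) / netA$n,
    frac_of_B = length(shared) / netB$n,
    frac_of_mean = length(shared) / mean(c(netA$n, netB$n))
  )
  if (!is.null(annotation)) {
    if (length(shared) == 0) {
      out$family_connectivity <- tibble(family = character(),
                                        mean_k_A = numeric(),
                                        mean_k_B = numeric(),
                                        n_shared = integer())
    } else {
      out$family_connectivity <- tibble(gene = shared,
                                        k_A = netA$degree[shared],
                                        k_B = netB$degree[shared]) %>%
        left_join(select(annotation, "gene", "family"), by = "gene") %>%
        group_by(.data$family) %>%
        summarise(mean_k_A = mean(.data$k_A), mean_k_B = mean(.data$k_B),
                  n_shared = n(), .groups = "drop")
    }
  }
  out
}

#' Node attribute and edge tables for network export
#'
#' Tables suitable for import into external network viewers: an edge list
#' with the similarity of each link, and a node table with family,
#' category, connectivity and module assignment.
#'
#' @param net An `fmen_network`.
#' @param sim The `fmen_similarity` the network was built from.
#' @param modules Optional [network_modules()] result.
#' @param annotation Optional annotation tibble.
#' @return List of tibbles `edges` (`gene_a`, `gene_b`, `similarity`) and
#'   `nodes` (`gene`, `k`, `module`, `family`, `category`).
#' @export
network_tables <- function(net, sim, modules = NULL, annotation = NULL) {
  el <- igraph::as_edgelist(net$graph)
  edges <- tibble(gene_a = el[, 1], gene_b = el[, 2],
                  similarity = sim$mat[el])
  nodes <- tibble(gene = net$nodes, k = unname(net$degree[net$nodes]))
  nodes$module <- if (!is.null(modules)) {
    unname(modules$membership[nodes$gene])
  } else NA_integer_
  if (!is.null(annotation)) {
    nodes <- left_join(nodes,
                       select(annotation, "gene", "family", "category"),
                       by = "gene")
  }
  list(edges = edges, nodes = nodes)
}

#' @rdname build_network
#' @param x An `fmen_network` object.
#' @param ... Unused.
#' @export
glance.fmen_network <- function(x, ...) {
  tibble(st = x$st, n_original_genes = x$n_original_genes, n = x$n,
         links = x$links, avg_k = x$avg_k)
}

#' @rdname build_network
#' @export
tidy.fmen_network <- function(x, ...) {
  tibble(gene = x$nodes, k = unname(x$degree[x$nodes]))
}
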