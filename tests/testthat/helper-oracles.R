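# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (loops, no vectorization) and never call package code.

brute_qc <- function(spots, flags_remove = c(1, 3), snr_min = 2) {
  keep <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    keep[i] <- !(spots$flag[i] %in% flags_remove) && spots$snr[i] >= snr_min
  }
  spots[keep, , drop = FALSE]
}

brute_outlier <- function(x, k = 2) {
  repeat {
    if (length(x) < 2) return(x)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(x)
    bad <- which(abs(x - mean(x)) > k * s)
    if (length(bad) == 0) return(x)
    x <- x[-bad]
  }
}

brute_detect <- function(positive, total, fraction = 0.34, min_spots = 2) {
  out <- logical(length(positive))
  for (i in seq_along(positive)) {
    need <- max(min_spots, ceiling(fraction * total[i]))
    out[i] <- positive[i] >= need
  }
  out
}

brute_rel_abund <- function(mat) {
  totals <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) totals[j] <- sum(mat[, j])
  mean_total <- mean(totals)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    for (i in seq_len(nrow(mat))) {
      out[i, j] <- log(mat[i, j] / totals[j] * mean_total + 1)
    }
  }
  out
}

brute_bray <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      d[j, k] <- sum(abs(mat[, j] - mat[, k])) / sum(mat[, j] + mat[, k])
    }
  }
  d
}

brute_edges <- function(sim_mat, st) {
  edges <- NULL
  n <- nrow(sim_mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sim_mat[i, j] >= st) {
        edges <- rbind(edges, c(rownames(sim_mat)[i], rownames(sim_mat)[j]))
      }
    }
  }
  edges
}

# Symmetric random GOE matrix, scaled to unit spectral radius order.
goe_matrix <- function(n) {
  m <- matrix(rnorm(n * n), n)
  (m + t(m)) / sqrt(2 * n)
}

# Build an fmen_network with an exact node and link count through the
# package's own constructor: nodes are laid out as paths (guaranteeing no
# isolates), then extra non-adjacent pairs are added until L edges exist.
network_with_counts <- function(n, L) {
  stopifnot(L >= n / 2)
  sim <- matrix(0, n, n, dimnames = list(sprintf("g%04d", 1:n),
                                         sprintf("g%04d", 1:n)))
  diag(sim) <- 1
  add_edge <- function(i, j) sim[c(i, j), c(j, i)] <<- pmax(sim[c(i, j), c(j, i)], 0.99)
  if (L >= n - 1) {
    for (i in seq_len(n - 1)) add_edge(i, i + 1)
    extra <- L - (n - 1)
    k <- 2
    while (extra > 0) {
      for (i in seq_len(n - k)) {
        if (extra == 0) break
        add_edge(i, i + k)
        extra <- extra - 1
      }
      k <- k + 1
    }
  } else {
    # forest of n - L path components, each of size >= 2
    n_comp <- n - L
    sizes <- rep(floor(n / n_comp), n_comp)
    sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1
    start <- 1
    for (s in sizes) {
      for (i in seq_len(s - 1)) add_edge(start + i - 1, start + i)
      start <- start + s
    }
  }
  sim_obj <- structure(list(mat = sim, n_samples = NA_integer_,
                            excluded = character()),
                       class = "fmen_similarity")
  build_network(sim_obj, 0.9)
}

# Small default-shaped generator config used across tests.
small_config <- function(seed, ...) {
  synth_config(n_genes = 120, n_modules = 2, module_size = 12,
               extra_core_frac_planting = 0.25, seed = seed, ...)
}
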