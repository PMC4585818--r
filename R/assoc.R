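#' Distance matrix container
#'
#' Thin wrapper recording the metric alongside a symmetric, zero-diagonal
#' dissimilarity matrix over samples.
#'
#' @param mat Symmetric numeric matrix with sample dimnames.
#' @param metric Metric name, e.g. `"bray_curtis"` or `"euclidean"`.
#' @return An `fmen_dist` object.
#' @export
fmen_dist <- function(mat, metric) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-12) abort("distance matrix not symmetric")
  if (any(abs(diag(mat)) > 1e-12)) abort("distance matrix diagonal not zero")
  if (any(mat < -1e-12)) abort("negative dissimilarities")
  structure(list(mat = mat, metric = metric,
                 samples = rownames(mat)),
            class = "fmen_dist")
}

#' @export
print.fmen_dist <- function(x, ...) {
  cat("<fmen_dist> ", x$metric, ", ", nrow(x$mat), " samples\n", sep = "")
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j, k) = sum_i |a_ij - a_ik| / sum_i (a_ij + a_ik)` over gene
#' abundances; identical samples give 0 and disjoint supports give 1.
#'
#' @param abund An [abundance_matrix()] or a non-negative gene x sample
#'   matrix.
#' @return An [fmen_dist()] with metric `"bray_curtis"`.
#' @export
bray_curtis <- function(abund) {
  mat <- if (inherits(abund, "fmen_abundance")) abund$values else abund
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) abort("need >= 2 samples")
  if (any(mat < 0)) abort("Bray-Curtis requires non-negative abundances")
  if (any(colSums(mat) == 0)) {
    abort(paste("all-zero sample(s):",
                paste(colnames(mat)[colSums(mat) == 0], collapse = ", ")))
  }
  d <- as.matrix(vegan::vegdist(t(mat), method = "bray"))
  fmen_dist(d, "bray_curtis")
}

#' Euclidean distance over environmental variables
#'
#' @param env Tibble with a `sample` column plus numeric variables.
#' @param variables Variables to use (default: all numeric columns).
#' @param standardize Z-score each variable first (default `TRUE`).
#' @return An [fmen_dist()] with metric `"euclidean"`.
#' @export
euclidean_env <- function(env, variables = NULL, standardize = TRUE) {
  stopifnot(is.data.frame(env), "sample" %in% names(env))
  if (is.null(variables)) {
    variables <- setdiff(names(env)[vapply(env, is.numeric, TRUE)], "sample")
  }
  x <- as.matrix(env[, variables, drop = FALSE])
  rownames(x) <- env$sample
  if (anyNA(x)) {
    bad <- env$sample[apply(x, 1, anyNA)]
    abort(paste("missing environmental values for sample(s):",
                paste(bad, collapse = ", ")))
  }
  if (standardize) x <- scale(x)
  x[is.nan(x)] <- 0  # constant column under z-scoring
  fmen_dist(as.matrix(dist(x)), "euclidean")
}

upper_vec <- function(d) {
  m <- if (inherits(d, "fmen_dist")) d$mat else d
  m[upper.tri(m)]
}

align_dist <- function(dA, dB) {
  if (!setequal(dA$samples, dB$samples)) {
    abort("distance matrices cover different sample sets")
  }
  fmen_dist(dB$mat[dA$samples, dA$samples], dB$metric)
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the vectorized upper
#' triangles. Significance is assessed by jointly permuting the rows and
#' columns of the second matrix; the default alternative is one-tailed
#' positive (`greater`), with `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @param dA,dB [fmen_dist()] objects over the same samples.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return An `fmen_mantel` object with `r`, `p`, `n_permutations`,
#'   `conditioned_on` (empty), `alternative`.
#' @export
mantel_test <- function(dA, dB, n_perm = 999, seed = 1L,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("`n_perm` must be >= 99")
  dB <- align_dist(dA, dB)
  a <- upper_vec(dA)
  b <- upper_vec(dB)
  if (sd(a) == 0 || sd(b) == 0) abort("constant distance vector")
  r_obs <- cor(a, b)
  n <- nrow(dA$mat)
  ut <- which(upper.tri(dA$mat), arr.ind = TRUE)
  r_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(a, dB$mat[cbind(p[ut[, 1]], p[ut[, 2]])])
    }, numeric(1))
  })
  p_val <- perm_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p = p_val, n_permutations = n_perm,
                 conditioned_on = character(), alternative = alternative,
                 metricA = dA$metric, metricB = dB$metric),
            class = "fmen_mantel")
}

perm_pvalue <- function(obs, perm, alternative) {
  switch(alternative,
    greater = (1 + sum(perm >= obs)) / (1 + length(perm)),
    less = (1 + sum(perm <= obs)) / (1 + length(perm)),
    two.sided = (1 + sum(abs(perm) >= abs(obs))) / (1 + length(perm))
  )
}

partial_r <- function(r_ab, r_ac, r_bc) {
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' The statistic is the first-order partial correlation
#' `r_AB|C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` of the
#' upper-triangle vectors. Significance comes from jointly permuting the
#' rows/columns of the first matrix while holding the second and third
#' fixed, recomputing the partial statistic each time.
#'
#' @inheritParams mantel_test
#' @param dC Conditioning [fmen_dist()].
#' @return An `fmen_mantel` object; `conditioned_on` records `dC`'s metric.
#' @export
partial_mantel_test <- function(dA, dB, dC, n_perm = 999, seed = 1L,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("`n_perm` must be >= 99")
  dB <- align_dist(dA, dB)
  dC <- align_dist(dA, dC)
  a <- upper_vec(dA); b <- upper_vec(dB); cc <- upper_vec(dC)
  if (sd(a) == 0 || sd(b) == 0 || sd(cc) == 0) {
    abort("constant distance vector")
  }
  r_ac <- cor(a, cc); r_bc <- cor(b, cc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
    abort("conditioning matrix is collinear with an input (|r| = 1)")
  }
  r_obs <- partial_r(cor(a, b), r_ac, r_bc)
  n <- nrow(dA$mat)
  ut <- which(upper.tri(dA$mat), arr.ind = TRUE)
  r_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      ap <- dA$mat[cbind(p[ut[, 1]], p[ut[, 2]])]
      partial_r(cor(ap, b), cor(ap, cc), r_bc)
    }, numeric(1))
  })
  p_val <- perm_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p = p_val, n_permutations = n_perm,
                 conditioned_on = dC$metric, alternative = alternative,
                 metricA = dA$metric, metricB = dB$metric),
            class = "fmen_mantel")
}

#' @export
print.fmen_mantel <- function(x, ...) {
  kind <- if (length(x$conditioned_on) > 0 && nzchar(x$conditioned_on[1])) {
    "partial Mantel"
  } else "Mantel"
  cat("<fmen_mantel> ", kind, ": r = ", round(x$r, 4), ", p = ",
      signif(x$p, 4), " (", x$n_permutations, " permutations, ",
      x$alternative, ")\n", sep = "")
  invisible(x)
}

#' @rdname mantel_test
#' @param x An `fmen_mantel` object.
#' @param ... Unused.
#' @export
tidy.fmen_mantel <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_permutations = x$n_permutations,
         alternative = x$alternative,
         conditioned_on = paste(x$conditioned_on, collapse = ","))
}

#' Mantel screen of community structure against environmental variables
#'
#' Runs one (partial) Mantel test per environmental variable against the
#' community distance matrix, mirroring a variables x (r, p) results table.
#'
#' @param d_comm Community [fmen_dist()] (e.g. [bray_curtis()]).
#' @param env Environment tibble with `sample` plus numeric variables.
#' @param variables Variables to screen (default all numeric).
#' @param conditioning Optional character vector of variable names to
#'   condition on (partial Mantel); `NULL` for simple Mantel.
#' @inheritParams mantel_test
#' @return A tibble `variable`, `r`, `p`.
#' @export
mantel_screen <- function(d_comm, env, variables = NULL, conditioning = NULL,
                          n_perm = 999, seed = 1L) {
  if (is.null(variables)) {
    variables <- setdiff(names(env)[vapply(env, is.numeric, TRUE)], "sample")
  }
  variables <- setdiff(variables, conditioning)
  d_cond <- if (!is.null(conditioning)) {
    euclidean_env(env, conditioning)
  } else NULL
  purrr::map_dfr(variables, function(v) {
    d_env <- euclidean_env(env, v)
    res <- if (is.null(d_cond)) {
      mantel_test(d_comm, d_env, n_perm = n_perm, seed = seed)
    } else {
      partial_mantel_test(d_comm, d_env, d_cond, n_perm = n_perm,
                          seed = seed)
    }
    tibble(variable = v, r = res$r, p = res$p)
  })
}
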