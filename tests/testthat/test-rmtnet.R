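sim_from_matrix <- function(m) {
  structure(list(mat = m, n_samples = NA_integer_, excluded = character()),
            class = "fmen_similarity")
}

test_that("similarity is |Pearson r| and matches an independent oracle", {
  withr::with_seed(41, {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    m["g2", ] <- -2 * m["g1", ] + 3          # affine anti-correlation
    s <- gene_similarity(m)
    expect_equal(s$mat["g1", "g2"], 1)
    for (i in 1:3) for (j in 1:3) {
      expect_equal(s$mat[i, j], abs(cor(m[i, ], m[j, ])), tolerance = 1e-12)
    }
    # independent long rows have similarity near zero
    long <- matrix(rnorm(2 * 2000), 2, 2000,
                   dimnames = list(c("a", "b"), NULL))
    colnames(long) <- paste0("s", 1:2000)
    expect_lt(gene_similarity(long)$mat["a", "b"], 0.1)
    # constant genes are excluded with a report
    mc <- rbind(m, flat = rep(2, 4))
    sc <- gene_similarity(mc)
    expect_equal(sc$excluded, "flat")
    expect_false("flat" %in% rownames(sc$mat))
  })
})

test_that("unfolded spacings have mean near one for large matrices", {
  withr::with_seed(42, {
    for (n in c(200, 400)) {
      uf <- unfold_spectrum(eigen(goe_matrix(n), symmetric = TRUE,
                                  only.values = TRUE)$values)
      expect_lt(abs(mean(uf$spacings) - 1), 0.05)
      expect_true(all(uf$spacings >= 0))
    }
  })
})

test_that("NNSD discriminates Poisson from GOE spectra", {
  withr::with_seed(43, {
    pois <- replicate(5, nnsd_poisson_test(diag(runif(500)))$decision)
    goe <- replicate(5, nnsd_poisson_test(goe_matrix(500))$decision)
    # acceptance of the true Poisson null is itself a 5%-level test, so a
    # single rejection among few replicates is within expectation
    expect_gte(mean(pois == "poisson-like"), 0.8)
    expect_true(all(goe == "goe-like"))
    # superposing two independent GOE blocks moves spacings toward Poisson
    dec <- replicate(5, {
      single <- nnsd_poisson_test(goe_matrix(400))$statistic
      block <- rbind(cbind(goe_matrix(200), matrix(0, 200, 200)),
                     cbind(matrix(0, 200, 200), goe_matrix(200)))
      nnsd_poisson_test(block)$statistic < single
    })
    expect_gte(mean(dec), 0.8)
  })
})

test_that("threshold scan recovers the gap in modular similarity", {
  withr::with_seed(44, {
    # three strong blocks over a weak background
    n <- 90
    m <- matrix(runif(n * n, 0, 0.5), n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    for (b in 0:2) {
      i <- b * 30 + 1:30
      m[i, i] <- runif(30 * 30, 0.85, 1)
      m[i, i][lower.tri(m[i, i])] <- t(m[i, i])[lower.tri(m[i, i])]
    }
    m <- (m + t(m)) / 2
    diag(m) <- 1
    rownames(m) <- colnames(m) <- sprintf("g%02d", 1:n)
    scan <- scan_threshold(sim_from_matrix(m), min_order = 40)
    expect_gte(scan$chosen_st, 0.5)
    expect_lte(scan$chosen_st, 0.86)
    net <- build_network(sim_from_matrix(m), scan$chosen_st)
    mods <- network_modules(net)
    expect_gte(mods$n_modules, 3)
  })
})

test_that("degenerate similarity matrices fail the scan explicitly", {
  idm <- diag(60)
  rownames(idm) <- colnames(idm) <- paste0("g", 1:60)
  expect_error(scan_threshold(sim_from_matrix(idm)),
               class = "fmen_scan_failure")
  ones <- matrix(1, 60, 60, dimnames = list(paste0("g", 1:60),
                                            paste0("g", 1:60)))
  expect_error(scan_threshold(sim_from_matrix(ones)),
               class = "fmen_scan_failure")
  err <- tryCatch(scan_threshold(sim_from_matrix(ones)),
                  error = function(e) e)
  expect_s3_class(err$scan_trace, "tbl_df")  # audit trace travels with it
})

test_that("network construction hits closed forms and the avgK identity", {
  # path on 3 nodes
  p3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p3[cbind(c(1, 2), c(2, 3))] <- 0.95
  p3 <- p3 + t(p3); diag(p3) <- 1
  net <- build_network(sim_from_matrix(p3), 0.9)
  expect_equal(net$n, 3)
  expect_equal(net$links, 2)
  expect_equal(net$avg_k, 4 / 3)
  # complete graph on n nodes: avgK = n - 1
  n <- 7
  km <- matrix(0.99, n, n, dimnames = list(paste0("g", 1:n),
                                           paste0("g", 1:n)))
  diag(km) <- 1
  expect_equal(build_network(sim_from_matrix(km), 0.9)$avg_k, n - 1)
  # no edges
  expect_error(build_network(sim_from_matrix(diag(3) + 0), 0.5),
               class = "fmen_empty_net")
})

test_that("published node/link counts reproduce the printed avgK", {
  printed <- data.frame(n = c(348, 1834, 58, 354, 45, 272),
                        L = c(671, 7585, 56, 911, 82, 634),
                        avgK = c(3.86, 8.27, 1.93, 5.15, 3.64, 4.66))
  for (i in seq_len(nrow(printed))) {
    net <- network_with_counts(printed$n[i], printed$L[i])
    expect_equal(net$n, printed$n[i])
    expect_equal(net$links, printed$L[i])
    expect_equal(round(net$avg_k, 2), printed$avgK[i])
    expect_equal(net$avg_k, 2 * net$links / net$n)  # exact identity
  }
})

test_that("edges match a brute-force double loop and thresholds nest", {
  withr::with_seed(45, {
    x <- matrix(rnorm(150 * 8), 150,
                dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:8)))
    s <- gene_similarity(x)
    for (st in c(0.5, 0.7, 0.9)) {
      net <- tryCatch(build_network(s, st), error = function(e) NULL)
      oracle <- brute_edges(s$mat, st)
      if (is.null(net)) {
        expect_null(oracle)
      } else {
        got <- igraph::as_edgelist(net$graph)
        norm <- function(e) {
          paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
        }
        expect_setequal(norm(got), norm(oracle))
      }
    }
    # monotonicity: raising the threshold never adds links or nodes
    nets <- lapply(c(0.5, 0.6, 0.7), function(st) build_network(s, st))
    expect_true(all(diff(vapply(nets, `[[`, 0, "links")) <= 0))
    expect_true(all(diff(vapply(nets, `[[`, 0, "n")) <= 0))
  })
})

test_that("modularity hits its closed forms", {
  # two disconnected 4-cliques: Q = 2 * (1/2 - 1/16) ... evaluated = 0.5
  n <- 8
  m <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  m[1:4, 1:4] <- 0.99
  m[5:8, 5:8] <- 0.99
  diag(m) <- 1
  net <- build_network(sim_from_matrix(m), 0.9)
  mods <- network_modules(net)
  expect_equal(mods$modularity, 0.5)
  expect_equal(mods$n_modules, 2)
  # complete graph: one module, Q = 0
  km <- matrix(0.99, 6, 6, dimnames = list(paste0("g", 1:6),
                                           paste0("g", 1:6)))
  diag(km) <- 1
  mods2 <- network_modules(build_network(sim_from_matrix(km), 0.9))
  expect_equal(mods2$modularity, 0)
  expect_equal(mods2$n_modules, 1)
})

test_that("network comparison reports shared nodes and family connectivity", {
  km <- matrix(0.99, 6, 6, dimnames = list(paste0("g", 1:6),
                                           paste0("g", 1:6)))
  diag(km) <- 1
  ann <- tibble::tibble(gene = paste0("g", 1:6),
                        family = rep(c("amyA", "nifH"), 3),
                        category = "x")
  netA <- build_network(sim_from_matrix(km), 0.9)
  cmpAA <- compare_networks(netA, netA, ann)
  expect_equal(cmpAA$n_shared, 6)
  expect_equal(cmpAA$frac_of_mean, 1)
  expect_equal(cmpAA$family_connectivity$mean_k_A,
               cmpAA$family_connectivity$mean_k_B)
  # disjoint node sets share nothing
  km2 <- km
  rownames(km2) <- colnames(km2) <- paste0("h", 1:6)
  cmpAB <- compare_networks(netA, build_network(sim_from_matrix(km2), 0.9),
                            ann)
  expect_equal(cmpAB$n_shared, 0)
  expect_equal(nrow(cmpAB$family_connectivity), 0)
})

test_that("shared-node arithmetic reproduces the published 22.1%", {
  netA <- network_with_counts(348, 671)
  netB <- network_with_counts(1834, 7585)
  # relabel B so that exactly 241 node names coincide with A's
  idx <- c(1:241, 1842:3434)
  rename_map <- sprintf("g%04d", idx)
  netB$nodes <- rename_map
  names(netB$degree) <- rename_map
  cmp <- compare_networks(netA, netB)
  expect_equal(cmp$n_shared, 241)
  expect_equal(round(100 * cmp$frac_of_mean, 1), 22.1)
})

test_that("export tables carry similarities, degrees and modules", {
  withr::with_seed(46, {
    x <- matrix(rnorm(40 * 10), 40,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:10)))
    s <- gene_similarity(x)
    net <- build_network(s, 0.6)
    mods <- network_modules(net)
    ann <- tibble::tibble(gene = rownames(x), family = "f", category = "c")
    tabs <- network_tables(net, s, mods, ann)
    expect_equal(nrow(tabs$edges), net$links)
    expect_true(all(tabs$edges$similarity >= 0.6))
    expect_equal(nrow(tabs$nodes), net$n)
    expect_equal(sort(unique(tabs$nodes$module)),
                 sort(unique(unname(mods$membership))))
    expect_equal(glance(net)$avg_k, net$avg_k)
    expect_equal(nrow(tidy(net)), net$n)
  })
})
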