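spot_row <- function(flag, snr, signal = 100) {
  tibble::tibble(slide = "s1", subgrid = 1L, gene = "g1", probe = 1L,
                 probe_id = "g1_p1", sample = "a", tech_rep = 1L,
                 signal = signal, flag = flag, snr = snr,
                 is_reference = FALSE)
}

test_that("QC removes flagged and low-SNR spots with an inclusive boundary", {
  spots <- dplyr::bind_rows(
    spot_row(0, 5), spot_row(1, 5), spot_row(3, 5),
    spot_row(0, 1.9), spot_row(0, 2.0), spot_row(0, 0)
  )
  out <- qc_filter(spots)
  expect_equal(nrow(out), 2)
  expect_equal(out$snr, c(5, 2.0))
  # flagged spots go even at high SNR
  expect_equal(nrow(qc_filter(dplyr::bind_rows(spot_row(1, 10),
                                               spot_row(0, 10)))), 1)
  # empty result is its own error class, distinct from malformed input
  expect_error(qc_filter(spot_row(1, 10)), class = "fmen_empty_qc")
  expect_error(qc_filter(data.frame(x = 1)), "must be a data frame with")
})

test_that("QC matches the brute-force oracle on random instances", {
  withr::with_seed(8, {
    for (i in 1:10) {
      spots <- spot_row(0, 1)[rep(1, 20), ]
      spots$flag <- sample(c(0L, 1L, 2L, 3L), 20, replace = TRUE)
      spots$snr <- round(runif(20, 0, 4), 2)
      got <- tryCatch(qc_filter(spots), error = function(e) spots[0, ])
      expect_equal(got, brute_qc(spots), ignore_attr = TRUE)
    }
  })
})

test_that("normalization is the identity when reference spots are constant", {
  d <- synth_dataset(synth_config(
    n_genes = 30, n_modules = 0, noise_cv = 0, subgrid_bias_sd = 0,
    tech_bias_sd = 0, sample_bias_sd = 0, flag_rate = 0, low_snr_rate = 0,
    seed = 3
  ))
  out <- normalize_spots(d$spots)
  expect_equal(out$signal, d$spots$signal, tolerance = 1e-12)
})

test_that("sub-grid scalings follow the mean-ratio rule", {
  # two sub-grids with reference means 100 and 200; slide mean 150
  spots <- tibble::tibble(
    slide = "s1", subgrid = rep(1:2, each = 2),
    gene = c("g1", "REF", "g1", "REF"), probe = c(1L, 0L, 2L, 0L),
    probe_id = c("g1_p1", "R1", "g1_p2", "R2"),
    sample = "a", tech_rep = 1L,
    signal = c(80, 100, 80, 200), flag = 0L, snr = 10,
    is_reference = c(FALSE, TRUE, FALSE, TRUE)
  )
  out <- normalize_spots(spots)
  # scalings 1.5 and 0.75 at the sub-grid level; later levels are identity
  # here (single slide, single sample whose mean equals the global mean)
  expect_equal(out$signal[1] / spots$signal[1], 1.5)
  expect_equal(out$signal[3] / spots$signal[3], 0.75)
})

test_that("normalization shrinks reference variability across sub-grids", {
  d <- synth_dataset(synth_config(n_genes = 50, n_modules = 0,
                                  subgrid_bias_sd = 0.4, seed = 6))
  cv <- function(x) sd(x) / mean(x)
  ref_cv <- function(spots) {
    spots %>%
      dplyr::filter(is_reference) %>%
      dplyr::group_by(slide, subgrid) %>%
      dplyr::summarise(m = mean(signal), .groups = "drop") %>%
      dplyr::pull(m) %>% cv()
  }
  expect_lt(ref_cv(normalize_spots(d$spots)), ref_cv(d$spots))
})

test_that("missing reference spots are reported", {
  spots <- spot_row(0, 10)
  expect_error(normalize_spots(spots), "reference")
})

test_that("outlier loop removes gross outliers and is inert for n <= 5", {
  expect_equal(remove_outlier_replicates(c(5, 5, 5)), c(5, 5, 5))
  expect_equal(remove_outlier_replicates(c(1, 1, 1, 1, 1, 1, 1, 100)),
               rep(1, 7))
  expect_equal(remove_outlier_replicates(42), 42)
  # analytic bound: max |x - mean| / sd = (n-1)/sqrt(n) < 2 for n <= 5
  withr::with_seed(13, {
    for (i in 1:50) {
      x <- rnorm(sample(2:5, 1), sd = 10)
      expect_equal(remove_outlier_replicates(x), x)
    }
  })
})

test_that("outlier loop matches the brute-force oracle", {
  withr::with_seed(14, {
    for (i in 1:30) {
      x <- c(rnorm(sample(3:12, 1)), rnorm(sample(0:3, 1), mean = 50))
      expect_equal(remove_outlier_replicates(x), brute_outlier(x))
    }
  })
})

test_that("detection call applies the fraction rule with a floor of two", {
  expect_false(detection_call(1, 1))          # floor of 2 unmet
  expect_true(detection_call(2, 3))           # ceil(1.02) = 2
  expect_false(detection_call(2, 6))          # ceil(2.04) = 3
  expect_true(detection_call(3, 6))
  expect_error(detection_call(4, 3), "exceeds")
  expect_error(detection_call(1, 0), "total")
  withr::with_seed(15, {
    tot <- sample(1:12, 50, replace = TRUE)
    pos <- vapply(tot, function(t) sample(0:t, 1), integer(1))
    expect_equal(detection_call(pos, tot), brute_detect(pos, tot))
  })
})

test_that("replicate-consistency filter zeroes unsupported groups", {
  md <- tibble::tibble(sample = paste0("a", 1:3), site = "X",
                       treatment = "planting", bio_rep = 1:3)
  det <- rbind(one_of_three = c(TRUE, FALSE, FALSE),
               two_of_three = c(TRUE, TRUE, FALSE),
               three_of_three = c(TRUE, TRUE, TRUE))
  colnames(det) <- md$sample
  out <- replicate_consistency_filter(det, md)
  expect_equal(unname(out["one_of_three", ]), c(FALSE, FALSE, FALSE))
  expect_equal(unname(out["two_of_three", ]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(out["three_of_three", ]), c(TRUE, TRUE, TRUE))
})

test_that("abundance transform matches hand computations", {
  # two samples, one gene each with signal 10: meanTotal 10, all ln(11)
  m <- matrix(c(10, 10), 1, dimnames = list("g1", c("a", "b")))
  md <- tibble::tibble(sample = c("a", "b"), site = "X", treatment = "t",
                       bio_rep = 1:2)
  out <- relative_abundance_transform(m, md)
  expect_equal(unname(out$values[1, ]), c(log(11), log(11)))
  # zeros map to zero; single sample keeps its own scale
  m2 <- matrix(c(3, 0, 7), 3, 1, dimnames = list(paste0("g", 1:3), "a"))
  out2 <- relative_abundance_transform(m2, md[1, ])
  expect_equal(unname(out2$values[, 1]), log(c(3, 7) + 1))  # zero row dropped
  expect_error(relative_abundance_transform(
    matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "a")), md[1, ]
  ), "all-zero")
})

test_that("abundance transform matches the brute-force oracle", {
  withr::with_seed(16, {
    m <- matrix(rpois(60, 40), 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    md <- tibble::tibble(sample = paste0("s", 1:6), site = "X",
                         treatment = "t", bio_rep = 1:6)
    out <- relative_abundance_transform(m, md)
    expect_equal(out$values, brute_rel_abund(m), tolerance = 1e-12)
  })
})

test_that("scaled relative abundances conserve the mean sample total", {
  d <- synth_dataset(small_config(seed = 31))
  a <- preprocess_spots(d$spots, d$metadata)
  pre_ln <- exp(a$values) - 1
  totals <- colSums(pre_ln)
  expect_equal(max(abs(totals - mean(totals))) / mean(totals), 0,
               tolerance = 1e-9)
})

test_that("detection mask and positivity coincide; no all-zero gene rows", {
  d <- synth_dataset(small_config(seed = 32))
  a <- preprocess_spots(d$spots, d$metadata)
  expect_identical(a$detected, a$values > 0)
  expect_true(all(rowSums(a$values) > 0))
  # replicate consistency: any detected gene x group has >= 2 supporting reps
  groups <- paste(a$metadata$site, a$metadata$treatment)
  for (g in unique(groups)) {
    sub <- a$detected[, groups == g, drop = FALSE]
    expect_true(all(rowSums(sub) != 1))
  }
})
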