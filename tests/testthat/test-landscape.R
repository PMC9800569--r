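burden_fixture <- function(lengths_mb, chrom = "chr1") {
  # interstitial AIs (3/1) of the given lengths on a diploid background
  rows <- list(data.frame(chromosome = chrom, start_bp = 1, end_bp = 1e6,
                          major_cn = 1, minor_cn = 1))
  pos <- 1e6 + 1
  for (l in lengths_mb) {
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chrom, start_bp = pos, end_bp = pos + l * 1e6 - 1,
      major_cn = 3, minor_cn = 1)
    pos <- pos + l * 1e6
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chrom, start_bp = pos, end_bp = pos + 1e6 - 1,
      major_cn = 1, minor_cn = 1)
    pos <- pos + 1e6
  }
  segment_profile("b", do.call(rbind, rows))
}

test_that("ai_burden_summary filters the length window", {
  asm <- test_assembly()
  p <- burden_fixture(c(2, 4, 60))
  b <- ai_burden_summary(list(p = p), asm)
  expect_equal(b$n_ai_in_window, 1L)
  expect_equal(b$median_ai_length_mb, 4)
  # no AIs -> count 0, median undefined
  flat <- segment_profile("f", data.frame(
    chromosome = "chr1", start_bp = 1, end_bp = 100e6,
    major_cn = 1, minor_cn = 1))
  b0 <- ai_burden_summary(list(f = flat), asm)
  expect_equal(b0$n_ai_in_window, 0L)
  expect_true(is.na(b0$median_ai_length_mb))
  expect_error(ai_burden_summary(list(p = p), asm, min_mb = 50, max_mb = 3),
               "min_mb")
})

test_that("ai_burden_summary matches a brute-force filter on random data", {
  set.seed(404)
  asm <- test_assembly()
  for (i in 1:25) {
    p <- random_profile(paste0("r", i))
    b <- ai_burden_summary(stats::setNames(list(p), p$sample_id), asm,
                           mode = "total_cn")
    sm <- smooth_segments(p)
    seg <- sm$segments
    n <- 0L; lens <- numeric()
    for (j in seq_len(nrow(seg))) {
      r <- seg[j, ]
      if (r$major_cn + r$minor_cn == 2) next
      ext <- .cov_extent(seg, r$chromosome)
      if (r$start_bp == ext[1] && r$end_bp == ext[2]) next
      l <- (r$end_bp - r$start_bp + 1) / 1e6
      if (l > 3 && l < 50) { n <- n + 1L; lens <- c(lens, l) }
    }
    expect_equal(b$n_ai_in_window, n)
    if (n > 0) expect_equal(b$median_ai_length_mb, stats::median(lens))
  }
})

test_that("skewness is Fisher-Pearson g1 and vanishes on symmetry", {
  x <- c(1, 2, 3, 4, 5, 3, 3)
  m <- mean(x)
  expect_equal(sample_skewness(x),
               mean((x - m)^3) / mean((x - m)^2)^1.5)
  sym <- c(-3, -1, 0, 1, 3, -2, 2)
  expect_lt(abs(sample_skewness(sym)), 1e-12)
  expect_error(sample_skewness(rep(2, 5)), "constant")
})

test_that("cluster_cancer_types matches a naive complete-linkage oracle", {
  feats <- function(n, seed) {
    set.seed(seed)
    data.frame(cohort_label = paste0("c", seq_len(n)),
               median_ai_count = stats::runif(n, 5, 80),
               median_ai_length_mb = stats::runif(n, 1, 30),
               length_skewness = stats::rnorm(n))
  }
  # two cohorts -> a single merge
  hc2 <- cluster_cancer_types(feats(2, 1))
  expect_equal(nrow(hc2$merge), 1L)
  # two tight groups with identical features within group split at the top
  f <- data.frame(cohort_label = c("a1", "a2", "b1", "b2"),
                  median_ai_count = c(10, 10, 60, 60),
                  median_ai_length_mb = c(2, 2, 20, 20),
                  length_skewness = c(0.1, 0.1, 1.5, 1.5))
  hc <- cluster_cancer_types(f)
  top <- stats::cutree(hc, k = 2)
  expect_equal(unname(top), c(1, 1, 2, 2))
  expect_equal(unname(hc$height[1:2]), c(0, 0))
  # random tables agree with the independent agglomerative oracle
  for (seed in 1:5) {
    f <- feats(8, seed + 10)
    hc <- cluster_cancer_types(f)
    m <- scale(as.matrix(f[, 2:4]))
    coph_oracle <- oracle_complete_linkage_cophenetic(m)
    expect_equal(unname(as.matrix(stats::cophenetic(hc))),
                 unname(coph_oracle), tolerance = 1e-10)
  }
  f_bad <- feats(3, 2); f_bad$length_skewness[2] <- NaN
  expect_error(cluster_cancer_types(f_bad), "non-finite")
})

test_that("differential_ai_by_length fold changes and role swap", {
  asm <- test_assembly()
  a <- list(s1 = burden_fixture(c(5, 12)), s2 = burden_fixture(c(5.2, 12.3)))
  # identical cohorts -> fold change 0, p = 1 everywhere
  d0 <- differential_ai_by_length(a, a, asm, bin_edges_mb = c(3, 10, 20))
  expect_equal(d0$fold_change, c(0, 0))
  expect_true(all(d0$p_two_sided == 1))
  # doubled per-sample counts in one bin -> fold change 1
  b <- list(s1 = burden_fixture(c(5, 5.5, 12)),
            s2 = burden_fixture(c(5.1, 5.4, 12.3)))
  d1 <- differential_ai_by_length(b, a, asm, bin_edges_mb = c(3, 10, 20))
  expect_equal(d1$fold_change[1], 1)
  expect_equal(d1$fold_change[2], 0)
  # swapping cohorts negates log(fold_change + 1), keeps p
  d2 <- differential_ai_by_length(a, b, asm, bin_edges_mb = c(3, 10, 20))
  expect_equal(log(d2$fold_change + 1), -log(d1$fold_change + 1))
  expect_equal(d2$p_two_sided, d1$p_two_sided)
  expect_error(differential_ai_by_length(list(), a, asm), "cohort")
})

test_that("a planted length enrichment yields the smallest p in its bin", {
  set.seed(77)
  asm <- test_assembly()
  mk <- function(extra_8mb) {
    lens <- c(stats::runif(3, 3, 6), rep(8.4, extra_8mb),
              stats::runif(2, 12, 18))
    burden_fixture(sample(lens))
  }
  a <- lapply(1:8, function(i) mk(extra_8mb = 4))
  b <- lapply(1:8, function(i) mk(extra_8mb = 0))
  names(a) <- paste0("a", 1:8); names(b) <- paste0("b", 1:8)
  d <- differential_ai_by_length(a, b, asm, bin_edges_mb = c(3, 7, 10, 20))
  expect_equal(which.min(d$p_two_sided), 2L)  # the 7-10 Mb bin
})
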