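make_profile <- function(rows) {
  segment_profile("s", do.call(rbind, lapply(rows, function(r) {
    data.frame(chromosome = r[[1]], start_bp = r[[2]], end_bp = r[[3]],
               major_cn = r[[4]], minor_cn = r[[5]],
               stringsAsFactors = FALSE)
  })))
}

test_that("presets carry the published parameters and cutoffs", {
  ova <- get_preset("ovaHRDscar")
  expect_equal(c(ova$loh_min_mb, ova$loh_max_mb, ova$lst_min_segment_mb,
                 ova$lst_max_gap_mb, ova$tai_min_mb, ova$cutoff),
               c(15, 50, 12, 1, 1, 54))
  expect_equal(get_preset("telli2016")$cutoff, 42L)
  expect_equal(get_preset("takaya2020")$cutoff, 63L)
  tnbc <- get_preset("tnbcHRDscar")
  expect_equal(c(tnbc$loh_min_mb, tnbc$loh_max_mb, tnbc$lst_min_segment_mb,
                 tnbc$lst_max_gap_mb, tnbc$tai_min_mb, tnbc$cutoff),
               c(10, 30, 5, 2, 1, 53))
  expect_error(get_preset("nope"), "valid presets")
  # telli2016 and ovaHRDscar share selection criteria exactly
  te <- get_preset("telli2016")
  expect_equal(unlist(te[2:6]), unlist(ova[2:6]))
})

test_that("count_loh applies strict window and whole-chromosome rules", {
  asm <- test_assembly()
  ova <- get_preset("ovaHRDscar"); tnbc <- get_preset("tnbcHRDscar")
  # 20 Mb interstitial 2/0 on chr1 covered 1..100Mb baseline
  p <- make_profile(list(list("chr1", 1, 30e6, 1, 1),
                         list("chr1", 30e6 + 1, 50e6, 2, 0),
                         list("chr1", 50e6 + 1, 100e6, 1, 1)))
  ai <- extract_ai(p, asm)
  expect_equal(count_loh(ai, ova), 1L)
  # 10 Mb: outside (15,50); also at tnbc's strict l_min=10 boundary
  p10 <- make_profile(list(list("chr1", 1, 30e6, 1, 1),
                           list("chr1", 30e6 + 1, 40e6, 2, 0),
                           list("chr1", 40e6 + 1, 100e6, 1, 1)))
  ai10 <- extract_ai(p10, asm)
  expect_equal(count_loh(ai10, ova), 0L)
  expect_equal(count_loh(ai10, tnbc), 0L)
  p11 <- make_profile(list(list("chr1", 1, 30e6, 1, 1),
                           list("chr1", 30e6 + 1, 41e6, 2, 0),
                           list("chr1", 41e6 + 1, 100e6, 1, 1)))
  expect_equal(count_loh(extract_ai(p11, asm), tnbc), 1L)
  # whole-chromosome LOH is never counted
  w <- make_profile(list(list("chr3", 1e6, 31e6, 2, 0)))
  expect_equal(count_loh(extract_ai(w, asm), ova), 0L)
  # homozygous deletion is not LOH
  hd <- make_profile(list(list("chr1", 1, 30e6, 1, 1),
                          list("chr1", 30e6 + 1, 50e6, 0, 0),
                          list("chr1", 50e6 + 1, 100e6, 1, 1)))
  expect_equal(count_loh(extract_ai(hd, asm), ova), 0L)
  expect_equal(count_loh(extract_ai(make_profile(
    list(list("chr1", 1, 1e6, 1, 1))), asm), ova), 0L)
})

test_that("count_lst evaluates per-arm breakpoints with gap rule", {
  asm <- test_assembly()  # chr1 centromere 80-90 Mb, q arm 90-200
  ova <- get_preset("ovaHRDscar"); tnbc <- get_preset("tnbcHRDscar")
  arm_pair <- function(gap_bp) {
    make_profile(list(
      list("chr1", 90e6 + 1, 103e6, 2, 0),                 # 13 Mb
      list("chr1", 103e6 + gap_bp + 1, 117e6 + gap_bp, 3, 1)))  # 14 Mb
  }
  expect_equal(count_lst(arm_pair(0.5e6), asm, ova), 1L)
  expect_equal(count_lst(arm_pair(1.5e6), asm, ova), 0L)
  expect_equal(count_lst(arm_pair(1.5e6), asm, tnbc), 1L)
  # flank below s
  short <- make_profile(list(
    list("chr1", 90e6 + 1, 101e6, 2, 0),   # 11 Mb < s=12
    list("chr1", 101e6 + 1, 120e6, 3, 1)))
  expect_equal(count_lst(short, asm, ova), 0L)
  # transition across the centromere belongs to neither arm
  across <- make_profile(list(
    list("chr1", 40e6, 82e6, 2, 0),
    list("chr1", 82e6 + 1, 130e6, 3, 1)))
  expect_equal(count_lst(across, asm, ova), 0L)
  # baseline-to-AI transitions count too (any state change)
  base_ai <- make_profile(list(
    list("chr1", 90e6 + 1, 110e6, 1, 1),
    list("chr1", 110e6 + 1, 130e6, 2, 1),
    list("chr1", 130e6 + 1, 200e6, 1, 1)))
  expect_equal(count_lst(base_ai, asm, ova), 2L)
})

test_that("count_tai requires one telomere, no centromere crossing", {
  asm <- test_assembly()
  ova <- get_preset("ovaHRDscar")
  # 5 Mb AI at covered chromosome start
  p <- make_profile(list(list("chr1", 1e6, 6e6 - 1, 2, 1),
                         list("chr1", 6e6, 100e6, 1, 1)))
  expect_equal(count_tai(extract_ai(p, asm), ova), 1L)
  # telomeric AI crossing the centromere (chr1 cen 80-90)
  cr <- make_profile(list(list("chr1", 1e6, 95e6, 2, 1),
                          list("chr1", 95e6 + 1, 200e6, 1, 1)))
  expect_equal(count_tai(extract_ai(cr, asm), ova), 0L)
  # below k
  tiny <- make_profile(list(list("chr1", 1e6, 1.8e6, 2, 1),
                            list("chr1", 1.8e6 + 1, 100e6, 1, 1)))
  expect_equal(count_tai(extract_ai(tiny, asm), ova), 0L)
  # whole-chromosome AI counts for neither TAI nor LOH
  w <- make_profile(list(list("chr3", 1e6, 99e6, 2, 0)))
  expect_equal(count_tai(extract_ai(w, asm), ova), 0L)
})

test_that("quantify_scars sums the three counters; classify is inclusive", {
  asm <- test_assembly()
  ova <- get_preset("ovaHRDscar")
  empty <- make_profile(list(list("chr1", 1, 200e6, 1, 1)))
  expect_equal(quantify_scars(empty, asm, ova)$levels, 0L)
  # one LOH (chr1), one LST pair (chr2 q arm), one TAI (chr3)
  p <- make_profile(list(
    list("chr1", 1, 30e6, 1, 1), list("chr1", 30e6 + 1, 50e6, 2, 0),
    list("chr1", 50e6 + 1, 200e6, 1, 1),
    list("chr2", 1, 67.5e6, 1, 1),
    list("chr2", 67.5e6 + 1, 80.5e6, 2, 0),
    list("chr2", 81e6 + 1, 95e6, 3, 1),
    list("chr2", 95e6 + 1, 150e6, 1, 1),
    list("chr3", 1e6, 6e6 - 1, 2, 1), list("chr3", 6e6, 100e6, 1, 1)))
  counts <- quantify_scars(p, asm, ova)
  expect_equal(counts$n_loh, 1L)
  expect_equal(counts$n_tai, 1L)
  expect_gte(counts$n_lst, 1L)
  expect_equal(counts$levels, counts$n_loh + counts$n_lst + counts$n_tai)

  calls <- classify_hr_status(data.frame(sample_id = c("a", "b", "c"),
                                         levels = c(54L, 53L, 42L)), ova)
  expect_equal(calls$status, c("HRD", "HRP", "HRP"))
  expect_equal(classify_hr_status(
    data.frame(sample_id = "c", levels = 42L),
    get_preset("telli2016"))$status, "HRD")
})

test_that("counters match brute-force oracles on random profiles", {
  set.seed(101)
  asm <- test_assembly()
  crit <- list(get_preset("ovaHRDscar"), get_preset("tnbcHRDscar"))
  for (i in 1:60) {
    p <- random_profile(paste0("r", i))
    sm <- smooth_segments(p)
    ai <- extract_ai(sm, asm)
    for (cr in crit) {
      expect_equal(count_loh(ai, cr), oracle_count_loh(sm, asm, cr),
                   info = paste("loh profile", i))
      expect_equal(count_tai(ai, cr), oracle_count_tai(sm, asm, cr),
                   info = paste("tai profile", i))
      expect_equal(count_lst(sm, asm, cr), oracle_count_lst(sm, asm, cr),
                   info = paste("lst profile", i))
    }
  }
})

test_that("criteria monotonicity holds on random profiles", {
  set.seed(202)
  asm <- test_assembly()
  base <- get_preset("ovaHRDscar")
  for (i in 1:25) {
    p <- smooth_segments(random_profile(paste0("r", i)))
    ai <- extract_ai(p, asm)
    narrower <- criteria_set("n", base$loh_min_mb + 3, base$loh_max_mb - 5,
                             base$lst_min_segment_mb + 4,
                             base$lst_max_gap_mb / 2,
                             base$tai_min_mb + 2, base$cutoff)
    expect_lte(count_loh(ai, narrower), count_loh(ai, base))
    expect_lte(count_lst(p, asm, narrower), count_lst(p, asm, base))
    expect_lte(count_tai(ai, narrower), count_tai(ai, base))
  }
})

test_that("telli2016 and ovaHRDscar give identical levels", {
  set.seed(303)
  asm <- test_assembly()
  for (i in 1:10) {
    p <- random_profile(paste0("r", i))
    a <- quantify_scars(p, asm, get_preset("telli2016"))
    b <- quantify_scars(p, asm, get_preset("ovaHRDscar"))
    expect_equal(a$levels, b$levels)
  }
})
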