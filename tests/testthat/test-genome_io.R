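test_that("assemblies load, validate, and reject bad centromeres", {
  asm <- genome_assembly("hg38")
  expect_s3_class(asm, "genome_assembly")
  expect_false("chrY" %in% asm$chromosomes$chromosome)  # default excludes Y
  expect_true("chrY" %in% genome_assembly("hg38",
                                          include_y = TRUE)$chromosomes$chromosome)
  chr17 <- asm$chromosomes[asm$chromosomes$chromosome == "chr17", ]
  expect_true(chr17$centromere_start_bp < chr17$centromere_end_bp)
  expect_error(custom_assembly("c1", 100, 50, 40), "centromere")
  expect_error(custom_assembly(c("c1", "c1"), c(100, 100), c(40, 40),
                               c(50, 50)), "duplicated")
  expect_error(genome_assembly("hg38", chromosomes = "chrQ"), "chrQ")
})

test_that("read_segments parses all three dialects and round-trips", {
  tmp <- withr::local_tempdir()
  seg <- data.frame(chromosome = c("chr1", "chr1", "chr2"),
                    start_bp = c(1, 5e6, 10),
                    end_bp = c(5e6 - 1, 9e6, 8e6),
                    major_cn = c(1, 2, 3), minor_cn = c(1, 0, 1))
  p <- segment_profile("s1", seg)

  f <- file.path(tmp, "generic.tsv")
  write_segments(p, f)
  back <- read_segments(f, "generic_seg")
  expect_length(back, 1L)
  expect_equal(back$s1$segments, p$segments)

  # same content in the other two dialects
  g <- utils::read.delim(f)
  ascat <- data.frame(sample = g$sample, chr = g$chromosome,
                      startpos = g$start, endpos = g$end,
                      nMajor = g$major_cn, nMinor = g$minor_cn)
  fa <- file.path(tmp, "ascat.tsv")
  utils::write.table(ascat, fa, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_segments(fa, "ascat_output")$s1$segments, p$segments)

  gdc <- data.frame(GDC_Aliquot = g$sample, Chromosome = g$chromosome,
                    Start = g$start, End = g$end,
                    Copy_Number = g$major_cn + g$minor_cn,
                    Major_Copy_Number = g$major_cn,
                    Minor_Copy_Number = g$minor_cn)
  fg <- file.path(tmp, "gdc.tsv")
  utils::write.table(gdc, fg, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_segments(fg, "gdc_allele_specific")$s1$segments,
               p$segments)

  # missing column names the column; unknown dialect errors
  bad <- g[, setdiff(names(g), "minor_cn")]
  fb <- file.path(tmp, "bad.tsv")
  utils::write.table(bad, fb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segments(fb, "generic_seg"), "minor_cn")
})

test_that("profile validation rejects bad segment tables", {
  expect_error(segment_profile("x", data.frame(
    chromosome = "chr1", start_bp = 10, end_bp = 5,
    major_cn = 1, minor_cn = 1)), "start > end")
  expect_error(segment_profile("x", data.frame(
    chromosome = "chr1", start_bp = 1, end_bp = 10,
    major_cn = 1, minor_cn = 2)), "minor_cn > major_cn")
  expect_error(segment_profile("x", data.frame(
    chromosome = c("chr1", "chr1"), start_bp = c(1, 5),
    end_bp = c(10, 20), major_cn = c(1, 1), minor_cn = c(1, 1))),
    "overlapping")
  expect_error(segment_profile("x", data.frame(
    chromosome = "chr1", start_bp = 1, end_bp = 10,
    major_cn = 1.5, minor_cn = 1)), "non-integer")
})

test_that("smoothing drops sub-threshold fragments and merges states", {
  # 10 Mb 2/1 | 40 bp 3/0 | 10 Mb 2/1  ->  one merged 2/1 segment
  p <- segment_profile("s", data.frame(
    chromosome = "chr1",
    start_bp = c(1, 10e6 + 1, 10e6 + 41),
    end_bp = c(10e6, 10e6 + 40, 20e6 + 40),
    major_cn = c(2, 3, 2), minor_cn = c(1, 0, 1)))
  sm <- smooth_segments(p)
  expect_equal(nrow(sm$segments), 1L)
  expect_equal(sm$segments$start_bp, 1)
  expect_equal(sm$segments$end_bp, 20e6 + 40)
  expect_equal(sm$segments$major_cn, 2)

  # exactly 50 bp is retained (strictly-smaller rule)
  p50 <- segment_profile("s", data.frame(
    chromosome = "chr1", start_bp = c(1, 101), end_bp = c(100, 150),
    major_cn = c(1, 2), minor_cn = c(1, 0)))
  expect_equal(nrow(smooth_segments(p50)$segments), 2L)
  p49 <- segment_profile("s", data.frame(
    chromosome = "chr1", start_bp = c(1, 101), end_bp = c(100, 149),
    major_cn = c(1, 2), minor_cn = c(1, 0)))
  expect_equal(nrow(smooth_segments(p49)$segments), 1L)  # 49 bp dropped
  p49b <- segment_profile("s", data.frame(
    chromosome = "chr1", start_bp = c(1, 101, 150),
    end_bp = c(100, 149, 5e6), major_cn = c(1, 2, 1),
    minor_cn = c(1, 0, 1)))
  expect_equal(nrow(smooth_segments(p49b)$segments), 1L)

  expect_error(smooth_segments(p, -1), "min_length_bp")
})

test_that("smoothing is idempotent and never increases segment count", {
  set.seed(11)
  for (i in 1:30) {
    p <- random_profile(paste0("r", i))
    s1 <- smooth_segments(p)
    expect_lte(nrow(s1$segments), nrow(p$segments))
    expect_equal(smooth_segments(s1)$segments, s1$segments)
  }
})

test_that("extract_ai applies the two AI conventions and sets flags", {
  asm <- test_assembly()
  p <- segment_profile("s", data.frame(
    chromosome = "chr1",
    start_bp = c(1e6, 21e6, 41e6, 61e6),
    end_bp = c(21e6 - 1, 41e6 - 1, 61e6 - 1, 150e6),
    major_cn = c(2, 2, 1, 2), minor_cn = c(1, 0, 1, 2)))
  as_mode <- extract_ai(p, asm, "allele_specific")
  # 2/1 and 2/0 are AIs; 1/1 and 2/2 balanced
  expect_equal(nrow(as_mode), 2L)
  expect_equal(as_mode$is_loh, c(FALSE, TRUE))
  tot_mode <- extract_ai(p, asm, "total_cn")
  # 2/1 (total 3) and 2/2 (total 4) are AIs; 2/0 copy-neutral LOH is not
  expect_equal(tot_mode$major_cn + tot_mode$minor_cn, c(3, 4))
  # flags: first segment touches the covered p end; last touches q end and
  # crosses the centromere (80-90 Mb)
  expect_true(as_mode$touches_p_telomere[1])
  expect_false(as_mode$spans_whole_chromosome[1])
  expect_true(tot_mode$touches_q_telomere[2])
  expect_true(tot_mode$crosses_centromere[2])
  # whole-chromosome AI
  w <- segment_profile("w", data.frame(
    chromosome = "chr3", start_bp = 5e5, end_bp = 99e6,
    major_cn = 2, minor_cn = 0))
  expect_true(extract_ai(w, asm)$spans_whole_chromosome)
  expect_error(extract_ai(
    segment_profile("u", data.frame(chromosome = "chrU", start_bp = 1,
                                    end_bp = 10, major_cn = 1,
                                    minor_cn = 0)), asm), "unknown chromosome")
})

test_that("splitting a segment then smoothing reproduces the profile", {
  set.seed(42)
  for (i in 1:40) {
    p <- smooth_segments(random_profile(paste0("r", i)))
    seg <- p$segments
    wide <- which(seg$end_bp - seg$start_bp > 200)
    if (length(wide) == 0L) next
    j <- sample(wide, 1L)
    cut <- seg$start_bp[j] +
      sample.int(seg$end_bp[j] - seg$start_bp[j] - 100, 1L) + 50
    top <- seg[j, ]; bot <- seg[j, ]
    top$end_bp <- cut; bot$start_bp <- cut + 1
    split_seg <- rbind(seg[seq_len(j - 1L), ], top, bot,
                       if (j < nrow(seg)) seg[(j + 1L):nrow(seg), ])
    q <- segment_profile(p$sample_id, split_seg)
    expect_equal(smooth_segments(q)$segments, seg)
  }
})
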