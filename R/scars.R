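#' @title HRD scar counters
#' @description
#' The three scar counters operate on a smoothed profile. LOH and TAI are
#' counted from classified AI segments ([extract_ai]); LSTs are counted as
#' qualifying breakpoints between copy-number states, evaluated per
#' chromosome arm. All length comparisons are strict, the cutoff comparison
#' (`levels >= cutoff` implies HRD) is inclusive.
#' @name scar_counters
NULL

#' Count HRD-LOH events
#'
#' Counts AI segments that are LOH (`minor_cn = 0`, `major_cn >= 1`), have
#' `loh_min_mb < length_mb < loh_max_mb` (strict), and do not span the whole
#' covered extent of their chromosome. Homozygous deletions (0/0) are not
#' LOH: no allele is retained.
#'
#' @param ai_segments AI table from [extract_ai] on a smoothed profile.
#' @param criteria a [criteria_set].
#' @return Integer count.
#' @export
count_loh <- function(ai_segments, criteria) {
  if (nrow(ai_segments) == 0L) return(0L)
  sum(ai_segments$is_loh &
        !ai_segments$spans_whole_chromosome &
        ai_segments$length_mb > criteria$loh_min_mb &
        ai_segments$length_mb < criteria$loh_max_mb)
}

#' Count telomeric allelic imbalances (TAI)
#'
#' Counts AI segments that touch exactly one covered chromosome end, do not
#' cross the centromere, do not span the whole chromosome, and are strictly
#' longer than `tai_min_mb`.
#'
#' @inheritParams count_loh
#' @return Integer count.
#' @export
count_tai <- function(ai_segments, criteria) {
  if (nrow(ai_segments) == 0L) return(0L)
  sum((ai_segments$touches_p_telomere | ai_segments$touches_q_telomere) &
        !ai_segments$spans_whole_chromosome &
        !ai_segments$crosses_centromere &
        ai_segments$length_mb > criteria$tai_min_mb)
}

# All candidate state-transition breakpoints of a profile, per chromosome
# arm. Segments are clipped to the arm intervals [1, cen_start - 1] and
# [cen_end + 1, chrom_length]; a transition whose gap contains the
# centromere therefore belongs to neither arm and is never counted.
# Returns one row per breakpoint: min_flank_mb (shorter clipped flank) and
# gap_mb (uncovered distance between the flanks).
lst_breakpoints <- function(profile, assembly) {
  seg <- profile$segments
  out <- list()
  for (chrom in unique(seg$chromosome)) {
    row <- assembly_row(assembly, chrom)
    s <- seg[seg$chromosome == chrom, , drop = FALSE]
    arms <- list(c(1, row$centromere_start_bp - 1),
                 c(row$centromere_end_bp + 1, row$length_bp))
    for (arm in arms) {
      lo <- pmax(s$start_bp, arm[1])
      hi <- pmin(s$end_bp, arm[2])
      keep <- lo <= hi
      if (sum(keep) < 2L) next
      a <- data.frame(start = lo[keep], end = hi[keep],
                      major = s$major_cn[keep], minor = s$minor_cn[keep])
      n <- nrow(a)
      differs <- a$major[-1L] != a$major[-n] | a$minor[-1L] != a$minor[-n]
      if (!any(differs)) next
      flank_prev <- (a$end[-n] - a$start[-n] + 1) / 1e6
      flank_next <- (a$end[-1L] - a$start[-1L] + 1) / 1e6
      gap <- (a$start[-1L] - a$end[-n] - 1) / 1e6
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        min_flank_mb = pmin(flank_prev, flank_next)[differs],
        gap_mb = gap[differs], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(), min_flank_mb = numeric(),
                      gap_mb = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count large-scale state transitions (LST)
#'
#' Counts breakpoints between consecutive copy-number states, evaluated per
#' chromosome arm (segments are clipped to the arm; the centromere interval
#' belongs to neither arm, so breakpoints falling inside it are never
#' counted). A breakpoint qualifies when both flanking segments are strictly
#' longer than `lst_min_segment_mb` within the arm and the uncovered gap
#' between them is strictly smaller than `lst_max_gap_mb`. Any state change
#' qualifies, not only AI-to-AI transitions.
#'
#' @param profile a smoothed [segment_profile].
#' @param assembly a [genome_assembly].
#' @param criteria a [criteria_set].
#' @return Integer count.
#' @export
count_lst <- function(profile, assembly, criteria) {
  bp <- lst_breakpoints(profile, assembly)
  if (nrow(bp) == 0L) return(0L)
  sum(bp$min_flank_mb > criteria$lst_min_segment_mb &
        bp$gap_mb < criteria$lst_max_gap_mb)
}

#' Quantify HRD scars for one sample
#'
#' Applies [smooth_segments], classifies AIs with [extract_ai] in
#' allele-specific mode, and runs the three scar counters. The scar level is
#' the sum `n_loh + n_lst + n_tai`.
#'
#' @param profile a [segment_profile].
#' @param assembly a [genome_assembly].
#' @param criteria a [criteria_set], e.g. from [get_preset()].
#' @param smooth_bp smoothing threshold in bp passed to [smooth_segments].
#' @param mode AI convention for LOH/TAI, see [extract_ai].
#' @return A one-row data frame (class `ai_counts`) with `sample_id`,
#'   `n_loh`, `n_lst`, `n_tai`, `levels`.
#' @examples
#' asm <- custom_assembly("chr1", 100e6, 45e6, 50e6)
#' p <- segment_profile("s1", data.frame(
#'   chromosome = "chr1", start_bp = 1, end_bp = 100e6,
#'   major_cn = 1, minor_cn = 1))
#' quantify_scars(p, asm, get_preset("ovaHRDscar"))
#' @export
quantify_scars <- function(profile, assembly, criteria, smooth_bp = 50,
                           mode = "allele_specific") {
  sm <- smooth_segments(profile, smooth_bp)
  ai <- extract_ai(sm, assembly, mode = mode)
  n_loh <- count_loh(ai, criteria)
  n_lst <- count_lst(sm, assembly, criteria)
  n_tai <- count_tai(ai, criteria)
  out <- data.frame(sample_id = profile$sample_id,
                    n_loh = as.integer(n_loh), n_lst = as.integer(n_lst),
                    n_tai = as.integer(n_tai),
                    levels = as.integer(n_loh + n_lst + n_tai),
                    stringsAsFactors = FALSE)
  class(out) <- c("ai_counts", "data.frame")
  out
}

#' Quantify HRD scars for a cohort
#'
#' @param profiles list of [segment_profile] objects.
#' @inheritParams quantify_scars
#' @return Data frame with one row per sample (columns as in
#'   [quantify_scars]).
#' @export
quantify_cohort <- function(profiles, assembly, criteria, smooth_bp = 50,
                            mode = "allele_specific") {
  if (length(profiles) == 0L) {
    return(data.frame(sample_id = character(), n_loh = integer(),
                      n_lst = integer(), n_tai = integer(),
                      levels = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(profiles, quantify_scars, assembly = assembly,
                               criteria = criteria, smooth_bp = smooth_bp,
                               mode = mode))
  rownames(out) <- NULL
  out
}

#' Classify HR status from scar levels
#'
#' A sample is HR-deficient (HRD) iff its scar level is greater than or
#' equal to the criteria cutoff, otherwise HR-proficient (HRP).
#'
#' @param counts output of [quantify_scars] / [quantify_cohort] (or any
#'   data frame with `sample_id` and `levels`).
#' @param criteria a [criteria_set] supplying the cutoff.
#' @return Data frame with `sample_id`, `levels`, `cutoff`, `status`.
#' @export
classify_hr_status <- function(counts, criteria) {
  data.frame(sample_id = counts$sample_id,
             levels = counts$levels,
             cutoff = rep(as.integer(criteria$cutoff),
                          length(counts$levels)),
             status = ifelse(counts$levels >= criteria$cutoff, "HRD", "HRP"),
             stringsAsFactors = FALSE)
}
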