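#' Extract allelic-imbalance (AI) segments from a profile
#'
#' Classifies each segment of a profile as an allelic imbalance under one of
#' two conventions and annotates positional flags needed by the scar
#' counters:
#' \describe{
#'   \item{allele_specific}{AI iff `major_cn != minor_cn` (includes
#'     copy-neutral LOH such as 2/0).}
#'   \item{total_cn}{AI iff `major_cn + minor_cn != 2` (the convention used
#'     for pan-cancer AI landscapes; copy-neutral LOH is not an AI here).}
#' }
#'
#' Telomere contact is defined against the profile's covered extent per
#' chromosome — the first and last base covered by any segment of that
#' chromosome in the profile — rather than the physical chromosome ends,
#' because array- and WGS-derived segmentations never reach the telomeric
#' repeats. A segment touching both covered ends spans the whole chromosome.
#' A segment crosses the centromere iff it starts before the centromere
#' interval and ends after it.
#'
#' @param profile a [segment_profile].
#' @param assembly a [genome_assembly] providing centromere intervals.
#' @param mode `"allele_specific"` (default) or `"total_cn"`.
#' @return Data frame of AI segments with columns `chromosome`, `start_bp`,
#'   `end_bp`, `length_mb`, `major_cn`, `minor_cn`, `is_loh`,
#'   `touches_p_telomere`, `touches_q_telomere`, `crosses_centromere`,
#'   `spans_whole_chromosome`.
#' @export
extract_ai <- function(profile, assembly,
                       mode = c("allele_specific", "total_cn")) {
  mode <- match.arg(mode)
  seg <- profile$segments
  empty <- data.frame(chromosome = character(), start_bp = numeric(),
                      end_bp = numeric(), length_mb = numeric(),
                      major_cn = numeric(), minor_cn = numeric(),
                      is_loh = logical(), touches_p_telomere = logical(),
                      touches_q_telomere = logical(),
                      crosses_centromere = logical(),
                      spans_whole_chromosome = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(seg) == 0L) return(empty)
  for (chrom in unique(seg$chromosome)) assembly_row(assembly, chrom)

  # covered extent per chromosome over the FULL profile
  cov_lo <- tapply(seg$start_bp, seg$chromosome, min)
  cov_hi <- tapply(seg$end_bp, seg$chromosome, max)

  is_ai <- if (mode == "allele_specific") {
    seg$major_cn != seg$minor_cn
  } else {
    seg$major_cn + seg$minor_cn != 2
  }
  ai <- seg[is_ai, , drop = FALSE]
  if (nrow(ai) == 0L) return(empty)

  cen <- assembly$chromosomes[match(ai$chromosome,
                                    assembly$chromosomes$chromosome), ]
  touches_p <- ai$start_bp == unname(cov_lo[ai$chromosome])
  touches_q <- ai$end_bp == unname(cov_hi[ai$chromosome])
  out <- data.frame(
    chromosome = ai$chromosome,
    start_bp = ai$start_bp,
    end_bp = ai$end_bp,
    length_mb = (ai$end_bp - ai$start_bp + 1) / 1e6,
    major_cn = ai$major_cn,
    minor_cn = ai$minor_cn,
    is_loh = ai$minor_cn == 0 & ai$major_cn >= 1,
    touches_p_telomere = touches_p,
    touches_q_telomere = touches_q,
    crosses_centromere = ai$start_bp < cen$centromere_start_bp &
      ai$end_bp > cen$centromere_end_bp,
    spans_whole_chromosome = touches_p & touches_q,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
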