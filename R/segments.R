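#' Allele-specific copy-number segment profile
#'
#' A `segment_profile` is one sample's ordered allele-specific copy-number
#' segments. Coordinates are 1-based inclusive, the seg-file convention, so
#' a segment's length in megabases is `(end - start + 1)/1e6`. The major
#' copy number is always the larger of the two parental copy numbers.
#'
#' @param sample_id sample identifier.
#' @param segments data frame with columns `chromosome`, `start_bp`,
#'   `end_bp`, `major_cn`, `minor_cn`.
#' @param build_label genome build label (informational).
#' @param purity optional tumor purity in (0, 1].
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments, build_label = "custom",
                            purity = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  required <- c("chromosome", "start_bp", "end_bp", "major_cn", "minor_cn")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0L) {
    stop("segment table missing column(s): ", paste(missing, collapse = ", "))
  }
  segments <- segments[, required]
  segments$chromosome <- as.character(segments$chromosome)
  for (col in c("start_bp", "end_bp", "major_cn", "minor_cn")) {
    v <- segments[[col]]
    if (col %in% c("major_cn", "minor_cn") && any(v != round(v))) {
      stop("non-integer copy numbers in sample ", sample_id)
    }
    segments[[col]] <- as.numeric(v)
  }
  # sort by chromosome (input order of appearance) then start
  chrom_order <- unique(segments$chromosome)
  o <- order(match(segments$chromosome, chrom_order), segments$start_bp)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  validate_segments(sample_id, segments)
  structure(list(sample_id = as.character(sample_id),
                 build_label = build_label,
                 segments = segments,
                 purity = purity),
            class = "segment_profile")
}

validate_segments <- function(sample_id, seg) {
  if (nrow(seg) == 0L) return(invisible(seg))
  if (any(seg$start_bp > seg$end_bp)) {
    i <- which(seg$start_bp > seg$end_bp)[1L]
    stop(sprintf("sample %s: segment with start > end at %s:%d",
                 sample_id, seg$chromosome[i], as.integer(seg$start_bp[i])))
  }
  if (any(seg$minor_cn > seg$major_cn)) {
    i <- which(seg$minor_cn > seg$major_cn)[1L]
    stop(sprintf("sample %s: minor_cn > major_cn at %s:%d",
                 sample_id, seg$chromosome[i], as.integer(seg$start_bp[i])))
  }
  if (any(seg$minor_cn < 0)) stop("sample ", sample_id, ": negative copy number")
  for (chrom in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == chrom, ]
    if (nrow(s) > 1L && any(s$start_bp[-1L] <= s$end_bp[-nrow(s)])) {
      stop(sprintf("sample %s: overlapping segments on %s", sample_id, chrom))
    }
  }
  invisible(seg)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %s: %d segments on %d chromosome(s)\n",
              x$sample_id, nrow(x$segments),
              length(unique(x$segments$chromosome))))
  invisible(x)
}

#' Segment lengths in megabases
#' @param profile a `segment_profile`.
#' @return numeric vector of lengths, `(end - start + 1)/1e6`.
#' @export
segment_lengths_mb <- function(profile) {
  with(profile$segments, (end_bp - start_bp + 1) / 1e6)
}

# column maps for the supported segment-table dialects
.seg_dialects <- list(
  generic_seg = c(sample = "sample", chromosome = "chromosome",
                  start_bp = "start", end_bp = "end",
                  major_cn = "major_cn", minor_cn = "minor_cn"),
  gdc_allele_specific = c(sample = "GDC_Aliquot", chromosome = "Chromosome",
                          start_bp = "Start", end_bp = "End",
                          major_cn = "Major_Copy_Number",
                          minor_cn = "Minor_Copy_Number"),
  ascat_output = c(sample = "sample", chromosome = "chr",
                   start_bp = "startpos", end_bp = "endpos",
                   major_cn = "nMajor", minor_cn = "nMinor")
)

#' Read allele-specific copy-number segment tables
#'
#' Reads a tab-delimited segment table in one of three dialects and returns
#' one validated [segment_profile] per sample found. Rows on chromosomes not
#' present in `assembly` (when given) are dropped with a message.
#'
#' Supported dialects:
#' \describe{
#'   \item{generic_seg}{`sample, chromosome, start, end, major_cn, minor_cn`}
#'   \item{gdc_allele_specific}{`GDC_Aliquot, Chromosome, Start, End,
#'     Copy_Number, Major_Copy_Number, Minor_Copy_Number`}
#'   \item{ascat_output}{`sample, chr, startpos, endpos, nMajor, nMinor`}
#' }
#'
#' @param path path to a tab-delimited file with header.
#' @param dialect one of `"generic_seg"`, `"gdc_allele_specific"`,
#'   `"ascat_output"`.
#' @param assembly optional [genome_assembly] used to filter rows to known
#'   chromosomes.
#' @param build_label build label recorded on each profile.
#' @return Named list of [segment_profile] objects, one per sample, in order
#'   of first appearance.
#' @export
read_segments <- function(path,
                          dialect = c("generic_seg", "gdc_allele_specific",
                                      "ascat_output"),
                          assembly = NULL, build_label = "custom") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cmap <- .seg_dialects[[dialect]]
  missing <- setdiff(unname(cmap), names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("dialect '%s': missing required column(s): %s",
                 dialect, paste(missing, collapse = ", ")))
  }
  df <- data.frame(sample = as.character(tab[[cmap[["sample"]]]]),
                   chromosome = as.character(tab[[cmap[["chromosome"]]]]),
                   start_bp = tab[[cmap[["start_bp"]]]],
                   end_bp = tab[[cmap[["end_bp"]]]],
                   major_cn = tab[[cmap[["major_cn"]]]],
                   minor_cn = tab[[cmap[["minor_cn"]]]],
                   stringsAsFactors = FALSE)
  if (!is.null(assembly)) {
    known <- df$chromosome %in% assembly$chromosomes$chromosome
    if (any(!known)) {
      message(sprintf("read_segments: dropped %d row(s) on unknown chromosome(s): %s",
                      sum(!known),
                      paste(unique(df$chromosome[!known]), collapse = ", ")))
      df <- df[known, , drop = FALSE]
    }
  }
  samples <- unique(df$sample)
  profiles <- lapply(samples, function(s) {
    segment_profile(s, df[df$sample == s,
                          c("chromosome", "start_bp", "end_bp",
                            "major_cn", "minor_cn")],
                    build_label = build_label)
  })
  names(profiles) <- samples
  profiles
}

#' Write profiles as a generic_seg table
#'
#' Emits the `generic_seg` dialect (`sample, chromosome, start, end,
#' major_cn, minor_cn`, tab-delimited); a write/read round trip is
#' field-identical.
#'
#' @param profiles a [segment_profile] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    data.frame(sample = p$sample_id,
               chromosome = p$segments$chromosome,
               start = format(p$segments$start_bp, scientific = FALSE,
                              trim = TRUE),
               end = format(p$segments$end_bp, scientific = FALSE,
                            trim = TRUE),
               major_cn = as.integer(p$segments$major_cn),
               minor_cn = as.integer(p$segments$minor_cn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(), chromosome = character(),
                      start = character(), end = character(),
                      major_cn = integer(), minor_cn = integer())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Smooth short allelic-imbalance fragments
#'
#' Removes segments strictly shorter than `min_length_bp` (default 50 bp,
#' the convention for allele-specific profiles derived from SNP data) and
#' then merges adjacent same-chromosome segments with identical
#' `(major_cn, minor_cn)` into one segment spanning their joint extent.
#' The operation is idempotent.
#'
#' @param profile a [segment_profile].
#' @param min_length_bp drop segments with `end - start + 1 < min_length_bp`.
#' @return A smoothed [segment_profile].
#' @export
smooth_segments <- function(profile, min_length_bp = 50) {
  if (min_length_bp < 0) stop("min_length_bp must be >= 0")
  seg <- profile$segments
  keep <- (seg$end_bp - seg$start_bp + 1) >= min_length_bp
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) > 1L) {
    same <- seg$chromosome[-1L] == seg$chromosome[-nrow(seg)] &
      seg$major_cn[-1L] == seg$major_cn[-nrow(seg)] &
      seg$minor_cn[-1L] == seg$minor_cn[-nrow(seg)]
    # run ids: a new run starts wherever the state or chromosome changes
    run <- cumsum(c(TRUE, !same))
    seg <- data.frame(
      chromosome = tapply(seg$chromosome, run, `[`, 1L),
      start_bp = as.numeric(tapply(seg$start_bp, run, min)),
      end_bp = as.numeric(tapply(seg$end_bp, run, max)),
      major_cn = as.numeric(tapply(seg$major_cn, run, `[`, 1L)),
      minor_cn = as.numeric(tapply(seg$minor_cn, run, `[`, 1L)),
      stringsAsFactors = FALSE)
    rownames(seg) <- NULL
  }
  out <- profile
  out$segments <- seg
  out
}
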