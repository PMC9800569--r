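#' Call promoter hypermethylation from probe beta values
#'
#' A gene promoter is called hypermethylated when the average beta value of
#' the probes within the TSS window reaches `threshold`. The window is
#' `[0, window_bp]` downstream of the TSS by default; promoter arrays
#' conventionally flank the TSS, so `signed_window = TRUE` widens it to
#' `[-window_bp, window_bp]`.
#'
#' @param rel_pos probe positions relative to the TSS (bp, signed).
#' @param beta probe beta values in [0, 1].
#' @param window_bp window half-width in bp (default 1500).
#' @param threshold mean-beta threshold (default 0.75, inclusive).
#' @param signed_window include probes upstream of the TSS.
#' @return Logical: hypermethylated or not.
#' @export
call_promoter_hypermethylation <- function(rel_pos, beta, window_bp = 1500,
                                           threshold = 0.75,
                                           signed_window = FALSE) {
  stopifnot(length(rel_pos) == length(beta))
  if (any(beta < 0 | beta > 1)) stop("beta values must be in [0, 1]")
  in_win <- if (signed_window) abs(rel_pos) <= window_bp
            else rel_pos >= 0 & rel_pos <= window_bp
  if (!any(in_win)) {
    stop("insufficient data: no probe within the TSS window")
  }
  mean(beta[in_win]) >= threshold
}

#' Default RAD51-paralog gene set
#' @return Character vector of gene symbols.
#' @export
rad51_paralogs <- function() {
  c("RAD51", "RAD51B", "RAD51C", "RAD51D", "XRCC2", "XRCC3")
}

#' Multi-omics ground-truth HR annotation of a cohort
#'
#' Labels each sample:
#' \describe{
#'   \item{HRD}{has a pathogenic somatic/germline mutation, a strong
#'     deletion signal, or promoter hypermethylation in one of the trigger
#'     genes (BRCA1/2 and the RAD51 paralogs by default).}
#'   \item{HRP}{not HRD, all three omics layers available (methylation,
#'     gene deletion, somatic mutation), and no strong deletion in any HR
#'     pathway gene.}
#'   \item{undefined}{everything else, plus any `manual_exclusions`.}
#' }
#' The three labels partition the sample set.
#'
#' @param alterations data frame `sample_id`, `gene`, `category` (one of
#'   `somatic_mutation`, `germline_mutation`, `strong_deletion`,
#'   `promoter_hypermethylation`, `amplification`), `pathogenic` (logical;
#'   only pathogenic mutations count as triggers).
#' @param availability data frame `sample_id`, `has_methylation`,
#'   `has_gene_deletion`, `has_somatic_mutation`; defines the cohort.
#' @param hrd_trigger_genes character vector of trigger genes.
#' @param hr_pathway_genes character vector of HR pathway genes checked for
#'   deletions in HRP candidates.
#' @param manual_exclusions sample ids forced to `undefined` (e.g. burden
#'   outliers).
#' @return Data frame `sample_id`, `label`, `evidence` (semicolon-joined
#'   `gene:category` strings for HRD samples).
#' @export
annotate_cohort <- function(alterations, availability,
                            hrd_trigger_genes = c("BRCA1", "BRCA2",
                                                  rad51_paralogs()),
                            hr_pathway_genes,
                            manual_exclusions = character()) {
  stopifnot(length(hrd_trigger_genes) > 0L, length(hr_pathway_genes) > 0L)
  valid_cat <- c("somatic_mutation", "germline_mutation", "strong_deletion",
                 "promoter_hypermethylation", "amplification")
  if (nrow(alterations) > 0L && !all(alterations$category %in% valid_cat)) {
    stop("unknown alteration category: ",
         paste(setdiff(alterations$category, valid_cat), collapse = ", "))
  }
  unknown <- setdiff(alterations$sample_id, availability$sample_id)
  if (length(unknown) > 0L) {
    stop("sample(s) in alterations but not in availability: ",
         paste(unknown, collapse = ", "))
  }
  mut_cat <- c("somatic_mutation", "germline_mutation")
  is_trigger <- alterations$gene %in% hrd_trigger_genes &
    ((alterations$category %in% mut_cat & alterations$pathogenic) |
       alterations$category %in% c("strong_deletion",
                                   "promoter_hypermethylation"))
  rows <- lapply(seq_len(nrow(availability)), function(i) {
    sid <- availability$sample_id[i]
    alt <- alterations[alterations$sample_id == sid, , drop = FALSE]
    trig <- alt[is_trigger[alterations$sample_id == sid], , drop = FALSE]
    if (sid %in% manual_exclusions) {
      label <- "undefined"; evidence <- ""
    } else if (nrow(trig) > 0L) {
      label <- "HRD"
      evidence <- paste(paste0(trig$gene, ":", trig$category),
                       collapse = ";")
    } else {
      omics_ok <- availability$has_methylation[i] &&
        availability$has_gene_deletion[i] &&
        availability$has_somatic_mutation[i]
      hr_del <- any(alt$category == "strong_deletion" &
                      alt$gene %in% hr_pathway_genes)
      label <- if (omics_ok && !hr_del) "HRP" else "undefined"
      evidence <- ""
    }
    data.frame(sample_id = sid, label = label, evidence = evidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
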