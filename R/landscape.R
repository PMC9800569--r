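#' Per-sample AI burden in a length window
#'
#' Counts, per sample, the allelic imbalances with length strictly inside
#' `(min_mb, max_mb)` that do not span a whole chromosome, and the median
#' length of the retained AIs (NA when none). Optionally restricted to LOH.
#'
#' @param profiles named list of [segment_profile]s.
#' @param assembly a [genome_assembly].
#' @param min_mb,max_mb window bounds in Mb (strict); defaults 3 and 50.
#' @param mode AI convention, see [extract_ai]; the pan-cancer landscape
#'   convention is `"total_cn"`.
#' @param loh_only restrict to LOH segments.
#' @param cohort_label optional label recorded per sample.
#' @param smooth_bp smoothing threshold.
#' @return Data frame `sample_id`, `cohort_label`, `n_ai_in_window`,
#'   `median_ai_length_mb`.
#' @export
ai_burden_summary <- function(profiles, assembly, min_mb = 3, max_mb = 50,
                              mode = "total_cn", loh_only = FALSE,
                              cohort_label = NA_character_, smooth_bp = 50) {
  if (min_mb >= max_mb) stop("min_mb must be < max_mb")
  rows <- lapply(profiles, function(p) {
    ai <- extract_ai(smooth_segments(p, smooth_bp), assembly, mode = mode)
    keep <- !ai$spans_whole_chromosome &
      ai$length_mb > min_mb & ai$length_mb < max_mb
    if (loh_only) keep <- keep & ai$is_loh
    lens <- ai$length_mb[keep]
    data.frame(sample_id = p$sample_id, cohort_label = cohort_label,
               n_ai_in_window = length(lens),
               median_ai_length_mb = if (length(lens)) stats::median(lens)
                                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher-Pearson sample skewness (g1)
#'
#' `g1 = m3 / m2^(3/2)` with central moments using the n denominator.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Skewness value.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need >= 2 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant input: skewness undefined")
  mean((x - m)^3) / m2^1.5
}

#' Per-cohort AI feature vectors
#'
#' Summarizes each cohort by the median per-sample AI count, the median AI
#' length, and the Fisher-Pearson skewness of the pooled AI lengths
#' (`per_sample = TRUE` instead averages per-sample skewness values).
#'
#' @param burden output of [ai_burden_summary] with `cohort_label` set.
#' @param lengths named list (by cohort label) of pooled AI length vectors.
#' @param per_sample not implemented for burden input; reserved flag.
#' @return Data frame `cohort_label`, `median_ai_count`,
#'   `median_ai_length_mb`, `length_skewness`.
#' @export
cancer_type_features <- function(burden, lengths, per_sample = FALSE) {
  labs <- unique(burden$cohort_label)
  rows <- lapply(labs, function(lb) {
    b <- burden[burden$cohort_label == lb, ]
    pooled <- lengths[[lb]]
    if (length(pooled) < 2L) {
      stop("cohort ", lb, " has < 2 AI lengths; features undefined")
    }
    data.frame(cohort_label = lb,
               median_ai_count = stats::median(b$n_ai_in_window),
               median_ai_length_mb = stats::median(pooled),
               length_skewness = sample_skewness(pooled),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of cancer types on AI features
#'
#' Z-scores the three feature columns, computes Euclidean distances and
#' applies complete-linkage agglomerative clustering. Deterministic given
#' input order (ties resolved by `stats::hclust`'s order of merging).
#'
#' @param features data frame as from [cancer_type_features].
#' @return An `hclust` object with cohort labels.
#' @export
cluster_cancer_types <- function(features) {
  cols <- c("median_ai_count", "median_ai_length_mb", "length_skewness")
  if (nrow(features) < 2L) stop("need >= 2 cohorts")
  m <- as.matrix(features[, cols])
  if (any(!is.finite(m))) stop("non-finite feature value")
  m <- scale(m)
  m[is.nan(m)] <- 0  # constant column across cohorts carries no signal
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  hc$labels <- features$cohort_label
  hc
}

#' Per-length-bin differential AI abundance between two cohorts
#'
#' For each bin `[low, high)` of AI length, compares the per-sample AI
#' counts of cohort A vs cohort B with a two-sided rank-sum test and
#' reports the fold change `(mean count A / mean count B) - 1`
#' (NA when cohort B has zero abundance in the bin).
#'
#' @param profiles_a,profiles_b named lists of [segment_profile]s.
#' @param assembly a [genome_assembly].
#' @param bin_edges_mb increasing numeric vector of bin edges; default
#'   1-Mb bins from 3 to 50 Mb.
#' @param mode AI convention, see [extract_ai].
#' @param adjust apply Benjamini-Hochberg correction across bins.
#' @param smooth_bp smoothing threshold.
#' @return Data frame `bin_low_mb`, `bin_high_mb`, `p_two_sided`,
#'   `fold_change` (and `p_adj` when `adjust`).
#' @export
differential_ai_by_length <- function(profiles_a, profiles_b, assembly,
                                      bin_edges_mb = 3:50,
                                      mode = "total_cn", adjust = FALSE,
                                      smooth_bp = 50) {
  if (length(profiles_a) < 1L || length(profiles_b) < 1L) {
    stop("each cohort needs >= 1 sample")
  }
  if (any(diff(bin_edges_mb) <= 0)) stop("bin edges must be increasing")
  lens_per_sample <- function(profiles) {
    lapply(profiles, function(p) {
      ai <- extract_ai(smooth_segments(p, smooth_bp), assembly, mode = mode)
      ai$length_mb[!ai$spans_whole_chromosome]
    })
  }
  la <- lens_per_sample(profiles_a)
  lb <- lens_per_sample(profiles_b)
  nb <- length(bin_edges_mb) - 1L
  out <- data.frame(bin_low_mb = bin_edges_mb[-(nb + 1L)],
                    bin_high_mb = bin_edges_mb[-1L],
                    p_two_sided = NA_real_, fold_change = NA_real_)
  for (i in seq_len(nb)) {
    lo <- out$bin_low_mb[i]; hi <- out$bin_high_mb[i]
    ca <- vapply(la, function(l) sum(l >= lo & l < hi), numeric(1))
    cb <- vapply(lb, function(l) sum(l >= lo & l < hi), numeric(1))
    if (length(unique(c(ca, cb))) > 1L) {
      out$p_two_sided[i] <- suppressWarnings(
        stats::wilcox.test(ca, cb, alternative = "two.sided")$p.value)
    } else {
      out$p_two_sided[i] <- 1
    }
    out$fold_change[i] <- if (mean(cb) > 0) mean(ca) / mean(cb) - 1
                          else NA_real_
  }
  if (adjust) out$p_adj <- stats::p.adjust(out$p_two_sided, "BH")
  out
}
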