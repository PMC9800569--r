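#' Decision-stump balanced accuracy
#'
#' Finds the single threshold on a numeric score that best separates HRD
#' from HRP samples under the rule `score >= split` implies HRD, maximizing
#' balanced accuracy BA = (TPR + TNR)/2. All distinct partitions are
#' examined: splits at the minimum (everything HRD), midpoints between
#' consecutive distinct values, and above the maximum (nothing HRD). Ties
#' are broken toward the lowest qualifying split, making the result fully
#' deterministic. The optimal BA is always at least 0.5 because the two
#' degenerate partitions achieve exactly 0.5.
#'
#' @param counts numeric vector of per-sample scores.
#' @param labels character/factor vector of `"HRD"` / `"HRP"`, same length.
#' @return List with `split_point`, `tpr`, `tnr`, `ba`.
#' @export
stump_balanced_accuracy <- function(counts, labels) {
  labels <- as.character(labels)
  stopifnot(length(counts) == length(labels))
  if (!all(c("HRD", "HRP") %in% labels)) {
    stop("both classes (HRD and HRP) must be present")
  }
  v <- sort(unique(counts))
  splits <- c(v[1L],
              if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
              v[length(v)] + 1)
  is_hrd <- labels == "HRD"
  n_pos <- sum(is_hrd); n_neg <- sum(!is_hrd)
  best <- NULL
  for (s in splits) {
    call_hrd <- counts >= s
    tpr <- sum(call_hrd & is_hrd) / n_pos
    tnr <- sum(!call_hrd & !is_hrd) / n_neg
    ba <- (tpr + tnr) / 2
    if (is.null(best) || ba > best$ba + 1e-12) {
      best <- list(split_point = s, tpr = tpr, tnr = tnr, ba = ba)
    }
  }
  best
}

# One-tailed rank-sum p-value that HRD counts are stochastically greater.
# Exact enumeration over all assignments of the pooled values to the HRD
# group when both groups have <= 8 samples (correct under ties); normal
# approximation with tie and continuity correction otherwise.
rank_sum_p_greater <- function(x_hrd, y_hrp) {
  n1 <- length(x_hrd); n2 <- length(y_hrp)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  pooled <- c(x_hrd, y_hrp)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8L && n2 <= 8L) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    return(mean(u_all >= u_obs - 1e-9))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)   # continuity correction
  min(1, stats::pnorm(z, lower.tail = FALSE))
}

#' Score one criteria configuration
#'
#' Combines the one-tailed Mann-Whitney U test (alternative: HRD counts
#' greater) with the decision-stump balanced accuracy into the selection
#' score `-log10(p) * BA`.
#'
#' @param counts_hrd,counts_hrp numeric vectors of per-sample scar counts
#'   in the annotated HRD and HRP classes (each of length >= 2).
#' @return List with `p_one_tailed`, `ba`, `stump` and `score`.
#' @export
score_criteria <- function(counts_hrd, counts_hrp) {
  p <- rank_sum_p_greater(counts_hrd, counts_hrp)
  stump <- stump_balanced_accuracy(
    c(counts_hrd, counts_hrp),
    rep(c("HRD", "HRP"), c(length(counts_hrd), length(counts_hrp))))
  list(p_one_tailed = p, ba = stump$ba, stump = stump,
       score = -log10(p) * stump$ba)
}

# Per-sample feature primitives reused across grid points: AI lengths
# relevant to each scar type, extracted once per sample.
feature_primitives <- function(profiles, assembly, feature, smooth_bp = 50) {
  lapply(profiles, function(p) {
    sm <- smooth_segments(p, smooth_bp)
    if (feature == "lst") {
      bp <- lst_breakpoints(sm, assembly)
      list(min_flank_mb = bp$min_flank_mb, gap_mb = bp$gap_mb)
    } else {
      ai <- extract_ai(sm, assembly, mode = "allele_specific")
      if (feature == "loh") {
        list(lengths = ai$length_mb[ai$is_loh & !ai$spans_whole_chromosome])
      } else {
        eligible <- (ai$touches_p_telomere | ai$touches_q_telomere) &
          !ai$spans_whole_chromosome & !ai$crosses_centromere
        list(lengths = ai$length_mb[eligible])
      }
    }
  })
}

#' Exhaustive grid search over scar selection criteria
#'
#' For every grid point, counts the chosen scar feature per sample under
#' those criteria and scores the separation of annotated HRD vs HRP samples
#' with [score_criteria]. Features are extracted once per sample, so the
#' grid scan itself is cheap. Degenerate LOH points (`l_min >= l_max`) are
#' skipped with a warning. Results are ranked by score (descending), with
#' ties broken toward smaller parameter values (`l_min`/`s`/`k` first,
#' then `l_max`/`m`).
#'
#' @param profiles list of [segment_profile]s.
#' @param assembly a [genome_assembly].
#' @param labels data frame `sample_id`, `label` ("HRD"/"HRP").
#' @param feature `"loh"`, `"lst"`, or `"tai"`.
#' @param grid for `"loh"`: list with numeric `l_min`, `l_max` (Mb); for
#'   `"lst"`: list with `s`, `m`; for `"tai"`: list with `k`. Defaults span
#'   1-20 Mb for minimum lengths, 20-60 Mb plus `Inf` for `l_max`, and
#'   0.5/1/2/3 Mb for `m`.
#' @param smooth_bp smoothing threshold, see [smooth_segments].
#' @return List with `results` (data frame, one row per grid point, ranked)
#'   and `best` (top row).
#' @export
grid_search_criteria <- function(profiles, assembly, labels,
                                 feature = c("loh", "lst", "tai"),
                                 grid = NULL, smooth_bp = 50) {
  feature <- match.arg(feature)
  if (is.null(grid)) {
    grid <- switch(feature,
                   loh = list(l_min = 1:20, l_max = c(20:60, Inf)),
                   lst = list(s = 1:20, m = c(0.5, 1, 2, 3)),
                   tai = list(k = c(0.5, 1:20)))
  }
  lab <- labels$label[match(names(profiles), labels$sample_id)]
  if (any(is.na(lab))) stop("unlabeled profile(s): ",
                            paste(names(profiles)[is.na(lab)], collapse = ", "))
  if (!all(c("HRD", "HRP") %in% lab)) stop("both classes must be present")
  prim <- feature_primitives(profiles, assembly, feature, smooth_bp)
  pts <- switch(feature,
                loh = expand.grid(l_min = grid$l_min, l_max = grid$l_max),
                lst = expand.grid(s = grid$s, m = grid$m),
                tai = expand.grid(k = grid$k))
  if (feature == "loh") {
    degen <- pts$l_min >= pts$l_max
    if (any(degen)) {
      warning(sum(degen), " degenerate grid point(s) with l_min >= l_max skipped")
      pts <- pts[!degen, , drop = FALSE]
    }
  }
  if (nrow(pts) == 0L) stop("empty grid")
  res <- pts
  res$p_one_tailed <- NA_real_; res$ba <- NA_real_; res$score <- NA_real_
  is_hrd <- lab == "HRD"
  for (i in seq_len(nrow(pts))) {
    counts <- vapply(prim, function(f) {
      switch(feature,
             loh = sum(f$lengths > pts$l_min[i] & f$lengths < pts$l_max[i]),
             lst = sum(f$min_flank_mb > pts$s[i] & f$gap_mb < pts$m[i]),
             tai = sum(f$lengths > pts$k[i]))
    }, numeric(1))
    sc <- score_criteria(counts[is_hrd], counts[!is_hrd])
    res$p_one_tailed[i] <- sc$p_one_tailed
    res$ba[i] <- sc$ba
    res$score[i] <- sc$score
  }
  ord <- switch(feature,
                loh = order(-res$score, res$l_min, res$l_max),
                lst = order(-res$score, res$s, res$m),
                tai = order(-res$score, res$k))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, best = res[1L, , drop = FALSE])
}

#' Bootstrap selection of the HR-status cutoff
#'
#' For each candidate cutoff, draws `n_boot` bootstrap replicates of
#' `resample_per_class` samples with replacement from each annotated class
#' and computes the balanced accuracy of the rule `levels >= cutoff` implies
#' HRD; reports the median and the percentile 95% confidence interval of
#' the replicate BAs, and selects the candidate with the highest median BA.
#'
#' When several candidates tie on median BA (a separable plateau), the
#' selected cutoff is the tied candidate closest to the intersection of the
#' kernel density estimates of the two classes' levels between the class
#' medians; if no such intersection exists, the largest tied candidate is
#' taken.
#'
#' @param levels numeric vector of per-sample scar levels.
#' @param labels "HRD"/"HRP" per sample.
#' @param candidates integer vector of candidate cutoffs; default spans the
#'   observed level range.
#' @param n_boot number of bootstrap replicates.
#' @param resample_per_class samples drawn per class per replicate.
#' @param seed integer seed.
#' @return List of class `cutoff_evaluation`: `table` (per-candidate
#'   `cutoff`, `median_ba`, `ci95_low`, `ci95_high`), `selected_cutoff`,
#'   `n_boot`, `seed`.
#' @export
select_cutoff <- function(levels, labels, candidates = NULL,
                          n_boot = 10000L, resample_per_class = 29L,
                          seed = 1L) {
  labels <- as.character(labels)
  x_hrd <- levels[labels == "HRD"]
  x_hrp <- levels[labels == "HRP"]
  if (length(x_hrd) < 2L || length(x_hrp) < 2L) {
    stop("each class needs >= 2 samples")
  }
  if (is.null(candidates)) {
    candidates <- seq(floor(min(levels)), ceiling(max(levels)) + 1L)
  }
  if (length(candidates) == 0L) stop("no candidate cutoffs")
  if (any(candidates < min(levels)) || any(candidates > max(levels) + 1)) {
    warning("some candidate cutoffs fall outside the observed level range")
  }
  set.seed(seed)
  bh <- matrix(sample(x_hrd, n_boot * resample_per_class, replace = TRUE),
               nrow = resample_per_class)
  bp <- matrix(sample(x_hrp, n_boot * resample_per_class, replace = TRUE),
               nrow = resample_per_class)
  tab <- data.frame(cutoff = candidates, median_ba = NA_real_,
                    ci95_low = NA_real_, ci95_high = NA_real_)
  for (i in seq_along(candidates)) {
    co <- candidates[i]
    ba <- (colMeans(bh >= co) + colMeans(bp < co)) / 2
    q <- stats::quantile(ba, c(0.5, 0.025, 0.975), names = FALSE)
    tab$median_ba[i] <- q[1L]; tab$ci95_low[i] <- q[2L]
    tab$ci95_high[i] <- q[3L]
  }
  tied <- tab$cutoff[tab$median_ba >= max(tab$median_ba) - 1e-12]
  selected <- if (length(tied) == 1L) {
    tied
  } else {
    cross <- density_intersection(x_hrd, x_hrp)
    if (is.na(cross)) max(tied) else tied[which.min(abs(tied - cross))]
  }
  structure(list(table = tab, selected_cutoff = selected,
                 n_boot = n_boot, seed = seed),
            class = "cutoff_evaluation")
}

# x-coordinate where the two classes' kernel density estimates cross,
# searched between the class medians; NA when they never cross there.
density_intersection <- function(x_hrd, x_hrp) {
  lo <- min(c(x_hrd, x_hrp)); hi <- max(c(x_hrd, x_hrp))
  if (!is.finite(lo) || lo == hi) return(NA_real_)
  grid <- seq(lo, hi, length.out = 512)
  dh <- stats::density(x_hrd, from = lo, to = hi, n = 512)$y
  dp <- stats::density(x_hrp, from = lo, to = hi, n = 512)$y
  m1 <- min(stats::median(x_hrp), stats::median(x_hrd))
  m2 <- max(stats::median(x_hrp), stats::median(x_hrd))
  inside <- grid >= m1 & grid <= m2
  if (!any(inside)) return(NA_real_)
  diff_sign <- sign(dh - dp)[inside]
  g <- grid[inside]
  flips <- which(diff_sign[-1L] * diff_sign[-length(diff_sign)] < 0)
  if (length(flips) == 0L) return(NA_real_)
  mean(g[c(flips[1L], flips[1L] + 1L)])
}

#' @export
print.cutoff_evaluation <- function(x, ...) {
  cat(sprintf("<cutoff_evaluation> %d candidates, n_boot=%d, selected cutoff=%d\n",
              nrow(x$table), x$n_boot, as.integer(x$selected_cutoff)))
  invisible(x)
}
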