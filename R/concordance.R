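#' Lin's concordance correlation coefficient
#'
#' `ccc = 2*cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments — the conventional definition. The
#' coefficient penalizes location and scale shifts as well as scatter, so
#' `|ccc| <= |Pearson r|` always.
#'
#' @param x,y numeric vectors of equal length >= 2, finite.
#' @return Concordance coefficient in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need >= 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("degenerate input: both constant with equal means")
  2 * sxy / denom
}

#' Agreement between two binary call sets
#'
#' Aligns two HRD/HRP call vectors by sample id and reports percent
#' agreement and Cohen's kappa, `kappa = (p_o - p_e) / (1 - p_e)` with the
#' marginal-product expected agreement `p_e`.
#'
#' @param calls_a,calls_b data frames with `sample_id` and `status`
#'   ("HRD"/"HRP"), or named character vectors.
#' @return List with `percent_agreement`, `cohen_kappa`, `table` (2x2
#'   contingency counts) and `n`.
#' @export
agreement <- function(calls_a, calls_b) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.character(x$status),
                                          x$sample_id)
    else stats::setNames(as.character(x), names(x))
  }
  a <- as_named(calls_a); b <- as_named(calls_b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) stop("no shared sample ids between call sets")
  a <- a[common]; b <- b[common]
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(percent_agreement = 100 * p_o, cohen_kappa = kappa,
       table = tab, n = n)
}

#' Intra- vs inter-patient pairwise scar-level differences
#'
#' Computes `|level_i - level_j|` over all sample pairs, split into
#' same-patient (intra) and different-patient (inter) pairs, and compares
#' the two distributions with a two-sided rank-sum test.
#'
#' @param levels data frame with `patient_id`, `sample_id`, `level`
#'   (optionally `phase`).
#' @param phase restrict to one treatment phase before pairing (optional).
#' @return List with `intra`, `inter` (numeric vectors) and `p_two_sided`
#'   (NA with a warning when either set is empty).
#' @export
pairwise_level_differences <- function(levels, phase = NULL) {
  if (!is.null(phase)) levels <- levels[levels$phase %in% phase, ]
  n <- nrow(levels)
  if (n < 2L) stop("need >= 2 samples")
  pairs <- utils::combn(n, 2L)
  d <- abs(levels$level[pairs[1L, ]] - levels$level[pairs[2L, ]])
  same <- levels$patient_id[pairs[1L, ]] == levels$patient_id[pairs[2L, ]]
  intra <- d[same]; inter <- d[!same]
  p <- if (length(intra) == 0L || length(inter) == 0L) {
    warning("no intra- or no inter-patient pairs; p undefined")
    NA_real_
  } else {
    suppressWarnings(
      stats::wilcox.test(intra, inter, alternative = "two.sided")$p.value)
  }
  list(intra = intra, inter = inter, p_two_sided = p)
}

#' Tumor purity from the truncal TP53 variant allele fraction
#'
#' `purity = 2 / ((CN / VAF) - (CN - 2))`, where CN is the absolute copy
#' number at the TP53 locus and VAF the truncal TP53 variant allele
#' fraction. Values marginally above 1 (up to 1.05, VAF estimation noise)
#' are clamped to 1; values outside (0, 1.05] indicate inconsistent inputs.
#'
#' @param vaf variant allele fraction in (0, 1].
#' @param cn absolute copy number at the locus (> 0).
#' @return List with `vaf`, `cn`, `purity`.
#' @export
estimate_purity_tp53 <- function(vaf, cn) {
  if (vaf <= 0 || vaf > 1) stop("vaf must be in (0, 1]")
  if (cn <= 0) stop("cn must be > 0")
  denom <- (cn / vaf) - (cn - 2)
  if (denom <= 0) stop("inconsistent input: non-positive denominator")
  purity <- 2 / denom
  if (purity > 1 && purity <= 1.05) purity <- 1
  if (purity <= 0 || purity > 1) {
    stop(sprintf("inconsistent input: purity %.3f outside (0, 1]", purity))
  }
  list(vaf = vaf, cn = cn, purity = purity)
}

#' Resolve a patient-level scar call from multiple samples
#'
#' Drops samples below the purity floor, picks samples by anatomical-site
#' strategy, averages levels within the chosen site, and classifies HR
#' status against the criteria cutoff:
#' \describe{
#'   \item{mean_all}{average over all eligible samples.}
#'   \item{ova_then_ome}{adnexal samples (sites in `sites_ova`) if any,
#'     else omental (`sites_ome`), else any remaining site.}
#'   \item{ome_then_ova}{the reverse priority.}
#' }
#'
#' @param samples data frame `sample_id`, `level`, `site`, optionally
#'   `purity` (NA purity is treated as unknown and kept).
#' @param strategy one of `"mean_all"`, `"ova_then_ome"`, `"ome_then_ova"`.
#' @param criteria a [criteria_set] supplying the cutoff.
#' @param purity_floor minimum purity (default 0.30).
#' @param sites_ova,sites_ome site labels of the two priority groups.
#' @return List with `level`, `status`, `n_used`, `sites_used`.
#' @export
resolve_patient_level <- function(samples,
                                  strategy = c("mean_all", "ova_then_ome",
                                               "ome_then_ova"),
                                  criteria = get_preset("ovaHRDscar"),
                                  purity_floor = 0.30,
                                  sites_ova = c("OVA", "ADN"),
                                  sites_ome = "OME") {
  strategy <- match.arg(strategy)
  if (!is.null(samples$purity)) {
    keep <- is.na(samples$purity) | samples$purity >= purity_floor
    samples <- samples[keep, , drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    stop("insufficient data: no sample passes the purity floor")
  }
  pick <- switch(strategy,
    mean_all = samples,
    ova_then_ome = ,
    ome_then_ova = {
      first <- if (strategy == "ova_then_ome") sites_ova else sites_ome
      second <- if (strategy == "ova_then_ome") sites_ome else sites_ova
      if (any(samples$site %in% first)) {
        samples[samples$site %in% first, , drop = FALSE]
      } else if (any(samples$site %in% second)) {
        samples[samples$site %in% second, , drop = FALSE]
      } else samples
    })
  level <- mean(pick$level)
  list(level = level,
       status = if (level >= criteria$cutoff) "HRD" else "HRP",
       n_used = nrow(pick),
       sites_used = unique(as.character(pick$site)))
}
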