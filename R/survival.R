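#' Two-group log-rank test
#'
#' Standard log-rank comparison of event times between HRD and HRP calls,
#' via `survival::survdiff`.
#'
#' @param records data frame `patient_id`, `time_months`, `event`
#'   (logical/0-1), `group` ("HRD"/"HRP").
#' @return List with `chisq` (1 df) and `p`.
#' @export
km_logrank <- function(records) {
  if (length(unique(records$group)) < 2L) {
    stop("both groups must be present")
  }
  fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = records)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(fit$chisq), p = p)
}

#' Cox proportional-hazards comparison of HR classes
#'
#' Fits `Surv(time, event) ~ group (+ covariates)` by partial likelihood
#' (Efron tie handling) and reports, per model term, the hazard ratio with
#' its Wald 95% confidence interval and p-value. The group term is coded so
#' the reported HR is HRD vs HRP.
#'
#' @param records as in [km_logrank]; covariate columns as named in
#'   `covariates` (e.g. `residual_tumor`, `age_years`).
#' @param covariates character vector of covariate column names (optional).
#' @return Data frame with `term`, `hr`, `ci_low`, `ci_high`, `p_wald`.
#' @export
cox_ph <- function(records, covariates = NULL) {
  if (length(unique(records$group)) < 2L) {
    stop("group indicator is constant")
  }
  records$group <- factor(records$group, levels = c("HRP", "HRD"))
  n_terms <- 1L + length(covariates)
  if (sum(records$event) < n_terms + 1L) {
    stop("too few events for the number of model terms")
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~", rhs))
  fit <- survival::coxph(f, data = records, ties = "efron")
  co <- summary(fit)
  est <- co$coefficients
  if (any(!is.finite(est[, "coef"])) || any(abs(est[, "coef"]) > 15) ||
      any(est[, "se(coef)"] > 100)) {
    stop("convergence error: monotone likelihood or separation ",
         "(|coef| or se diverged)")
  }
  data.frame(term = rownames(est),
             hr = unname(est[, "exp(coef)"]),
             ci_low = unname(co$conf.int[, "lower .95"]),
             ci_high = unname(co$conf.int[, "upper .95"]),
             p_wald = unname(est[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier median survival time
#'
#' Product-limit estimate; the median is the smallest observed time at
#' which the survival curve drops to 0.5 or below, NA when the curve never
#' reaches 0.5 (heavy censoring).
#'
#' @param time event/censoring times.
#' @param event logical/0-1 event indicators.
#' @return Median time or NA.
#' @export
km_median <- function(time, event) {
  event <- as.logical(event)
  o <- order(time, -as.integer(event))  # events precede ties' censorings
  time <- time[o]; event <- event[o]
  n <- length(time)
  at_risk <- n:1
  surv <- cumprod(1 - ifelse(event, 1 / at_risk, 0))
  crossed <- which(surv <= 0.5 + 1e-12 & event)
  if (length(crossed) == 0L) return(NA_real_)
  time[crossed[1L]]
}

#' Bootstrap distribution of the median-survival fold change
#'
#' Resamples the pooled patient list with replacement `n_boot` times
#' (group labels travel with the patients; `stratified = TRUE` resamples
#' within group instead) and computes, per replicate, the fold change
#' `KM-median(HRD) / KM-median(HRP)`. Replicates in which either group's
#' KM median is undefined (curve never reaches 0.5) or empty are dropped
#' and counted.
#'
#' @param records as in [km_logrank].
#' @param n_boot number of replicates (default 1000).
#' @param seed integer seed.
#' @param stratified resample within group rather than pooled.
#' @return List of class `foldchange_distribution`: `replicates`,
#'   `n_boot`, `n_dropped`, `seed`, `summary` (median and IQR).
#' @export
bootstrap_median_foldchange <- function(records, n_boot = 1000L, seed = 1L,
                                        stratified = FALSE) {
  if (length(unique(records$group)) < 2L) {
    stop("both groups must be present")
  }
  set.seed(seed)
  n <- nrow(records)
  idx_hrd <- which(records$group == "HRD")
  idx_hrp <- which(records$group == "HRP")
  fc <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- if (stratified) {
      c(sample(idx_hrd, length(idx_hrd), replace = TRUE),
        sample(idx_hrp, length(idx_hrp), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    r <- records[idx, ]
    hrd <- r[r$group == "HRD", ]; hrp <- r[r$group == "HRP", ]
    if (nrow(hrd) == 0L || nrow(hrp) == 0L) next
    mh <- km_median(hrd$time_months, hrd$event)
    mp <- km_median(hrp$time_months, hrp$event)
    if (is.na(mh) || is.na(mp) || mp == 0) next
    fc[b] <- mh / mp
  }
  reps <- fc[!is.na(fc)]
  n_dropped <- n_boot - length(reps)
  if (n_dropped > n_boot / 2) {
    stop("reliability error: KM median undefined in > 50% of replicates")
  }
  structure(list(replicates = reps, n_boot = n_boot,
                 n_dropped = n_dropped, seed = seed,
                 summary = c(median = stats::median(reps),
                             iqr = stats::IQR(reps))),
            class = "foldchange_distribution")
}

#' @export
print.foldchange_distribution <- function(x, ...) {
  cat(sprintf(paste0("<foldchange_distribution> %d/%d replicates ",
                     "(%d dropped); median fold-change %.3f\n"),
              length(x$replicates), x$n_boot, x$n_dropped,
              x$summary[["median"]]))
  invisible(x)
}
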