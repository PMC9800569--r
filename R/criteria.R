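#' Scar selection criteria
#'
#' A `criteria_set` bundles the five parameters that define which allelic
#' imbalances count as HRD scars, plus the HR-status cutoff:
#' \describe{
#'   \item{loh_min_mb, loh_max_mb}{LOH segments with
#'     `loh_min_mb < length < loh_max_mb` are counted (strict bounds;
#'     `loh_max_mb` may be `Inf`).}
#'   \item{lst_min_segment_mb}{both segments flanking a large-scale state
#'     transition must be strictly longer than this (Mb).}
#'   \item{lst_max_gap_mb}{the uncovered gap between the flanking segments
#'     must be strictly smaller than this (Mb).}
#'   \item{tai_min_mb}{telomeric AIs strictly longer than this are counted.}
#'   \item{cutoff}{samples with scar levels `>= cutoff` are called HRD.}
#' }
#'
#' @param name label for the criteria set.
#' @param loh_min_mb,loh_max_mb,lst_min_segment_mb,lst_max_gap_mb,tai_min_mb
#'   numeric criteria in Mb, see Details.
#' @param cutoff non-negative integer HR-status cutoff.
#' @return An object of class `criteria_set`.
#' @seealso [get_preset()] for the published parameterizations.
#' @export
criteria_set <- function(name, loh_min_mb, loh_max_mb, lst_min_segment_mb,
                         lst_max_gap_mb, tai_min_mb, cutoff) {
  stopifnot(loh_min_mb >= 0, loh_min_mb < loh_max_mb,
            lst_min_segment_mb > 0, lst_max_gap_mb >= 0,
            tai_min_mb >= 0, cutoff >= 0)
  structure(list(name = name,
                 loh_min_mb = loh_min_mb, loh_max_mb = loh_max_mb,
                 lst_min_segment_mb = lst_min_segment_mb,
                 lst_max_gap_mb = lst_max_gap_mb,
                 tai_min_mb = tai_min_mb,
                 cutoff = cutoff),
            class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf(paste0("<criteria_set> %s: LOH (%g, %g) Mb; LST s=%g Mb, ",
                     "m=%g Mb; TAI k=%g Mb; cutoff >= %d\n"),
              x$name, x$loh_min_mb, x$loh_max_mb, x$lst_min_segment_mb,
              x$lst_max_gap_mb, x$tai_min_mb, as.integer(x$cutoff)))
  invisible(x)
}

.presets <- list(
  telli2016   = list(15, 50, 12, 1, 1, 42L),
  takaya2020  = list(15, 50, 12, 1, 1, 63L),
  ovaHRDscar  = list(15, 50, 12, 1, 1, 54L),
  tnbcHRDscar = list(10, 30,  5, 2, 1, 53L)
)

#' Published scar criteria presets
#'
#' The four published parameterizations of the scar counters. Telli2016,
#' Takaya2020 and ovaHRDscar share the same selection criteria
#' (LOH in (15, 50) Mb, LST s = 12 Mb / m = 1 Mb, TAI k = 1 Mb) and differ
#' only in the HR-status cutoff (42, 63 and 54 respectively). tnbcHRDscar,
#' derived for triple-negative breast cancer, uses LOH in (10, 30) Mb,
#' LST s = 5 Mb / m = 2 Mb, TAI k = 1 Mb and cutoff 53.
#'
#' @param name one of `"telli2016"`, `"takaya2020"`, `"ovaHRDscar"`,
#'   `"tnbcHRDscar"`.
#' @return A [criteria_set].
#' @examples
#' get_preset("ovaHRDscar")
#' @export
get_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.presets)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(.presets), collapse = ", "))
  }
  p <- .presets[[name]]
  criteria_set(name, p[[1]], p[[2]], p[[3]], p[[4]], p[[5]], p[[6]])
}
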