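#' Synthetic cohort simulation
#'
#' The simulator plants discrete allelic-imbalance events of four kinds on a
#' balanced (1/1) diploid baseline:
#' \describe{
#'   \item{loh}{interstitial copy-neutral LOH segments (2/0).}
#'   \item{interstitial}{interstitial non-LOH AIs (2/1).}
#'   \item{lst_pairs}{two adjacent long AI segments in different states
#'     (2/1 next to 3/1) separated by a short uncovered gap — the canonical
#'     generator of a large-scale state transition.}
#'   \item{tai}{AI segments anchored at a covered chromosome end (2/1).}
#' }
#' Events are placed uniformly at random within chromosome arms, never
#' crossing the centromere, separated from each other and from arm
#' boundaries by configurable margins so that the scar truth implied by the
#' placement geometry is computable without running the counters
#' (see [expected_scar_truth]).
#'
#' @name synthetic_cohort
NULL

#' Event length/rate component
#'
#' @param rate expected number of events per sample (Poisson).
#' @param dist `"lnorm"` or `"unif"`.
#' @param p1,p2 distribution parameters in Mb: `meanlog`/`sdlog` for
#'   `"lnorm"`, `min`/`max` for `"unif"`.
#' @param min_mb,max_mb optional truncation bounds (rejection sampling).
#' @return A list describing the component.
#' @export
event_component <- function(rate, dist = c("lnorm", "unif"), p1, p2,
                            min_mb = 0, max_mb = Inf) {
  dist <- match.arg(dist)
  stopifnot(rate >= 0, p2 > 0 || dist == "unif")
  list(rate = rate, dist = dist, p1 = p1, p2 = p2,
       min_mb = min_mb, max_mb = max_mb)
}

draw_lengths_mb <- function(comp, n) {
  if (n == 0L) return(numeric())
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 8L)
    x <- if (comp$dist == "lnorm") {
      stats::rlnorm(m, comp$p1, comp$p2)
    } else {
      stats::runif(m, comp$p1, comp$p2)
    }
    out <- c(out, x[x > comp$min_mb & x < comp$max_mb])
    guard <- guard + 1L
    if (guard > 200L) stop("length distribution incompatible with truncation")
  }
  out[seq_len(n)]
}

#' Per-class event configuration
#'
#' Defaults describe the contrast seen in real HR-deficient vs proficient
#' tumors scaled to the small default genome: HRD-like samples carry many
#' 15-50 Mb LOH segments, long adjacent state transitions and telomeric
#' AIs; HRP-like samples carry mostly sub-megabase imbalances.
#'
#' @param loh list of [event_component]s for LOH events.
#' @param interstitial list of components for non-LOH interstitial AIs.
#' @param tai list of components for telomeric AIs.
#' @param lst_rate expected number of adjacent-pair events.
#' @param lst_flank [event_component] for pair flank lengths.
#' @param lst_gap_max_mb pair-internal uncovered gap ~ Uniform(0, this).
#' @return A list of class parameters.
#' @export
class_config <- function(loh, interstitial, tai, lst_rate, lst_flank,
                         lst_gap_max_mb) {
  list(loh = loh, interstitial = interstitial, tai = tai,
       lst_rate = lst_rate, lst_flank = lst_flank,
       lst_gap_max_mb = lst_gap_max_mb)
}

default_hrd_class <- function() {
  class_config(
    loh = list(event_component(2, "lnorm", log(24), 0.35, max_mb = 60)),
    interstitial = list(event_component(2, "lnorm", log(2.5), 0.8,
                                        max_mb = 30)),
    tai = list(event_component(2, "lnorm", log(6), 0.6, max_mb = 25)),
    lst_rate = 1.5,
    lst_flank = event_component(2, "lnorm", log(16), 0.2, max_mb = 30),
    lst_gap_max_mb = 0.8)
}

default_hrp_class <- function() {
  class_config(
    loh = list(event_component(2, "lnorm", log(0.7), 0.7, max_mb = 20)),
    interstitial = list(event_component(2, "lnorm", log(0.8), 0.8,
                                        max_mb = 20),
                        event_component(0.5, "lnorm", log(8), 0.5,
                                        max_mb = 25)),
    tai = list(event_component(1, "lnorm", log(2), 0.5, max_mb = 20)),
    lst_rate = 0.5,
    lst_flank = event_component(1, "lnorm", log(6), 0.4, max_mb = 20),
    lst_gap_max_mb = 1.5)
}

#' Default simulation genome: 3 chromosomes (200/150/100 Mb) with
#' centromeres spanning 40-45% of each chromosome; small enough that
#' brute-force oracles stay cheap.
#' @return A [genome_assembly].
#' @export
sim_assembly <- function() {
  len <- c(200e6, 150e6, 100e6)
  custom_assembly(paste0("chr", 1:3), len, 0.40 * len, 0.45 * len)
}

#' Simulation configuration
#'
#' @param assembly a [genome_assembly]; default [sim_assembly()].
#' @param hrd,hrp per-class [class_config]s.
#' @param noise_rate expected number of sub-50 bp AI fragments per sample
#'   (smoothed away by [smooth_segments]).
#' @param margin_mb minimum distance (Mb) from any event to an arm
#'   boundary.
#' @param spacing_mb minimum baseline distance (Mb) between events.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(assembly = sim_assembly(),
                       hrd = default_hrd_class(),
                       hrp = default_hrp_class(),
                       noise_rate = 2, margin_mb = 13, spacing_mb = 13) {
  stopifnot(noise_rate >= 0, margin_mb >= 0, spacing_mb >= 0)
  structure(list(assembly = assembly, hrd = hrd, hrp = hrp,
                 noise_rate = noise_rate, margin_mb = margin_mb,
                 spacing_mb = spacing_mb),
            class = "sim_config")
}

# arms as data frame: chromosome, lo, hi (bp, inclusive, centromere excluded)
assembly_arms <- function(assembly) {
  ch <- assembly$chromosomes
  rbind(data.frame(chromosome = ch$chromosome, lo = 1,
                   hi = ch$centromere_start_bp - 1, arm = "p",
                   stringsAsFactors = FALSE),
        data.frame(chromosome = ch$chromosome, lo = ch$centromere_end_bp + 1,
                   hi = ch$length_bp, arm = "q", stringsAsFactors = FALSE))
}

# place an interval of width w_bp; anchored: "p"/"q" arm end or NA for
# interior. events: data.frame(chromosome, start, end). Returns list or NULL.
place_event <- function(w_bp, arms, events, margin_bp, spacing_bp,
                        anchored = NA, n_attempts = 2000L) {
  for (try in seq_len(n_attempts)) {
    a <- arms[sample.int(nrow(arms), 1L, prob = arms$hi - arms$lo + 1), ]
    if (!is.na(anchored)) {
      if (a$arm != anchored) next
      if (anchored == "p") {
        start <- a$lo
      } else {
        start <- a$hi - w_bp + 1
      }
      end <- start + w_bp - 1
      # keep the non-telomeric end away from the centromere
      if (anchored == "p" && end > a$hi - margin_bp) next
      if (anchored == "q" && start < a$lo + margin_bp) next
    } else {
      lo <- a$lo + margin_bp
      hi <- a$hi - margin_bp - w_bp + 1
      if (hi < lo) next
      start <- lo + floor(stats::runif(1) * (hi - lo + 1))
      end <- start + w_bp - 1
    }
    ev <- events[events$chromosome == a$chromosome, , drop = FALSE]
    if (nrow(ev) == 0L ||
        all(start > ev$end + spacing_bp | end < ev$start - spacing_bp)) {
      return(list(chromosome = a$chromosome, start = start, end = end,
                  arm = a$arm))
    }
  }
  NULL
}

# One sample. Event placement is rejection sampling at the sample level:
# when a drawn event load cannot be placed on the configured genome, the
# whole sample is redrawn from the next derived sub-seed (up to 20 times)
# before a capacity error is raised, so the generator conditions mildly on
# placeability instead of failing on Poisson tail draws.
simulate_profile <- function(sample_id, config, class_params, sub_seed) {
  for (attempt in 0:19) {
    r <- try(simulate_profile_once(sample_id, config, class_params,
                                   (sub_seed + attempt * 131) %% 2147483399),
             silent = TRUE)
    if (!inherits(r, "try-error")) return(r)
    if (!grepl("capacity error", attr(r, "condition")$message)) {
      stop(attr(r, "condition"))
    }
  }
  stop("capacity error: event load unplaceable on the configured genome ",
       "after 20 redraws (sample ", sample_id, ")")
}

simulate_profile_once <- function(sample_id, config, class_params, sub_seed) {
  set.seed(sub_seed)
  arms <- assembly_arms(config$assembly)
  margin_bp <- round(config$margin_mb * 1e6)
  spacing_bp <- round(config$spacing_mb * 1e6)
  events <- data.frame(chromosome = character(), start = numeric(),
                       end = numeric(), type = character(),
                       length_mb = numeric(), flank2_mb = numeric(),
                       gap_mb = numeric(), stringsAsFactors = FALSE)
  # draw all events first, then place widest-first (tightest packing)
  pending <- list()
  queue_event <- function(type, w_bp, anchored = NA, length_mb = w_bp / 1e6,
                          flank2_mb = NA, gap_mb = NA) {
    pending[[length(pending) + 1L]] <<-
      list(type = type, w_bp = w_bp, anchored = anchored,
           length_mb = length_mb, flank2_mb = flank2_mb, gap_mb = gap_mb)
  }
  for (comp in class_params$tai) {
    lens <- draw_lengths_mb(comp, stats::rpois(1L, comp$rate))
    for (l in lens) {
      queue_event("tai", round(l * 1e6), anchored = sample(c("p", "q"), 1L),
                  length_mb = l)
    }
  }
  n_pairs <- stats::rpois(1L, class_params$lst_rate)
  if (n_pairs > 0L) {
    f1 <- draw_lengths_mb(class_params$lst_flank, n_pairs)
    f2 <- draw_lengths_mb(class_params$lst_flank, n_pairs)
    gaps <- stats::runif(n_pairs, 0, class_params$lst_gap_max_mb)
    for (i in seq_len(n_pairs)) {
      w <- round(f1[i] * 1e6) + round(gaps[i] * 1e6) + round(f2[i] * 1e6)
      queue_event("lst_pair", w, length_mb = f1[i], flank2_mb = f2[i],
                  gap_mb = round(gaps[i] * 1e6) / 1e6)
    }
  }
  for (comp in class_params$loh) {
    lens <- draw_lengths_mb(comp, stats::rpois(1L, comp$rate))
    for (l in lens) queue_event("loh", round(l * 1e6), length_mb = l)
  }
  for (comp in class_params$interstitial) {
    lens <- draw_lengths_mb(comp, stats::rpois(1L, comp$rate))
    for (l in lens) queue_event("interstitial", round(l * 1e6),
                                length_mb = l)
  }
  if (length(pending) > 0L) {
    widths <- vapply(pending, `[[`, numeric(1), "w_bp")
    for (e in pending[order(-widths)]) {
      pos <- place_event(e$w_bp, arms, events, margin_bp, spacing_bp,
                         anchored = e$anchored)
      if (is.null(pos)) {
        stop("capacity error: cannot place ", e$type, " event of ",
             round(e$w_bp / 1e6, 2), " Mb on the configured genome")
      }
      events[nrow(events) + 1L, ] <- list(pos$chromosome, pos$start,
                                          pos$end, e$type, e$length_mb,
                                          e$flank2_mb, e$gap_mb)
    }
  }

  # assemble segments: event pieces + 1/1 baseline filling the rest
  state_of <- list(loh = c(2, 0), interstitial = c(2, 1), tai = c(2, 1))
  rows <- list()
  for (chrom in config$assembly$chromosomes$chromosome) {
    L <- assembly_row(config$assembly, chrom)$length_bp
    ev <- events[events$chromosome == chrom, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    cursor <- 1
    if (nrow(ev) > 0L) {
      for (i in seq_len(nrow(ev))) {
        if (ev$start[i] > cursor) {
          rows[[length(rows) + 1L]] <-
            c(chrom, cursor, ev$start[i] - 1, 1, 1)
        }
        if (ev$type[i] == "lst_pair") {
          w1 <- round(ev$length_mb[i] * 1e6)
          g <- round(ev$gap_mb[i] * 1e6)
          rows[[length(rows) + 1L]] <-
            c(chrom, ev$start[i], ev$start[i] + w1 - 1, 2, 1)
          rows[[length(rows) + 1L]] <-
            c(chrom, ev$start[i] + w1 + g, ev$end[i], 3, 1)
        } else {
          st <- state_of[[ev$type[i]]]
          rows[[length(rows) + 1L]] <-
            c(chrom, ev$start[i], ev$end[i], st[1], st[2])
        }
        cursor <- ev$end[i] + 1
      }
    }
    if (cursor <= L) rows[[length(rows) + 1L]] <- c(chrom, cursor, L, 1, 1)
  }
  seg <- data.frame(chromosome = vapply(rows, `[`, "", 1L),
                    start_bp = as.numeric(vapply(rows, `[`, "", 2L)),
                    end_bp = as.numeric(vapply(rows, `[`, "", 3L)),
                    major_cn = as.numeric(vapply(rows, `[`, "", 4L)),
                    minor_cn = as.numeric(vapply(rows, `[`, "", 5L)),
                    stringsAsFactors = FALSE)

  # sub-50 bp AI fragment noise, carved out of baseline segments
  n_noise <- stats::rpois(1L, config$noise_rate)
  if (n_noise > 0L) {
    for (k in seq_len(n_noise)) {
      base_idx <- which(seg$major_cn == 1 & seg$minor_cn == 1 &
                          seg$end_bp - seg$start_bp > 1e4)
      if (length(base_idx) == 0L) break
      i <- base_idx[sample.int(length(base_idx), 1L)]
      w <- sample.int(49L, 1L)
      p <- seg$start_bp[i] + 100 +
        floor(stats::runif(1) * (seg$end_bp[i] - seg$start_bp[i] - 200 - w))
      frag <- data.frame(chromosome = seg$chromosome[i],
                         start_bp = c(seg$start_bp[i], p, p + w),
                         end_bp = c(p - 1, p + w - 1, seg$end_bp[i]),
                         major_cn = c(1, 3, 1), minor_cn = c(1, 1, 1),
                         stringsAsFactors = FALSE)
      after <- if (i < nrow(seg)) seg[(i + 1L):nrow(seg), , drop = FALSE]
      seg <- rbind(seg[seq_len(i - 1L), , drop = FALSE], frag, after)
    }
    rownames(seg) <- NULL
  }

  profile <- segment_profile(sample_id, seg,
                             build_label = config$assembly$build_label)
  list(profile = profile, events = events)
}

#' Simulate a labeled cohort of segment profiles
#'
#' Generates `n_hrd` HRD-like and `n_hrp` HRP-like profiles under `config`.
#' Each sample uses a deterministic sub-stream derived from `seed`, its
#' class and its index, so enlarging the cohort leaves earlier samples
#' unchanged.
#'
#' @param config a [sim_config].
#' @param n_hrd,n_hrp class sizes (non-negative integers).
#' @param seed integer seed for the cohort.
#' @return List with `profiles` (named list of [segment_profile]),
#'   `labels` (data frame `sample_id`, `label`), and `events` (named list
#'   of per-sample planted-event tables, see [expected_scar_truth]).
#' @examples
#' cohort <- simulate_cohort(sim_config(), n_hrd = 2, n_hrp = 2, seed = 1)
#' cohort$labels
#' @export
simulate_cohort <- function(config, n_hrd, n_hrp, seed = 1L) {
  stopifnot(n_hrd >= 0, n_hrp >= 0)
  sub_seed <- function(class_offset, i) {
    (as.numeric(seed) * 48271 + class_offset * 1e6 + i * 7919) %% 2147483399
  }
  profiles <- list(); events <- list(); ids <- character(); lab <- character()
  for (i in seq_len(n_hrd)) {
    id <- sprintf("HRD_%03d", i)
    r <- simulate_profile(id, config, config$hrd, sub_seed(1, i))
    profiles[[id]] <- r$profile; events[[id]] <- r$events
    ids <- c(ids, id); lab <- c(lab, "HRD")
  }
  for (i in seq_len(n_hrp)) {
    id <- sprintf("HRP_%03d", i)
    r <- simulate_profile(id, config, config$hrp, sub_seed(2, i))
    profiles[[id]] <- r$profile; events[[id]] <- r$events
    ids <- c(ids, id); lab <- c(lab, "HRP")
  }
  list(profiles = profiles,
       labels = data.frame(sample_id = ids, label = lab,
                           stringsAsFactors = FALSE),
       events = events)
}

#' Scar counts implied by planted events
#'
#' Computes, from the generator's placement geometry alone (never from the
#' counters), the scar counts a correct counter must report when the
#' placement margins exceed the LST flank threshold. Each planted event
#' sits on long baseline flanks with zero uncovered gap, so an event of
#' length `l` contributes LST breakpoints at each boundary where `l`
#' exceeds `lst_min_segment_mb`.
#'
#' @param events one sample's planted-event table from [simulate_cohort].
#' @param criteria a [criteria_set].
#' @return Data frame with `n_loh`, `n_lst`, `n_tai`, `levels`.
#' @export
expected_scar_truth <- function(events, criteria) {
  s <- criteria$lst_min_segment_mb
  m <- criteria$lst_max_gap_mb
  n_loh <- sum(events$type == "loh" &
                 events$length_mb > criteria$loh_min_mb &
                 events$length_mb < criteria$loh_max_mb)
  n_tai <- sum(events$type == "tai" & events$length_mb > criteria$tai_min_mb)
  n_lst <- 0L
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$type %in% c("loh", "interstitial")) {
      n_lst <- n_lst + 2L * (e$length_mb > s)
    } else if (e$type == "tai") {
      n_lst <- n_lst + 1L * (e$length_mb > s)
    } else if (e$type == "lst_pair") {
      n_lst <- n_lst + (e$length_mb > s) + (e$flank2_mb > s) +
        (min(e$length_mb, e$flank2_mb) > s && e$gap_mb < m)
    }
  }
  data.frame(n_loh = as.integer(n_loh), n_lst = as.integer(n_lst),
             n_tai = as.integer(n_tai),
             levels = as.integer(n_loh + n_lst + n_tai))
}

#' Simulate survival records matched to HR labels
#'
#' Event times are exponential: the HRP hazard is `log(2) /
#' baseline_median_months` and the HRD hazard is that baseline times
#' `hazard_ratio_hrd` (values below 1 mean longer survival for HRD, as
#' observed for platinum-treated carriers). A fraction `censoring_rate` of
#' patients is censored at a uniform time before their event.
#'
#' @param labels data frame with `sample_id` and `label` (HRD/HRP), as
#'   returned by [simulate_cohort].
#' @param baseline_median_months median event time of the HRP group.
#' @param hazard_ratio_hrd hazard ratio of HRD vs HRP (> 0).
#' @param censoring_rate fraction in [0, 1).
#' @param seed integer seed.
#' @return Data frame `patient_id`, `time_months`, `event`, `group`.
#' @export
simulate_survival <- function(labels, baseline_median_months = 18,
                              hazard_ratio_hrd = 0.5, censoring_rate = 0.2,
                              seed = 1L) {
  if (hazard_ratio_hrd <= 0) stop("hazard_ratio_hrd must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  set.seed(seed)
  n <- nrow(labels)
  base_h <- log(2) / baseline_median_months
  h <- ifelse(labels$label == "HRD", base_h * hazard_ratio_hrd, base_h)
  t_event <- stats::rexp(n, rate = h)
  censored <- stats::runif(n) < censoring_rate
  t_obs <- ifelse(censored, stats::runif(n) * t_event, t_event)
  data.frame(patient_id = labels$sample_id,
             time_months = t_obs,
             event = !censored,
             group = labels$label,
             stringsAsFactors = FALSE)
}
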