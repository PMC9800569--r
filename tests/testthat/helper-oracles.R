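# Independent brute-force oracles and fixture generators. Everything here
# is deliberately written as plain scalar loops over the definitions, never
# reusing the package's vectorized counting paths.

# small 3-chromosome test assembly (same geometry as sim_assembly())
test_assembly <- function() {
  len <- c(200e6, 150e6, 100e6)
  custom_assembly(paste0("chr", 1:3), len, 0.40 * len, 0.45 * len)
}

# A random valid profile: per chromosome, up to max_seg contiguous-ish
# segments with random states, random covered extent, occasional uncovered
# gaps and occasional sub-50 bp fragments.
random_profile <- function(id = "r", assembly = test_assembly(),
                           max_seg = 15L) {
  rows <- list()
  for (i in seq_len(nrow(assembly$chromosomes))) {
    chrom <- assembly$chromosomes$chromosome[i]
    L <- assembly$chromosomes$length_bp[i]
    n <- sample.int(max_seg, 1L)
    start0 <- sample.int(max(L %/% 20, 2L), 1L)
    pos <- start0
    for (k in seq_len(n)) {
      w <- if (stats::runif(1) < 0.1) sample.int(60L, 1L)  # tiny fragment
           else round(stats::rlnorm(1, log(8e6), 1.1))
      end <- min(pos + w - 1, L)
      if (end < pos) break
      major <- sample(0:3, 1L)
      minor <- sample(0:major, 1L)
      if (major == 0) minor <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, start_bp = pos, end_bp = end,
        major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
      gap <- if (stats::runif(1) < 0.3) round(stats::rlnorm(1, log(5e5), 1))
             else 0
      pos <- end + 1 + gap
      if (pos > L) break
    }
  }
  segment_profile(id, do.call(rbind, rows))
}

# covered extent of one chromosome in a profile
.cov_extent <- function(seg, chrom) {
  s <- seg[seg$chromosome == chrom, ]
  c(min(s$start_bp), max(s$end_bp))
}

oracle_count_loh <- function(smoothed, assembly, criteria) {
  seg <- smoothed$segments
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    r <- seg[i, ]
    if (!(r$minor_cn == 0 && r$major_cn >= 1)) next
    len <- (r$end_bp - r$start_bp + 1) / 1e6
    if (!(len > criteria$loh_min_mb && len < criteria$loh_max_mb)) next
    ext <- .cov_extent(seg, r$chromosome)
    if (r$start_bp == ext[1] && r$end_bp == ext[2]) next  # whole chromosome
    n <- n + 1L
  }
  n
}

oracle_count_tai <- function(smoothed, assembly, criteria) {
  seg <- smoothed$segments
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    r <- seg[i, ]
    if (r$major_cn == r$minor_cn) next
    a <- assembly$chromosomes[assembly$chromosomes$chromosome ==
                                r$chromosome, ]
    ext <- .cov_extent(seg, r$chromosome)
    p_tel <- r$start_bp == ext[1]
    q_tel <- r$end_bp == ext[2]
    if (!p_tel && !q_tel) next
    if (p_tel && q_tel) next  # whole chromosome
    if (r$start_bp < a$centromere_start_bp &&
        r$end_bp > a$centromere_end_bp) next  # crosses centromere
    len <- (r$end_bp - r$start_bp + 1) / 1e6
    if (len > criteria$tai_min_mb) n <- n + 1L
  }
  n
}

oracle_count_lst <- function(smoothed, assembly, criteria) {
  seg <- smoothed$segments
  n <- 0L
  for (chrom in unique(seg$chromosome)) {
    a <- assembly$chromosomes[assembly$chromosomes$chromosome == chrom, ]
    for (arm in list(c(1, a$centromere_start_bp - 1),
                     c(a$centromere_end_bp + 1, a$length_bp))) {
      s <- seg[seg$chromosome == chrom, ]
      clipped <- list()
      for (i in seq_len(nrow(s))) {
        lo <- max(s$start_bp[i], arm[1]); hi <- min(s$end_bp[i], arm[2])
        if (lo <= hi) {
          clipped[[length(clipped) + 1L]] <-
            list(start = lo, end = hi, major = s$major_cn[i],
                 minor = s$minor_cn[i])
        }
      }
      if (length(clipped) < 2L) next
      for (i in seq_len(length(clipped) - 1L)) {
        x <- clipped[[i]]; y <- clipped[[i + 1L]]
        if (x$major == y$major && x$minor == y$minor) next
        len_x <- (x$end - x$start + 1) / 1e6
        len_y <- (y$end - y$start + 1) / 1e6
        gap <- (y$start - x$end - 1) / 1e6
        if (len_x > criteria$lst_min_segment_mb &&
            len_y > criteria$lst_min_segment_mb &&
            gap < criteria$lst_max_gap_mb) {
          n <- n + 1L
        }
      }
    }
  }
  n
}

# exhaustive-threshold stump oracle: try every value between/around the
# observed scores at a fine offset grid
oracle_stump_ba <- function(counts, labels) {
  is_hrd <- labels == "HRD"
  cand <- sort(unique(c(counts, counts - 0.5, counts + 0.5,
                        min(counts) - 1, max(counts) + 1)))
  best <- -Inf
  for (s in cand) {
    tpr <- sum(counts >= s & is_hrd) / sum(is_hrd)
    tnr <- sum(counts < s & !is_hrd) / sum(!is_hrd)
    best <- max(best, (tpr + tnr) / 2)
  }
  best
}

# exact one-tailed rank-sum p by enumerating which pooled positions belong
# to the HRD group; U computed by pair counting (independent of ranks)
oracle_u_p_greater <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); nn <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    u <- 0
    for (ai in a) for (bj in b) {
      u <- u + (ai > bj) + 0.5 * (ai == bj)
    }
    u
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(nn, n1)
  u_all <- apply(combos, 2L, u_of)
  mean(u_all >= u_obs - 1e-9)
}

# naive complete-linkage agglomeration returning the cophenetic matrix
oracle_complete_linkage_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    gi <- groups[[best[2]]]; gj <- groups[[best[3]]]
    coph[gi, gj] <- best[1]; coph[gj, gi] <- best[1]
    groups[[best[2]]] <- c(gi, gj)
    groups[[best[3]]] <- NULL
  }
  coph
}

# hand log-rank: observed-minus-expected over distinct event times
oracle_logrank_chisq <- function(time, event, group) {
  ev_times <- sort(unique(time[event]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at <- time >= t
    N <- sum(at); n1 <- sum(at & group == "HRD")
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == "HRD")
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (1 - n1 / N) * (N - d) / (N - 1)
  }
  (O1 - E1)^2 / V
}
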