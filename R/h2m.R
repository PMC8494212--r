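#' Pool heterozygous-like normal allele fractions across controls
#'
#' Collects, per locus, the normal allele fractions labelled `het` or
#' `noise` across all controls, in genomic order. Loci labelled `error`
#' (allele fraction near zero) or `hom` (near one) are excluded: only a
#' mixture of reference and non-reference reads is informative about local
#' allelic balance. Loci with no retained observation are dropped.
#'
#' @param obs Data frame of classified normal observations: columns
#'   `chrom`, `pos`, `control_id`, `n_ref`, `n_alt` and `label` (from
#'   [classify_nvaf()]).
#' @return A tibble with one row per retained (locus, control) observation:
#'   `chrom`, `pos`, `locus_idx` (genomic order index within chromosome),
#'   `control_id`, `n_alt`, `depth`, `nvaf`, `label`.
#' @export
pool_nvafs <- function(obs) {
  stopifnot(all(c("chrom", "pos", "control_id", "label") %in% names(obs)))
  counts <- normalize_counts(obs)
  pooled <- obs %>%
    mutate(depth = counts$depth, n_alt = counts$alt, nvaf = n_alt / depth) %>%
    filter(label %in% c("het", "noise")) %>%
    select(chrom, pos, control_id, n_alt, depth, nvaf, label) %>%
    arrange(chrom, pos, control_id)
  pooled %>%
    group_by(chrom) %>%
    mutate(locus_idx = match(pos, sort(unique(pos)))) %>%
    ungroup() %>%
    select(chrom, pos, locus_idx, control_id, n_alt, depth, nvaf, label)
}

#' Segment pooled loci by mean allele-fraction deviation
#'
#' Orders loci within each chromosome and segments the per-locus statistic
#' `m_i` = mean over controls of `|nvaf - 0.5|` with deterministic binary
#' segmentation: the best least-squares split of a segment is accepted
#' when it reduces the within-segment squared error by more than
#' `penalty * log(n)` noise variances, with the noise variance estimated
#' robustly from successive differences of `m_i` (insensitive to the
#' level shifts being sought). Chromosomes with fewer than
#' `2 * min_seg_size` loci form a single segment.
#'
#' @param pooled Output of [pool_nvafs()].
#' @param config Configuration list; uses `h2m$min_seg_size` and
#'   `h2m$penalty`.
#' @return A tibble of class `h2m_segments`: `segment_id`, `chrom`,
#'   `idx_start`, `idx_end`, `pos_start`, `pos_end`, `n_loci`, `baf_hat`
#'   (mean folded allele fraction, reported on (0, 0.5]). Segments
#'   partition the ordered locus list. Run [flag_h2m()] to add the
#'   deviance-based hard-to-map flag.
#' @export
segment_loci <- function(pooled, config = default_config()) {
  min_size <- config$h2m$min_seg_size
  pen_mult <- config$h2m$penalty

  per_locus <- pooled %>%
    group_by(chrom, locus_idx, pos) %>%
    summarise(m_dev = mean(abs(nvaf - 0.5)),
              folded = mean(pmin(nvaf, 1 - nvaf)),
              .groups = "drop") %>%
    arrange(chrom, locus_idx)
  if (nrow(per_locus) == 0L) {
    segs <- tibble(segment_id = integer(0), chrom = character(0),
                   idx_start = integer(0), idx_end = integer(0),
                   pos_start = integer(0), pos_end = integer(0),
                   n_loci = integer(0), baf_hat = numeric(0))
    class(segs) <- c("h2m_segments", class(segs))
    return(segs)
  }

  segs <- per_locus %>%
    group_by(chrom) %>%
    dplyr::group_modify(function(df, key) {
      bounds <- binary_segment(df$m_dev, min_size = min_size,
                               pen_mult = pen_mult)
      purrr::map_dfr(seq_len(nrow(bounds)), function(i) {
        l <- bounds$start[i]
        r <- bounds$end[i]
        tibble(
          idx_start = df$locus_idx[l],
          idx_end = df$locus_idx[r],
          pos_start = df$pos[l],
          pos_end = df$pos[r],
          n_loci = r - l + 1L,
          baf_hat = max(mean(df$folded[l:r]), 1e-6)
        )
      })
    }) %>%
    ungroup() %>%
    mutate(segment_id = row_number()) %>%
    select(segment_id, chrom, idx_start, idx_end, pos_start, pos_end,
           n_loci, baf_hat)
  class(segs) <- c("h2m_segments", class(segs))
  segs
}

# Deterministic binary segmentation on a numeric series. The noise
# variance is estimated robustly from successive differences (median
# absolute difference), so level shifts do not inflate it; a split is
# accepted when it reduces the within-segment SSE by more than
# pen_mult * log(n) noise variances (a BIC-type penalty). Returns 1-based
# (start, end) index pairs partitioning 1..length(x).
binary_segment <- function(x, min_size = 5L, pen_mult = 6) {
  n <- length(x)
  if (n == 0L) return(tibble(start = integer(0), end = integer(0)))
  log_n <- log(max(n, 2L))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(l, r) {
    s <- cs[r] - if (l > 1L) cs[l - 1L] else 0
    s2 <- cs2[r] - if (l > 1L) cs2[l - 1L] else 0
    max(s2 - s^2 / (r - l + 1L), 0)
  }
  segments <- list()
  queue <- list(c(1L, n))
  while (length(queue) > 0L) {
    seg <- queue[[1L]]
    queue <- queue[-1L]
    l <- seg[1L]; r <- seg[2L]
    m <- r - l + 1L
    if (m < 2L * min_size) {
      segments[[length(segments) + 1L]] <- seg
      next
    }
    s0 <- sse(l, r)
    ks <- (l + min_size - 1L):(r - min_size)
    s1 <- vapply(ks, function(k) sse(l, k) + sse(k + 1L, r), numeric(1))
    k_best <- ks[which.min(s1)]
    # noise scale local to this segment, robust to the level shifts sought
    sigma2 <- (median(abs(diff(x[l:r]))) / (0.6745 * sqrt(2)))^2
    penalty <- pen_mult * log_n * max(sigma2, 1e-12)
    if (s0 - min(s1) > penalty) {
      queue <- c(list(c(l, k_best), c(k_best + 1L, r)), queue)
    } else {
      segments[[length(segments) + 1L]] <- seg
    }
  }
  b <- do.call(rbind, segments)
  b <- b[order(b[, 1L]), , drop = FALSE]
  tibble(start = b[, 1L], end = b[, 2L])
}

#' Flag hard-to-map segments by the majority-deviant rule
#'
#' A (locus, control) observation is *deviant* when its alt count falls
#' outside the central `1 - alpha` binomial interval around 0.5 at its
#' depth, i.e. outside `[qbinom(alpha/2, d, 0.5), qbinom(1 - alpha/2, d,
#' 0.5)]`. A segment is hard-to-map (H2M) when the fraction of deviant
#' member observations strictly exceeds `majority_threshold` — a majority
#' of its heterozygous-like allele fractions systematically deviate from
#' 0.5.
#'
#' @param segments Output of [segment_loci()].
#' @param pooled Output of [pool_nvafs()].
#' @param config Configuration list; uses `h2m$alpha` and
#'   `h2m$majority_threshold`.
#' @return `segments` with added columns `frac_deviant` and `h2m`.
#' @export
flag_h2m <- function(segments, pooled, config = default_config()) {
  alpha <- config$h2m$alpha
  thr <- config$h2m$majority_threshold
  pooled <- pooled %>%
    mutate(deviant = n_alt < qbinom(alpha / 2, depth, 0.5) |
             n_alt > qbinom(1 - alpha / 2, depth, 0.5))
  fr <- purrr::map_dbl(seq_len(nrow(segments)), function(i) {
    m <- pooled$chrom == segments$chrom[i] &
      pooled$locus_idx >= segments$idx_start[i] &
      pooled$locus_idx <= segments$idx_end[i]
    if (!any(m)) return(0)
    mean(pooled$deviant[m])
  })
  segments$frac_deviant <- fr
  segments$h2m <- fr > thr
  segments
}

#' Merged genomic intervals covering all hard-to-map segments
#'
#' Flagged segments that are adjacent in the ordered locus list (no
#' unflagged locus between them) coalesce into one interval, as do
#' positionally overlapping ones.
#'
#' @param segments Output of [flag_h2m()].
#' @return A tibble `chrom`, `start`, `end` of 1-based inclusive intervals,
#'   merged per chromosome.
#' @export
h2m_intervals <- function(segments) {
  h <- segments[segments$h2m %in% TRUE, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  h <- h[order(h$chrom, h$idx_start), ]
  joined <- h %>%
    group_by(chrom) %>%
    mutate(gap = idx_start - dplyr::lag(idx_end, default = dplyr::first(idx_start)),
           block = cumsum(gap > 1L)) %>%
    group_by(chrom, block) %>%
    summarise(start = min(pos_start), end = max(pos_end), .groups = "drop") %>%
    select(chrom, start, end)
  merge_intervals(joined)
}

# Merge 1-based inclusive intervals per chromosome via IRanges::reduce.
merge_intervals <- function(df) {
  df %>%
    group_by(chrom) %>%
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end),
                            min.gapwidth = 1L)
      tibble(start = IRanges::start(ir), end = IRanges::end(ir))
    }) %>%
    ungroup() %>%
    arrange(chrom, start)
}

#' Interval membership of genomic positions
#'
#' @param chrom,pos Parallel vectors of positions (1-based).
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_targets()] or [h2m_intervals()].
#' @return Logical vector: `TRUE` where the position falls inside any
#'   interval.
#' @export
in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    ir <- IRanges::IRanges(start = iv$start, end = iv$end)
    sel <- which(chrom == ch)
    if (length(sel) == 0L) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' @export
print.h2m_segments <- function(x, ...) {
  cat("Allele-fraction segments:", nrow(x), "segments,",
      sum(x$h2m %in% TRUE), "flagged hard-to-map\n")
  NextMethod()
}

#' Plot pooled allele-fraction deviations and segment structure
#'
#' Per-locus mean deviation from 0.5 in locus order, with fitted segment
#' means and hard-to-map segments shaded.
#'
#' @param object An `h2m_segments` object (after [flag_h2m()]).
#' @param pooled The pooled observation table the segments were fit to.
#' @param ... Unused.
#' @return A ggplot object, faceted by chromosome.
#' @export
autoplot.h2m_segments <- function(object, pooled, ...) {
  per_locus <- pooled %>%
    group_by(chrom, locus_idx) %>%
    summarise(m_dev = mean(abs(nvaf - 0.5)), .groups = "drop")
  shade <- dplyr::filter(object, h2m %in% TRUE)
  p <- ggplot2::ggplot(per_locus,
                       ggplot2::aes(x = locus_idx, y = m_dev)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_segment(
      data = object,
      ggplot2::aes(x = idx_start, xend = idx_end,
                   y = 0.5 - baf_hat, yend = 0.5 - baf_hat),
      colour = "steelblue", linewidth = 0.9, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "ordered genomic loci", y = "mean |nVAF - 0.5|") +
    ggplot2::theme_minimal()
  if (nrow(shade) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = idx_start, xmax = idx_end, ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15, inherit.aes = FALSE)
  }
  p
}
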