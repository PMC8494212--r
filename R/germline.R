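#' Assign variants to allele-fraction segments
#'
#' Maps each variant to the segment covering its position. Within a
#' chromosome, segment bounds are extended to the midpoints between
#' consecutive segments so every position on a segmented chromosome gets a
#' segment; variants on chromosomes with no segments get `NA`.
#'
#' @param variants Data frame with columns `chrom` and `pos`.
#' @param segments An `h2m_segments` tibble.
#' @return Integer vector of `segment_id` (NA where unassigned).
#' @export
assign_segments <- function(variants, segments) {
  out <- rep(NA_integer_, nrow(variants))
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, ]
    seg <- seg[order(seg$pos_start), ]
    sel <- which(variants$chrom == ch)
    if (length(sel) == 0L) next
    # cut points: midpoints between consecutive segments
    if (nrow(seg) > 1L) {
      cuts <- (utils::head(seg$pos_end, -1L) + utils::tail(seg$pos_start, -1L)) / 2
    } else {
      cuts <- numeric(0)
    }
    idx <- findInterval(variants$pos[sel], cuts) + 1L
    out[sel] <- seg$segment_id[idx]
  }
  out
}

#' Local germline allele-fraction band per segment
#'
#' Estimates the local B-allele-fraction band of each segment as the
#' median folded tumor allele fraction `min(v, 1 - v)` of database-known
#' heterozygous SNPs inside the segment. Known heterozygous SNPs are
#' variants whose population allele frequency reaches `vige$common_af` in
#' either germline database, whose depth meets the BASE minimum, and whose
#' tumor allele fraction lies inside `vige$het_vaf` (excluding homozygous
#' database variants, which carry no band information). With fewer than
#' `vige$min_support` supporting SNPs the band is reported missing, and
#' downstream germline-equilibrium posteriors in that segment stay
#' missing too.
#'
#' @param variants Variant table with `chrom`, `pos`, `vaf`, `depth` and a
#'   `segment_id` column (see [assign_segments()]).
#' @param annotations Annotation table with `key`, `af_db1`, `af_db2`
#'   columns; joined on `key`.
#' @param config Configuration list.
#' @return A tibble `segment_id`, `baf_local`, `n_support`.
#' @export
local_baf <- function(variants, annotations, config = default_config()) {
  vc <- config$vige
  ann <- annotations %>% select(key, af_db1, af_db2)
  known <- variants %>%
    left_join(ann, by = "key") %>%
    mutate(
      af_max = pmax(dplyr::coalesce(af_db1, 0), dplyr::coalesce(af_db2, 0))
    ) %>%
    filter(
      af_max >= vc$common_af,
      depth >= config$base$min_depth,
      vaf > vc$het_vaf[1], vaf < vc$het_vaf[2],
      !is.na(segment_id)
    )
  known %>%
    group_by(segment_id) %>%
    summarise(
      baf_local = median(pmin(vaf, 1 - vaf)),
      n_support = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(baf_local = ifelse(n_support >= vc$min_support, baf_local, NA_real_))
}

#' Germline-equilibrium posterior probability
#'
#' Posterior probability that a variant is in germline equilibrium: its
#' tumor allele fraction matches the local germline band rather than a
#' sub-band somatic allele fraction. The germline likelihood is the larger
#' of the two mirrored band binomials,
#' `L_g = max(Binom(a | d, b), Binom(a | d, 1 - b))`; the somatic
#' likelihood integrates a binomial over a uniform grid of sub-band
#' success probabilities `p` in `(af_floor, band_mult * min(b, 1 - b))`
#' (step `grid_step`), using the strand-symmetric average
#' `(Binom(a | d, p) + Binom(a | d, 1 - p)) / 2` so the posterior is
#' invariant to which allele is labelled B. The posterior is
#' `gamma = w L_g / (w L_g + (1 - w) L_s)` with prior `w`.
#'
#' Variants with `gamma > 0.5` are treated as private germline by the
#' filter ladder; the posterior is always attached, never used to delete a
#' variant from the table.
#'
#' @param alt_count,depth Integer vectors of tumor alt counts and depths.
#' @param baf_local Local band per variant (recycled); `NA` yields `NA`.
#' @param config Configuration list (uses the `vige` section).
#' @return Numeric vector of posteriors in `[0, 1]` (`NA` where the band
#'   is missing).
#' @export
#' @examples
#' vige_posterior(100, 200, 0.5) # allele fraction on the band
#' vige_posterior(10, 100, 0.5)  # clearly sub-band: somatic-like
vige_posterior <- function(alt_count, depth, baf_local,
                           config = default_config()) {
  vc <- config$vige
  n <- max(length(alt_count), length(depth), length(baf_local))
  a <- rep_len(as.numeric(alt_count), n)
  d <- rep_len(as.numeric(depth), n)
  b <- rep_len(as.numeric(baf_local), n)
  w <- vc$prior
  vapply(seq_len(n), function(i) {
    if (is.na(b[i]) || is.na(a[i]) || is.na(d[i])) return(NA_real_)
    bf <- min(b[i], 1 - b[i])
    hi <- vc$band_mult * bf
    grid <- if (hi > vc$af_floor) {
      seq(vc$af_floor, hi, by = vc$grid_step)
    } else {
      vc$af_floor
    }
    lg <- max(dbinom(a[i], d[i], b[i], log = TRUE),
              dbinom(a[i], d[i], 1 - b[i], log = TRUE))
    l1 <- dbinom(a[i], d[i], grid, log = TRUE)
    l2 <- dbinom(a[i], d[i], 1 - grid, log = TRUE)
    m <- max(l1, l2)
    if (!is.finite(m)) m <- 0
    ls <- m + log(sum(exp(l1 - m) + exp(l2 - m)) / (2 * length(grid)))
    # posterior on the log scale for numerical safety at high depth
    1 / (1 + exp(log(1 - w) - log(w) + ls - lg))
  }, numeric(1))
}

#' Attach germline-equilibrium results to a variant table
#'
#' Convenience wrapper: assigns segments, estimates local bands, and
#' computes the posterior for every variant that is not database-common.
#'
#' @param variants Variant table (`chrom`, `pos`, `key`, `vaf`, `depth`,
#'   `alt_count`).
#' @param segments An `h2m_segments` tibble.
#' @param annotations Annotation table.
#' @param config Configuration list.
#' @return `variants` with columns `segment_id`, `baf_local`, `n_support`,
#'   `gamma_vige` added. Database-common variants (population AF at or
#'   above `vige$common_af`) get `NA` posteriors — they are handled by the
#'   BASE population-frequency criterion instead.
#' @export
vige_annotate <- function(variants, segments, annotations,
                          config = default_config()) {
  variants$segment_id <- assign_segments(variants, segments)
  bands <- local_baf(variants, annotations, config)
  out <- variants %>%
    left_join(bands, by = "segment_id") %>%
    left_join(select(annotations, key, af_db1, af_db2), by = "key") %>%
    mutate(
      af_max = pmax(dplyr::coalesce(af_db1, 0), dplyr::coalesce(af_db2, 0)),
      gamma_vige = ifelse(
        af_max >= config$vige$common_af,
        NA_real_,
        vige_posterior(alt_count, depth, baf_local, config)
      )
    ) %>%
    select(-af_db1, -af_db2, -af_max)
  out
}
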