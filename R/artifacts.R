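#' Two-sided Fisher exact test for strand bias
#'
#' Exact two-sided p-value on the 2x2 table
#' `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]`: the sum of hypergeometric
#' probabilities (conditional on the margins) of all tables no more
#' probable than the observed one, with the standard relative tolerance
#' `1 + 1e-7` on the comparison — the same definition as
#' [stats::fisher.test()]. The computation is vectorised directly on the
#' hypergeometric pmf so that large batches of variants (or exhaustive
#' table sweeps) do not pay the per-call overhead of building `htest`
#' objects; agreement with [stats::fisher.test()] is pinned down in the
#' test suite.
#'
#' Degenerate tables (an all-zero row or column) carry no evidence and
#' return 1.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev Non-negative integer vectors
#'   (recycled to a common length).
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @export
#' @examples
#' strand_bias_test(10, 10, 10, 10) # balanced: p = 1
#' strand_bias_test(50, 50, 20, 0)  # all alt reads on one strand
strand_bias_test <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  n <- max(length(ref_fwd), length(ref_rev), length(alt_fwd), length(alt_rev))
  rf <- rep_len(as.numeric(ref_fwd), n)
  rr <- rep_len(as.numeric(ref_rev), n)
  af <- rep_len(as.numeric(alt_fwd), n)
  ar <- rep_len(as.numeric(alt_rev), n)
  if (any(c(rf, rr, af, ar) < 0, na.rm = TRUE)) {
    stop("stranded counts must be non-negative")
  }
  vapply(seq_len(n), function(i) {
    if (anyNA(c(rf[i], rr[i], af[i], ar[i]))) return(NA_real_)
    r1 <- rf[i] + rr[i]           # ref reads (white balls)
    r2 <- af[i] + ar[i]           # alt reads (black balls)
    c1 <- rf[i] + af[i]           # forward reads drawn
    if (r1 + r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
    support <- max(0, c1 - r2):min(r1, c1)
    pr <- dhyper(support, r1, r2, c1)
    p_obs <- dhyper(rf[i], r1, r2, c1)
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' @importFrom stats dhyper
NULL

#' Cluster tumor allele fractions
#'
#' Fits a free-location binomial mixture (plus discrete-uniform noise) to
#' the tumor alt counts of BASE-passing variants and hard-assigns each
#' variant to a cluster. Sequencing-artifact classes form coherent,
#' usually low, genome-wide allele-fraction clusters; this clustering is
#' the substrate for the oxoG and FFPE criteria. Initial cluster locations
#' are spread over the quantiles of the observed allele fractions, so the
#' fit is deterministic.
#'
#' The number of binomial components is chosen by BIC over `1` to
#' `artifacts$n_clusters`, so coherent artifact bands are neither split
#' nor merged by a fixed component count.
#'
#' @param variants Variant table with `alt_count` and `depth` columns.
#' @param config Configuration list; uses `artifacts$n_clusters`,
#'   `artifacts$min_cluster_input` and the `mixture` convergence settings.
#' @return A list with `assignments` (integer cluster index per variant,
#'   `NA` for noise-assigned variants) and `model` (a `binom_mixture`, or
#'   `NULL` when there were fewer than `min_cluster_input` variants, in
#'   which case all variants share cluster 1 and no artifact flagging is
#'   possible).
#' @export
cluster_tumor_vafs <- function(variants, config = default_config()) {
  n <- nrow(variants)
  if (n == 0L) {
    return(list(assignments = integer(0), model = NULL))
  }
  if (n < config$artifacts$min_cluster_input) {
    return(list(assignments = rep(1L, n), model = NULL))
  }
  v <- variants$alt_count / variants$depth
  counts <- tibble(alt = variants$alt_count, depth = variants$depth)
  fits <- purrr::map(seq_len(config$artifacts$n_clusters), function(K) {
    p_init <- quantile(v, probs = seq(0.5 / K, 1 - 0.5 / K, length.out = K),
                       names = FALSE)
    p_init <- pmin(pmax(p_init, 1e-3), 1 - 1e-3)
    # strictly increasing start points; nudge duplicates deterministically
    if (K > 1L) {
      for (k in 2:K) {
        if (p_init[k] <= p_init[k - 1L]) p_init[k] <- p_init[k - 1L] + 1e-3
      }
    }
    p_init <- pmin(p_init, 1 - 1e-3)
    names(p_init) <- paste0("c", seq_len(K))
    fit_binom_mixture(
      counts,
      p_init = p_init,
      p_lower = 1e-4, p_upper = 1 - 1e-4,
      estimate_p = TRUE, noise = TRUE,
      tol = config$mixture$tol, max_iter = config$mixture$max_iter
    )
  })
  # free parameters per fit: K success probabilities + K free weights
  bic <- vapply(seq_along(fits), function(K) {
    -2 * fits[[K]]$loglik + 2 * K * log(n)
  }, numeric(1))
  fit <- fits[[which.min(bic)]]
  idx <- match(fit$labels, names(fit$p))
  list(assignments = idx, model = fit)
}

# Substitution class on the reference-strand representation, pairing
# complementary changes: oxoG = C>A/G>T, FFPE = C>T/G>A (indels are
# admitted into the FFPE class by the caller).
substitution_class <- function(ref, alt) {
  dplyr::case_when(
    (ref == "C" & alt == "A") | (ref == "G" & alt == "T") ~ "CA_GT",
    (ref == "C" & alt == "T") | (ref == "G" & alt == "A") ~ "CT_GA",
    TRUE ~ "other"
  )
}

#' Flag artifact variants from characterised allele-fraction clusters
#'
#' For a given artifact mode, tests every tumor allele-fraction cluster
#' for enrichment of the mode's substitution class against the background
#' class rate among all clustered variants (one-sided binomial test). A
#' cluster is *characterised by* the class when its class fraction is at
#' least `char_frac` and the enrichment p-value is below `enrich_alpha`;
#' class-member variants of characterised clusters are flagged.
#'
#' Class membership: oxoG is the C>A/G>T substitution pair (SNVs only);
#' FFPE is the C>T/G>A pair plus insertions and deletions.
#'
#' @param variants Variant table with `ref`, `alt`, `vclass` columns.
#' @param assignments Integer cluster assignment per variant (from
#'   [cluster_tumor_vafs()]); `NA` (noise) variants are never flagged.
#' @param mode `"OXOG"` or `"FFPE"`.
#' @param config Configuration list (uses the `artifacts` section).
#' @return A tibble with per-variant columns `flagged` (logical),
#'   `cluster_id`, and `enrich_pvalue` of the variant's cluster (NA for
#'   noise variants).
#' @export
flag_substitution_cluster <- function(variants, assignments, mode,
                                      config = default_config()) {
  mode <- match.arg(mode, c("OXOG", "FFPE"))
  ac <- config$artifacts
  n <- nrow(variants)
  cls <- substitution_class(variants$ref, variants$alt)
  in_class <- if (mode == "OXOG") {
    cls == "CA_GT" & variants$vclass == "SNV"
  } else {
    (cls == "CT_GA" & variants$vclass == "SNV") |
      variants$vclass %in% c("INS", "DEL")
  }
  out <- tibble(flagged = rep(FALSE, n),
                cluster_id = assignments,
                enrich_pvalue = rep(NA_real_, n))
  ok <- !is.na(assignments)
  if (!any(ok) || !any(in_class[ok])) return(out)
  bg <- mean(in_class[ok])
  if (bg >= 1) bg <- 1 - 1e-12
  for (cl in sort(unique(assignments[ok]))) {
    m <- ok & assignments == cl
    x <- sum(in_class[m])
    sz <- sum(m)
    pv <- stats::binom.test(x, sz, bg, alternative = "greater")$p.value
    out$enrich_pvalue[m] <- pv
    if (x / sz >= ac$char_frac && pv < ac$enrich_alpha) {
      out$flagged[m & in_class] <- TRUE
    }
  }
  out
}

#' Call oxoG, FFPE and strand-bias artifacts on a variant table
#'
#' Runs the tumor allele-fraction clustering, both substitution-cluster
#' modes, and the per-variant strand-bias test, and combines them into a
#' single artifact label with first-match precedence OXOG, STRANDBIAS,
#' FFPE (the ladder order); all raw flags are retained as columns.
#'
#' @param variants Variant table (BASE-passing consensus variants) with
#'   `ref`, `alt`, `vclass`, `alt_count`, `depth`, `ref_fwd`, `ref_rev`,
#'   `alt_fwd`, `alt_rev`.
#' @param config Configuration list.
#' @return `variants` with added columns `cluster_id`, `is_oxog`,
#'   `is_ffpe`, `sb_pvalue`, `is_strandbias`, and `artifact` in
#'   `c("OXOG", "STRANDBIAS", "FFPE", "NONE")`.
#' @export
call_artifacts <- function(variants, config = default_config()) {
  cl <- cluster_tumor_vafs(variants, config)
  flaggable <- !is.null(cl$model)
  if (flaggable) {
    ox <- flag_substitution_cluster(variants, cl$assignments, "OXOG", config)
    ff <- flag_substitution_cluster(variants, cl$assignments, "FFPE", config)
    is_oxog <- ox$flagged
    is_ffpe <- ff$flagged
  } else {
    is_oxog <- is_ffpe <- rep(FALSE, nrow(variants))
  }
  sb <- rep(NA_real_, nrow(variants))
  snv <- variants$vclass == "SNV" &
    !is.na(variants$ref_fwd) & !is.na(variants$ref_rev) &
    !is.na(variants$alt_fwd) & !is.na(variants$alt_rev)
  if (any(snv)) {
    sb[snv] <- strand_bias_test(variants$ref_fwd[snv], variants$ref_rev[snv],
                                variants$alt_fwd[snv], variants$alt_rev[snv])
  }
  is_sb <- !is.na(sb) & sb < config$artifacts$sb_alpha
  variants %>%
    mutate(
      cluster_id = if (flaggable) cl$assignments else NA_integer_,
      is_oxog = is_oxog,
      is_ffpe = is_ffpe,
      sb_pvalue = sb,
      is_strandbias = is_sb,
      artifact = dplyr::case_when(
        is_oxog ~ "OXOG",
        is_sb ~ "STRANDBIAS",
        is_ffpe ~ "FFPE",
        TRUE ~ "NONE"
      )
    )
}
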