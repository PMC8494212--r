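#' BASE sequencing-quality criterion
#'
#' The entry criterion of the filter ladder: a variant passes when its
#' read depth and quality score meet the minimums (inclusive), it falls
#' inside the targeted capture region, its predicted impact class is
#' retained (low/moderate/high by default), and its maximum population
#' allele frequency across the two germline databases is below the
#' common-SNP ceiling. Missing population frequencies count as zero;
#' missing impact is treated as MODIFIER and fails.
#'
#' @param variants Variant table with `chrom`, `pos`, `key`, `depth`,
#'   `qscore`.
#' @param annotations Annotation table (joined on `key`).
#' @param targets Target intervals (1-based inclusive) from
#'   [read_targets()].
#' @param config Configuration list.
#' @return Logical vector, one element per variant.
#' @export
base_filter <- function(variants, annotations, targets,
                        config = default_config()) {
  bc <- config$base
  ann <- variants %>%
    left_join(select(annotations, key, af_db1, af_db2, impact), by = "key")
  impact <- dplyr::coalesce(ann$impact, "MODIFIER")
  af_max <- pmax(dplyr::coalesce(ann$af_db1, 0), dplyr::coalesce(ann$af_db2, 0))
  variants$depth >= bc$min_depth &
    variants$qscore >= bc$min_qscore &
    in_intervals(variants$chrom, variants$pos, targets) &
    impact %in% bc$impact_keep &
    af_max < bc$max_pop_af
}

#' Quality control of unmatched normal controls
#'
#' Flags controls whose quality metrics are outliers in the unfavourable
#' direction: low median coverage, low fraction of targets at 100x, or a
#' high number of tumor calls made against them. Outliers are detected
#' with robust z-scores (deviation from the panel median in units of the
#' MAD); when the MAD of a metric is zero, any deviation in the
#' unfavourable direction counts as infinite. Because a homogeneous panel
#' has a tiny MAD, a z-score alone would exclude controls over trivial
#' absolute differences, so a control is only excluded when its metric
#' also deviates from the panel median by more than a relative margin
#' (`umnqc$rel_cut`, default 20%). With fewer than three controls no
#' exclusion is attempted.
#'
#' @param controls Tibble with `control_id`, `median_coverage`,
#'   `frac_targets_100x`, `n_calls_against`.
#' @param config Configuration list (uses `umnqc$z_cut`, `umnqc$rel_cut`).
#' @return `controls` with an added logical `excluded` column.
#' @export
umn_qc <- function(controls, config = default_config()) {
  if (nrow(controls) < 3L) {
    warning("fewer than 3 controls: no QC exclusion applied", call. = FALSE)
    controls$excluded <- FALSE
    return(controls)
  }
  cut <- config$umnqc$z_cut
  rel <- config$umnqc$rel_cut
  flag <- function(x, direction) {
    med <- median(x)
    s <- mad(x)
    z <- if (s == 0) {
      ifelse(x == med, 0, sign(x - med) * Inf)
    } else {
      (x - med) / s
    }
    rel_dev <- if (med == 0) abs(x - med) else abs(x - med) / abs(med)
    (direction * z > cut) & (rel_dev > rel)
  }
  controls$excluded <-
    flag(controls$median_coverage, -1) |
    flag(controls$frac_targets_100x, -1) |
    flag(controls$n_calls_against, 1)
  controls
}

#' Cross-normal consensus fraction
#'
#' @param n_present Number of QC-passing runs in which the variant was
#'   called (after per-run BASE filtering).
#' @param n_runs Number of QC-passing runs.
#' @param tau Consensus threshold; the comparison is inclusive, so 18 of
#'   20 runs passes at `tau = 0.9`.
#' @return A tibble with `consensus_fraction` and `consensus_pass`.
#' @export
consensus_fraction <- function(n_present, n_runs, tau = 0.9) {
  if (any(n_runs < 1L)) stop("consensus requires at least one QC-passing run")
  f <- n_present / n_runs
  tibble(consensus_fraction = f, consensus_pass = f >= tau)
}

#' Apply the cumulative filter ladder
#'
#' Combines the upstream annotations into a per-variant verdict. The
#' ladder criteria, in order, are BASE (sequencing quality), UMNQC
#' (support from at least one QC-passing control run), H2MGERM
#' (hard-to-map intervals and germline equilibrium), OXOG, STRAND and
#' FFPE (artifact classes), together with the cross-normal consensus
#' rule. A variant recurrent in the somatic database at or above
#' `cosmic$rescue_min` counts is retained regardless of every other
#' criterion. Every input variant receives a verdict row — nothing is
#' silently dropped — and the criterion flags are independent booleans,
#' so applying the artifact stages in any order yields the same final
#' set.
#'
#' @param variants Variant table that already carries the upstream
#'   results: `base_pass`, `umnqc_pass`, consensus columns
#'   (`consensus_fraction`, `consensus_pass`), germline-equilibrium
#'   columns (`gamma_vige`, from [vige_annotate()]) and artifact columns
#'   (`is_oxog`, `is_ffpe`, `sb_pvalue`, `artifact`, from
#'   [call_artifacts()]). A missing stage raises an error naming it.
#' @param annotations Annotation table (for `cosmic_count`).
#' @param h2m Hard-to-map intervals from [h2m_intervals()].
#' @param config Configuration list.
#' @return A verdict tibble: the input plus per-criterion booleans
#'   (`h2m_pass`, `vige_pass`, `oxog_pass`, `strand_pass`, `ffpe_pass`),
#'   `cosmic_count`, `cosmic_rescued` and `final_pass`.
#' @export
apply_ladder <- function(variants, annotations, h2m,
                         config = default_config()) {
  needed <- c(
    base = "base_pass", umnqc = "umnqc_pass",
    consensus = "consensus_pass", vige = "gamma_vige",
    oxog = "is_oxog", strand = "sb_pvalue", ffpe = "is_ffpe"
  )
  missing <- needed[!needed %in% names(variants)]
  if (length(missing) > 0L) {
    stop("missing upstream annotation for stage ",
         paste(names(missing), collapse = ", "), call. = FALSE)
  }
  out <- variants %>%
    left_join(select(annotations, key, cosmic_count), by = "key") %>%
    mutate(
      cosmic_count = dplyr::coalesce(cosmic_count, 0L),
      h2m_pass = !in_intervals(chrom, pos, h2m),
      vige_pass = is.na(gamma_vige) | gamma_vige <= config$vige$cut,
      oxog_pass = !is_oxog,
      strand_pass = is.na(sb_pvalue) | sb_pvalue >= config$artifacts$sb_alpha,
      ffpe_pass = !is_ffpe,
      cosmic_rescued = cosmic_count >= config$cosmic$rescue_min,
      final_pass = cosmic_rescued |
        (base_pass & umnqc_pass & h2m_pass & vige_pass &
           oxog_pass & strand_pass & ffpe_pass & consensus_pass)
    )
  class(out) <- c("umn_verdicts", class(out))
  out
}

ladder_stages <- c("BASE", "UMNQC", "H2MGERM", "OXOG", "STRAND", "FFPE")

#' Survivor sets of the cumulative ladder stages
#'
#' @param verdicts Verdict tibble from [apply_ladder()].
#' @return Named list (BASE, UMNQC, H2MGERM, OXOG, STRAND, FFPE) of
#'   variant-key character vectors. Each stage applies its criterion on
#'   top of all earlier ones; rescued variants are members of every
#'   stage.
#' @export
stage_survivors <- function(verdicts) {
  v <- verdicts
  keep <- list(
    BASE = v$base_pass & v$consensus_pass,
    UMNQC = v$umnqc_pass,
    H2MGERM = v$h2m_pass & v$vige_pass,
    OXOG = v$oxog_pass,
    STRAND = v$strand_pass,
    FFPE = v$ffpe_pass
  )
  acc <- rep(TRUE, nrow(v))
  out <- list()
  for (st in ladder_stages) {
    acc <- acc & keep[[st]]
    out[[st]] <- v$key[acc | v$cosmic_rescued]
  }
  out
}

#' Per-stage attrition of the filter ladder
#'
#' @param verdicts Verdict tibble from [apply_ladder()].
#' @return A tibble with one row per cumulative stage and the number of
#'   surviving variants.
#' @export
ladder_attrition <- function(verdicts) {
  surv <- stage_survivors(verdicts)
  tibble(stage = factor(names(surv), levels = ladder_stages),
         n_pass = vapply(surv, length, integer(1)))
}

#' Plot ladder attrition
#'
#' @param object A verdict tibble of class `umn_verdicts`.
#' @param ... Unused.
#' @return A ggplot bar chart of surviving calls per cumulative stage.
#' @export
autoplot.umn_verdicts <- function(object, ...) {
  att <- ladder_attrition(object)
  ggplot2::ggplot(att, ggplot2::aes(x = stage, y = n_pass)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cumulative filtering criterion",
                  y = "surviving variant calls") +
    ggplot2::theme_minimal()
}

#' Run the full tumor-only filtering workflow
#'
#' Orchestrates the pipeline on in-memory tables: per-run BASE filtering,
#' control quality control, cross-normal consensus, per-control
#' allele-fraction genotyping, pooled segmentation with hard-to-map
#' flagging, germline-equilibrium posteriors, artifact calling, and the
#' cumulative ladder.
#'
#' @param runs Variant table across calling runs (one row per call per
#'   run, `run_id` equal to the control identifier), e.g. row-bound
#'   outputs of [read_run_vcf()].
#' @param normals Normal genotype observations from
#'   [read_normal_genotypes()] (or the synthetic generator).
#' @param targets Target intervals from [read_targets()].
#' @param annotations Annotation table from [read_annotations()].
#' @param config Configuration list.
#' @param use_controls Optional character vector restricting the panel to
#'   a subset of control identifiers (drawn before quality control).
#' @return A list with elements `verdicts` (the per-variant verdict
#'   table), `controls` (per-control QC metrics with exclusion flags),
#'   `segments` (flagged allele-fraction segments), `h2m` (merged
#'   hard-to-map intervals) and `attrition` (per-stage survivor counts).
#' @export
run_workflow <- function(runs, normals, targets, annotations,
                         config = default_config(),
                         use_controls = NULL) {
  if (!is.null(use_controls)) {
    runs <- filter(runs, run_id %in% use_controls)
    normals <- filter(normals, control_id %in% use_controls)
  }
  if (nrow(runs) == 0L) stop("no calling runs supplied")

  # --- control QC ------------------------------------------------------
  qc <- normals %>%
    group_by(control_id) %>%
    summarise(median_coverage = median(depth),
              frac_targets_100x = mean(depth >= 100),
              .groups = "drop") %>%
    left_join(runs %>% dplyr::count(run_id, name = "n_calls_against"),
              by = c(control_id = "run_id")) %>%
    mutate(n_calls_against = dplyr::coalesce(n_calls_against, 0L))
  qc <- umn_qc(qc, config)
  passing <- qc$control_id[!qc$excluded]
  if (length(passing) == 0L) stop("all controls failed quality control")

  # --- per-run BASE filtering and consensus ----------------------------
  runs <- runs %>%
    mutate(base_pass_run = base_filter(runs, annotations, targets, config))
  pass_runs <- filter(runs, run_id %in% passing)
  pres <- pass_runs %>%
    filter(base_pass_run) %>%
    distinct(key, run_id) %>%
    dplyr::count(key, name = "n_runs_present")

  merged <- runs %>%
    group_by(key) %>%
    arrange(dplyr::desc(depth), run_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    select(-base_pass_run) %>%
    left_join(pres, by = "key") %>%
    mutate(
      n_runs_present = dplyr::coalesce(n_runs_present, 0L),
      n_runs = length(passing),
      umnqc_pass = key %in% unique(pass_runs$key)
    )
  cons <- consensus_fraction(merged$n_runs_present, merged$n_runs,
                             config$consensus$tau)
  merged <- dplyr::bind_cols(merged, cons)
  merged$base_pass <- base_filter(merged, annotations, targets, config)

  # --- normal allele-fraction model, pooling, segmentation -------------
  classified <- normals %>%
    filter(control_id %in% passing) %>%
    group_by(control_id) %>%
    dplyr::group_modify(function(df, k) {
      fit <- fit_vaf_mixture(df, config)
      df$label <- fit$labels
      df
    }) %>%
    ungroup()
  pooled <- pool_nvafs(classified)
  segments <- segment_loci(pooled, config)
  segments <- flag_h2m(segments, pooled, config)
  h2m_iv <- h2m_intervals(segments)

  # --- germline equilibrium --------------------------------------------
  merged <- vige_annotate(merged, segments, annotations, config)

  # --- artifact calling on BASE-passing consensus variants -------------
  # run-private calls (seen in a single run) are excluded from the
  # allele-fraction clustering: tumor-wide artifact clusters are defined
  # by reproducible calls
  base_set <- filter(merged, base_pass, consensus_pass)
  art <- call_artifacts(base_set, config) %>%
    select(key, cluster_id, is_oxog, is_ffpe, sb_pvalue, is_strandbias,
           artifact)
  merged <- merged %>%
    left_join(art, by = "key") %>%
    mutate(
      is_oxog = dplyr::coalesce(is_oxog, FALSE),
      is_ffpe = dplyr::coalesce(is_ffpe, FALSE),
      is_strandbias = dplyr::coalesce(is_strandbias, FALSE),
      artifact = dplyr::coalesce(artifact, "NONE")
    )

  verdicts <- apply_ladder(merged, annotations, h2m_iv, config)
  list(
    verdicts = verdicts,
    controls = qc,
    segments = segments,
    h2m = h2m_iv,
    attrition = ladder_attrition(verdicts)
  )
}
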