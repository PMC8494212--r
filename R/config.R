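#' Default workflow configuration
#'
#' Returns the full set of tunable parameters as a nested list. Values
#' mirror the thresholds of the published filter ladder where those are
#' stated (minimum depth and quality 10, consensus threshold 0.90, COSMIC
#' rescue at 10 counts, germline-equilibrium cut 0.5, strand-bias alpha
#' 0.05); the remaining numerical knobs are package defaults documented in
#' the methods vignette.
#'
#' Sections and keys:
#' \describe{
#'   \item{base}{`min_depth`, `min_qscore`, `max_pop_af`, `impact_keep` —
#'     the BASE quality criteria applied per calling run.}
#'   \item{consensus}{`tau` — minimum fraction of QC-passing runs a variant
#'     must be called in (inclusive comparison).}
#'   \item{cosmic}{`rescue_min` — COSMIC recurrence count at or above which
#'     a variant is retained regardless of other criteria.}
#'   \item{mixture}{`p_init`, `tol`, `max_iter`, `estimate_p` — EM settings
#'     for the error/het/hom + noise mixture over normal allele fractions.}
#'   \item{h2m}{`alpha` (central binomial interval used for the deviance
#'     rule), `min_seg_size`, `majority_threshold`, `penalty` (BIC penalty
#'     multiplier for binary segmentation).}
#'   \item{vige}{`prior`, `min_support`, `common_af`, `cut`, `grid_step`,
#'     `af_floor`, `band_mult`, `het_vaf` — germline-equilibrium posterior
#'     settings.}
#'   \item{artifacts}{`char_frac`, `enrich_alpha`, `sb_alpha`,
#'     `min_cluster_input`, `n_clusters` — artifact-cluster classification.}
#'   \item{umnqc}{`z_cut` — robust z-score cut for excluding low-quality
#'     unmatched normal controls.}
#' }
#'
#' @return A nested named list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$consensus$tau
default_config <- function() {
  list(
    base = list(
      min_depth = 10,
      min_qscore = 10,
      max_pop_af = 0.01,
      impact_keep = c("HIGH", "MODERATE", "LOW")
    ),
    consensus = list(tau = 0.90),
    cosmic = list(rescue_min = 10),
    mixture = list(
      p_init = c(error = 0.01, het = 0.50, hom = 0.99),
      tol = 1e-6,
      max_iter = 500L,
      estimate_p = TRUE
    ),
    h2m = list(
      alpha = 0.01,
      min_seg_size = 5L,
      majority_threshold = 0.5,
      penalty = 6
    ),
    vige = list(
      prior = 0.5,
      min_support = 5L,
      common_af = 0.01,
      cut = 0.5,
      grid_step = 1e-4,
      af_floor = 0.01,
      band_mult = 0.9,
      het_vaf = c(0.1, 0.9)
    ),
    artifacts = list(
      char_frac = 0.8,
      enrich_alpha = 0.01,
      sb_alpha = 0.05,
      min_cluster_input = 20L,
      n_clusters = 5L
    ),
    umnqc = list(z_cut = 3, rel_cut = 0.2)
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it over [default_config()]. Keys absent
#' from the file keep their defaults; unknown keys raise an error so typos
#' do not silently fall back to defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A nested named list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

merge_config <- function(cfg, user, prefix = "") {
  for (nm in names(user)) {
    full <- paste0(prefix, nm)
    if (!nm %in% names(cfg)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]] <- merge_config(cfg[[nm]], user[[nm]], paste0(full, "."))
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}
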