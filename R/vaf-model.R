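#' Classify normal-sample allele fractions into genotype states
#'
#' Fits the error / heterozygous / homozygous + noise mixture to the
#' allele counts observed in a normal control. The three genotype
#' components are binomial; the noise component is discrete uniform over
#' `{0, ..., depth}` so that loci with erratic allele fractions — the
#' non-Mendelian loci that motivate hard-to-map detection — are not forced
#' into a genotype class. Component success probabilities start at
#' `(0.01, 0.50, 0.99)` and, when estimated, are clamped to
#' `(1e-4, 0.15)`, `(0.3, 0.7)` and `(0.85, 1 - 1e-4)` respectively, which
#' fixes the genotype identity of each component by construction.
#'
#' @param obs Data frame of normal observations with columns `n_alt` and
#'   `n_ref` (or `alt` and `depth`).
#' @param config Configuration list (see [default_config()]); only the
#'   `mixture` section is used.
#' @return A `binom_mixture` fit with components `error`, `het`, `hom`
#'   (plus `noise`).
#' @export
#' @examples
#' obs <- tibble::tibble(n_alt = rbinom(300, 400, 0.5), n_ref = 400 - n_alt)
#' fit <- fit_vaf_mixture(obs)
#' table(fit$labels)
fit_vaf_mixture <- function(obs, config = default_config()) {
  obs <- normalize_counts(obs)
  mc <- config$mixture
  p_init <- mc$p_init
  if (is.null(names(p_init))) names(p_init) <- c("error", "het", "hom")
  fit_binom_mixture(
    obs,
    p_init = p_init,
    p_lower = c(1e-4, 0.3, 0.85),
    p_upper = c(0.15, 0.7, 1 - 1e-4),
    estimate_p = isTRUE(mc$estimate_p),
    noise = TRUE,
    tol = mc$tol,
    max_iter = mc$max_iter
  )
}

normalize_counts <- function(obs) {
  if (all(c("n_alt", "n_ref") %in% names(obs))) {
    tibble(alt = obs$n_alt, depth = obs$n_alt + obs$n_ref)
  } else if (all(c("alt", "depth") %in% names(obs)) && is.numeric(obs$alt)) {
    tibble(alt = obs$alt, depth = obs$depth)
  } else {
    stop("observations need numeric columns (alt, depth) or (n_alt, n_ref)")
  }
}

#' Hard genotype labels for normal observations under a fitted mixture
#'
#' @param obs Data frame of normal observations (columns `n_alt`/`n_ref`
#'   or `alt`/`depth`; any other columns are carried through).
#' @param model A `binom_mixture` fitted by [fit_vaf_mixture()].
#' @return `obs` with an added `label` column in
#'   `c("error", "het", "hom", "noise")`. Downstream pooling keeps only
#'   `het` and `noise` loci: near-zero (sequencing error) and near-one
#'   (homozygous) allele fractions carry no information about local
#'   heterozygous balance.
#' @export
classify_nvaf <- function(obs, model) {
  counts <- normalize_counts(obs)
  pred <- predict(model, counts)
  obs$label <- pred$label
  obs
}
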