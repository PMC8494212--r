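#' Build the gold-standard variant set
#'
#' Starts from the matched tumor-normal call set and removes calls lying
#' in hard-to-map intervals unless they are recurrent in the somatic
#' database (at least `cosmic$rescue_min` counts) — calls in such regions
#' are unreliable even with a matched normal.
#'
#' @param mtn_calls Tibble of matched tumor-normal calls with `chrom`,
#'   `pos`, `key`.
#' @param h2m Hard-to-map intervals from [h2m_intervals()].
#' @param annotations Annotation table (for `cosmic_count`).
#' @param config Configuration list.
#' @return Character vector of gold-standard variant keys.
#' @export
build_gold_standard <- function(mtn_calls, h2m, annotations,
                                config = default_config()) {
  ann <- mtn_calls %>%
    left_join(select(annotations, key, cosmic_count), by = "key") %>%
    mutate(
      cosmic_count = dplyr::coalesce(cosmic_count, 0L),
      in_h2m = in_intervals(chrom, pos, h2m)
    )
  ann$key[!ann$in_h2m | ann$cosmic_count >= config$cosmic$rescue_min]
}

#' Score a call set against a gold standard
#'
#' @param calls Character vector of called variant keys.
#' @param gold Character vector of gold-standard keys.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `sens`, `ppv`, `f1`;
#'   undefined ratios (empty denominators) are `NA`.
#' @export
#' @examples
#' score_calls(c("x", "y", "z"), c("x", "w"))
score_calls <- function(calls, gold) {
  calls <- unique(calls)
  gold <- unique(gold)
  tp <- length(intersect(calls, gold))
  fp <- length(setdiff(calls, gold))
  fn <- length(setdiff(gold, calls))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(ppv) && sens + ppv > 0) {
    2 * sens * ppv / (sens + ppv)
  } else {
    NA_real_
  }
  tibble(tp = tp, fp = fp, fn = fn, sens = sens, ppv = ppv, f1 = f1)
}

#' Odds ratio and Wald confidence interval for a 2x2 table
#'
#' Cross-tabulation of an exposure (rows: NO/YES) against the
#' heterozygous-versus-noise outcome (columns). The sample odds ratio is
#' `(yes_noise / yes_het) / (no_noise / no_het)` and the 95% interval is
#' Wald on the log scale, `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c +
#' 1/d))`, with a two-sided p-value from the Wald statistic. Tables with
#' a zero cell get the Haldane–Anscombe 0.5 correction, flagged in the
#' output.
#'
#' @param no_het,no_noise,yes_het,yes_noise Cell counts.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @return A one-row tibble: `or_hat`, `ci_low`, `ci_high`, `pvalue`,
#'   `corrected`.
#' @export
#' @examples
#' odds_ratio_2x2(10, 10, 10, 10) # identity table: OR 1
odds_ratio_2x2 <- function(no_het, no_noise, yes_het, yes_noise,
                           conf_z = 1.96) {
  cells <- c(no_het, no_noise, yes_het, yes_noise)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1L]; b <- cells[2L]; c_ <- cells[3L]; d <- cells[4L]
  log_or <- log((d / c_) / (b / a))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- log_or / se
  tibble(
    or_hat = exp(log_or),
    ci_low = exp(log_or - conf_z * se),
    ci_high = exp(log_or + conf_z * se),
    pvalue = 2 * stats::pnorm(-abs(z)),
    corrected = corrected
  )
}

#' Logistic model of non-Mendelian status on annotation covariates
#'
#' Optional multivariate companion to [odds_ratio_2x2()]: ordinary
#' logistic regression of a binary noise-versus-heterozygous outcome on
#' locus-level indicator covariates.
#'
#' @param data Data frame containing the outcome and covariates.
#' @param formula Model formula; the left-hand side must be a 0/1 or
#'   logical outcome (1 = noise).
#' @return A tidy tibble of odds ratios with Wald 95% intervals per term.
#' @export
nonmendelian_logit <- function(data, formula) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  est <- summary(fit)$coefficients
  tibble(
    term = rownames(est),
    or_hat = exp(est[, "Estimate"]),
    ci_low = exp(est[, "Estimate"] - 1.96 * est[, "Std. Error"]),
    ci_high = exp(est[, "Estimate"] + 1.96 * est[, "Std. Error"]),
    pvalue = est[, "Pr(>|z|)"]
  )
}
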