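# Shared fixtures: small VCF/BED text written on the fly, an
# independent exact-test oracle, and a direct germline-equilibrium
# posterior oracle that mirrors the documented definition without
# sharing code with the implementation.

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Fwd depths\">",
  "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Rev depths\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
)

write_test_vcf <- function(body, path = withr::local_tempfile(fileext = ".vcf",
                                                              .local_envir = parent.frame())) {
  writeLines(c(vcf_header, body), path)
  path
}

write_test_bed <- function(lines, path = withr::local_tempfile(fileext = ".bed",
                                                               .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Exact two-sided test by explicit enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients.
fisher_oracle <- function(rf, rr, af, ar) {
  r1 <- rf + rr
  r2 <- af + ar
  c1 <- rf + af
  if (r1 + r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  pr <- exp(logp)
  p_obs <- pr[match(rf, support)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Direct-Bayes germline-equilibrium posterior: the documented definition
# (mirrored band binomial vs sub-band uniform mixture on a fixed grid)
# computed with plain arithmetic.
vige_oracle <- function(a, d, b, prior = 0.5, af_floor = 0.01,
                        band_mult = 0.9, step = 1e-4) {
  bf <- min(b, 1 - b)
  hi <- band_mult * bf
  grid <- if (hi > af_floor) seq(af_floor, hi, by = step) else af_floor
  lg <- max(dbinom(a, d, b), dbinom(a, d, 1 - b))
  ls <- mean((dbinom(a, d, grid) + dbinom(a, d, 1 - grid)) / 2)
  prior * lg / (prior * lg + (1 - prior) * ls)
}

# A small cohort for pipeline-level tests (kept light; the acceptance
# suite exercises the full default cohort).
small_sim <- function(seed = 1, ...) {
  sim_config(
    n_controls = 12L,
    n_germline_het = 40L,
    n_germline_hom = 10L,
    n_somatic = 8L,
    n_oxog = 20L,
    n_ffpe = 10L,
    n_strandbias = 6L,
    depth_mean = 500,
    seed = seed,
    ...
  )
}

# Screen the panel once, then run the workflow on a draw of n_use
# QC-passing controls -- the study design the generator emulates.
screen_and_run <- function(bundle, n_use = 10L, draw_seed = 1L,
                           config = default_config()) {
  qc <- bundle$normals |>
    dplyr::group_by(control_id) |>
    dplyr::summarise(median_coverage = median(depth),
                     frac_targets_100x = mean(depth >= 100),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::count(bundle$runs, run_id,
                                  name = "n_calls_against"),
                     by = c(control_id = "run_id"))
  qc <- umn_qc(qc, config)
  passing <- qc$control_id[!qc$excluded]
  set.seed(draw_seed)
  use <- sample(passing, min(n_use, length(passing)))
  run_workflow(bundle$runs, bundle$normals, bundle$targets,
               bundle$annotations, config, use_controls = use)
}
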