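#' Configuration for the synthetic tumor + unmatched-normal cohort
#'
#' Returns the generator settings with defaults emulating a targeted
#' capture panel study: 20 unmatched normal controls, mean target
#' coverage near 800x, tumor purity 0.65 (so clonal somatic variants sit
#' near allele fraction 0.325), a dozen somatic variants of which a
#' fraction are recurrent somatic-database hotspots, common and private
#' germline heterozygous sites, one contiguous hard-to-map region, and
#' oxoG (allele fraction 1-3%), FFPE and strand-bias artifact classes.
#' One designated "bad" control has half coverage and five-fold the
#' run-private call load, to exercise control quality control. True
#' variants drop out of any individual run with probability `dropout`,
#' so a 90% consensus threshold is stressed but typically met.
#'
#' @param ... Named overrides of any default.
#' @return A list of generator settings.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_controls = 20L,
    n_target_regions = 6L,
    region_size = 50000L,
    depth_mean = 800,
    purity = 0.65,
    n_germline_het = 80L,
    frac_private = 0.1,
    n_germline_hom = 20L,
    n_somatic = 12L,
    frac_cosmic_somatic = 0.4,
    h2m_regions = list(list(n_loci = 15L, deviation = 0.2)),
    cosmic_h2m_prob = 0.1,
    n_oxog = 30L,
    oxog_vaf = c(0.01, 0.03),
    n_ffpe = 15L,
    ffpe_indel_frac = 1 / 3,
    ffpe_vaf = c(0.04, 0.08),
    n_strandbias = 10L,
    sb_vaf = c(0.1, 0.4),
    dropout = 0.03,
    n_private_per_run = 5L,
    bad_control = TRUE,
    epsilon = 0.001,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown simulation settings: ", paste(bad, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

rand_substitution <- function(n, classes = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(classes)) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  } else {
    pick <- classes[sample.int(length(classes), n, replace = TRUE)]
    ref <- substr(pick, 1L, 1L)
    alt <- substr(pick, 2L, 2L)
  }
  tibble(ref = ref, alt = unname(alt))
}

#' Generate a synthetic cohort with known truth labels
#'
#' Draws a tumor's variant calls against each unmatched normal control,
#' per-control genotype tables at the tumor's loci, the capture targets,
#' an annotation table and a truth table. Germline heterozygous sites
#' draw alt counts as Binomial(d, 0.5) in tumor and (for database-common
#' sites) in every control; private germline sites are absent from the
#' controls. Somatic sites are Binomial(d, purity/2) in the tumor and
#' Binomial(d, epsilon) in controls. Hard-to-map loci draw erratic allele
#' fractions in both tumor and controls: the per-observation deviation
#' from 0.5 has magnitude at least the configured `deviation`. Artifact
#' variants carry their class substitutions (or indels for part of the
#' FFPE class), and strand-bias variants put all alt reads on the forward
#' strand. Each run additionally carries a few run-private calls seen in
#' no other run.
#'
#' With a fixed seed the generator is deterministic, including the files
#' it writes.
#'
#' @param config Settings from [sim_config()].
#' @param dir Optional directory; when given, the file bundle is written
#'   there (`runs/<control>.vcf`, `normals/<control>.tsv`, `targets.bed`,
#'   `annotations.tsv`, `truth.tsv`).
#' @return A list with tibbles `runs`, `normals`, `targets`,
#'   `annotations`, `truth`, the per-run presence table `presence`, and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  n_ctl <- config$n_controls
  controls <- sprintf("N%02d", seq_len(n_ctl))
  bad_id <- if (isTRUE(config$bad_control)) controls[n_ctl] else character(0)

  # --- targets ---------------------------------------------------------
  chroms <- rep(c("chr1", "chr2", "chr3"), length.out = config$n_target_regions)
  targets <- tibble(
    chrom = chroms,
    start = 1000000L + 200000L * (seq_len(config$n_target_regions) - 1L),
    end = 1000000L + 200000L * (seq_len(config$n_target_regions) - 1L) +
      config$region_size - 1L
  ) %>% arrange(chrom, start)

  # --- hard-to-map windows (reserved sub-intervals of region 1...) -----
  empty_h2m <- tibble(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      truth = character(0), deviation = numeric(0))
  h2m_loci <- purrr::imap_dfr(config$h2m_regions, function(hr, i) {
    reg <- targets[pmin(i, nrow(targets)), ]
    w_start <- reg$start + 5000L + (i - 1L) * 10000L
    pos <- w_start + 50L * (seq_len(hr$n_loci) - 1L)
    if (any(pos > reg$end)) stop("target region too small for requested hard-to-map loci")
    sub <- rand_substitution(hr$n_loci)
    tibble(chrom = reg$chrom, pos = pos, ref = sub$ref, alt = sub$alt,
           truth = "h2m", deviation = hr$deviation)
  })
  if (nrow(h2m_loci) == 0L) h2m_loci <- empty_h2m
  h2m_windows <- if (nrow(h2m_loci) == 0L) {
    tibble(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    h2m_loci %>%
      group_by(chrom) %>%
      summarise(start = min(pos) - 25L, end = max(pos) + 25L,
                .groups = "drop")
  }

  draw_positions <- function(n) {
    # sample unique positions in targets, outside reserved windows
    out <- tibble(chrom = character(0), pos = integer(0))
    while (nrow(out) < n) {
      ridx <- sample.int(nrow(targets), n, replace = TRUE)
      cand <- tibble(
        chrom = targets$chrom[ridx],
        pos = targets$start[ridx] +
          sample.int(config$region_size, n, replace = TRUE) - 1L
      )
      cand <- cand[!in_intervals(cand$chrom, cand$pos, h2m_windows), ]
      out <- distinct(bind_rows(out, cand), chrom, pos)
    }
    out[seq_len(n), ]
  }

  n_het <- config$n_germline_het
  n_priv <- round(config$frac_private * n_het)
  n_common <- n_het - n_priv
  counts <- c(
    germline_common = n_common,
    germline_private = n_priv,
    germline_hom = config$n_germline_hom,
    somatic = config$n_somatic,
    oxog = config$n_oxog,
    ffpe = config$n_ffpe,
    strandbias = config$n_strandbias
  )
  k_private <- config$n_private_per_run *
    ifelse(controls %in% bad_id, 5L, 1L)
  all_pos <- draw_positions(sum(counts) + sum(k_private))
  loci <- all_pos[seq_len(sum(counts)), ]
  private_pos <- all_pos[sum(counts) + seq_len(sum(k_private)), ]
  loci$truth <- rep(names(counts), counts)

  alleles <- vector("list", nrow(loci))
  n_ffpe_indel <- round(config$ffpe_indel_frac * config$n_ffpe)
  ffpe_rows <- which(loci$truth == "ffpe")
  ffpe_indel_rows <- utils::head(ffpe_rows, n_ffpe_indel)
  for (i in seq_len(nrow(loci))) {
    alleles[[i]] <- switch(
      loci$truth[i],
      oxog = rand_substitution(1L, c("CA", "GT")),
      ffpe = if (i %in% ffpe_indel_rows) {
        if (stats::runif(1) < 0.5) tibble(ref = "AT", alt = "A")
        else tibble(ref = "A", alt = "AT")
      } else {
        rand_substitution(1L, c("CT", "GA"))
      },
      strandbias = rand_substitution(1L, c("AT", "TA", "CG", "GC")),
      rand_substitution(1L)
    )
  }
  loci$ref <- vapply(alleles, function(x) x$ref, character(1))
  loci$alt <- vapply(alleles, function(x) x$alt, character(1))
  loci$deviation <- NA_real_

  variants <- bind_rows(loci, h2m_loci) %>% arrange(chrom, pos)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)

  # --- true tumor allele fractions -------------------------------------
  variants$p_true <- dplyr::case_when(
    variants$truth %in% c("germline_common", "germline_private") ~ 0.5,
    variants$truth == "germline_hom" ~ 0.99,
    variants$truth == "somatic" ~ config$purity / 2,
    variants$truth == "oxog" ~ runif(nrow(variants), config$oxog_vaf[1],
                                     config$oxog_vaf[2]),
    variants$truth == "ffpe" ~ runif(nrow(variants), config$ffpe_vaf[1],
                                     config$ffpe_vaf[2]),
    variants$truth == "strandbias" ~ runif(nrow(variants), config$sb_vaf[1],
                                           config$sb_vaf[2]),
    variants$truth == "h2m" ~ runif(nrow(variants), 0.1, 0.9)
  )

  # --- tumor read counts (shared across runs: same tumor) --------------
  nv <- nrow(variants)
  variants$depth <- pmax(rpois(nv, config$depth_mean), 20L)
  variants$alt_count <- pmax(rbinom(nv, variants$depth, variants$p_true), 1L)
  variants$alt_fwd <- ifelse(
    variants$truth == "strandbias",
    variants$alt_count,
    rbinom(nv, variants$alt_count, 0.5)
  )
  variants$alt_rev <- variants$alt_count - variants$alt_fwd
  ref_n <- variants$depth - variants$alt_count
  variants$ref_fwd <- rbinom(nv, ref_n, 0.5)
  variants$ref_rev <- ref_n - variants$ref_fwd
  variants$vaf <- variants$alt_count / variants$depth
  variants$qscore <- round(runif(nv, 30, 90), 1)
  variants$vclass <- variant_class(variants$ref, variants$alt)

  # --- annotations ------------------------------------------------------
  ann <- variants %>%
    mutate(
      af_db1 = ifelse(truth %in% c("germline_common", "germline_hom"),
                      round(runif(nv, 0.05, 0.5), 4), 0),
      af_db2 = ifelse(truth %in% c("germline_common", "germline_hom"),
                      round(runif(nv, 0.05, 0.5), 4), 0),
      cosmic_count = dplyr::case_when(
        truth == "somatic" & runif(nv) < config$frac_cosmic_somatic ~
          sample(10:80, nv, replace = TRUE),
        truth == "h2m" & runif(nv) < config$cosmic_h2m_prob ~
          sample(10:30, nv, replace = TRUE),
        TRUE ~ 0L
      ),
      umap = ifelse(truth == "h2m", round(runif(nv, 0.5, 1), 3), 1),
      grc_patch = ifelse(truth == "h2m", runif(nv) < 0.3, runif(nv) < 0.02),
      impact = dplyr::case_when(
        truth == "somatic" ~ sample(c("HIGH", "MODERATE"), nv, replace = TRUE),
        TRUE ~ sample(c("MODERATE", "LOW"), nv, replace = TRUE)
      )
    ) %>%
    select(chrom, pos, ref, alt, key, af_db1, af_db2, cosmic_count,
           umap, grc_patch, impact)

  # --- run-private calls ------------------------------------------------
  private_pos$run_only <- rep(controls, k_private)
  private <- purrr::map_dfr(controls, function(id) {
    p <- private_pos[private_pos$run_only == id, ]
    k <- nrow(p)
    sub <- rand_substitution(k)
    d <- pmax(rpois(k, config$depth_mean), 20L)
    a <- pmax(rbinom(k, d, runif(k, 0.05, 0.3)), 1L)
    af <- rbinom(k, a, 0.5)
    rf <- rbinom(k, d - a, 0.5)
    tibble(
      chrom = p$chrom, pos = p$pos, ref = sub$ref, alt = sub$alt,
      truth = "run_private", deviation = NA_real_,
      key = variant_key(p$chrom, p$pos, sub$ref, sub$alt),
      p_true = NA_real_, depth = d, alt_count = a,
      alt_fwd = af, alt_rev = a - af, ref_fwd = rf, ref_rev = d - a - rf,
      vaf = a / d, qscore = round(runif(k, 30, 90), 1),
      vclass = variant_class(sub$ref, sub$alt),
      run_only = id
    )
  })
  ann_private <- private %>%
    mutate(af_db1 = 0, af_db2 = 0, cosmic_count = 0L, umap = 1,
           grc_patch = FALSE,
           impact = sample(c("MODERATE", "LOW"), nrow(private),
                           replace = TRUE)) %>%
    select(chrom, pos, ref, alt, key, af_db1, af_db2, cosmic_count,
           umap, grc_patch, impact)

  # --- per-run presence and run tables ---------------------------------
  presence <- purrr::map_dfr(controls, function(id) {
    keep <- runif(nv) > config$dropout
    bind_rows(
      tibble(key = variants$key[keep], run_id = id),
      tibble(key = private$key[private$run_only == id], run_id = id)
    )
  })
  all_vars <- bind_rows(variants, select(private, -run_only))
  runs <- presence %>%
    left_join(all_vars, by = "key") %>%
    select(chrom, pos, ref, alt, key, vclass, ref_fwd, ref_rev,
           alt_fwd, alt_rev, depth, alt_count, vaf, qscore, run_id) %>%
    arrange(run_id, chrom, pos, ref, alt)

  # --- normal genotype tables ------------------------------------------
  dev0 <- dplyr::coalesce(variants$deviation, 0)
  normals <- purrr::map_dfr(controls, function(id) {
    cov <- config$depth_mean * if (id %in% bad_id) 0.5 else 1
    d <- pmax(rpois(nv, cov), 10L)
    dev <- runif(nv, dev0, dev0 + 0.25)
    p_h2m <- pmin(pmax(0.5 + ifelse(runif(nv) < 0.5, -1, 1) * dev, 0.02),
                  0.98)
    p_n <- dplyr::case_when(
      variants$truth == "germline_hom" ~ 0.995,
      variants$truth == "germline_common" ~ 0.5,
      variants$truth == "h2m" ~ p_h2m,
      TRUE ~ config$epsilon
    )
    na <- rbinom(nv, d, p_n)
    tibble(
      control_id = id,
      chrom = variants$chrom, pos = variants$pos,
      ref = variants$ref, alt = variants$alt, key = variants$key,
      n_ref = d - na, n_alt = na, depth = d, nvaf = na / d
    )
  })

  truth <- bind_rows(
    select(variants, chrom, pos, ref, alt, key, truth, p_true),
    select(private, chrom, pos, ref, alt, key, truth, p_true)
  ) %>% arrange(chrom, pos, ref, alt)
  annotations <- bind_rows(ann, ann_private) %>% arrange(chrom, pos, ref, alt)

  bundle <- list(
    runs = runs,
    normals = normals,
    targets = targets,
    annotations = annotations,
    truth = truth,
    presence = presence,
    config = config
  )
  if (!is.null(dir)) {
    write_cohort(bundle, dir)
  }
  bundle
}

#' Write a synthetic cohort bundle to disk
#'
#' @param bundle Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "normals"), recursive = TRUE, showWarnings = FALSE)
  write_bed(bundle$targets, file.path(dir, "targets.bed"))
  readr::write_tsv(select(bundle$annotations, -key),
                   file.path(dir, "annotations.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  for (id in unique(bundle$runs$run_id)) {
    rv <- filter(bundle$runs, run_id == id)
    write_run_vcf(rv, file.path(dir, "runs", paste0(id, ".vcf")))
    nb <- bundle$normals %>%
      filter(control_id == id) %>%
      select(chrom, pos, ref, alt, n_ref, n_alt)
    readr::write_tsv(nb, file.path(dir, "normals", paste0(id, ".tsv")))
  }
  invisible(dir)
}

# Emit one run's calls as a minimal VCF 4.2 with per-allele stranded
# depths in FORMAT fields ADF/ADR.
write_run_vcf <- function(rv, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=umnvar-simulate",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allele depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
  )
  rv <- arrange(rv, chrom, pos, ref, alt)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\t.\t.\tADF:ADR\t%d,%d:%d,%d",
    rv$chrom, rv$pos, rv$ref, rv$alt, format(rv$qscore),
    rv$ref_fwd, rv$alt_fwd, rv$ref_rev, rv$alt_rev
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
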