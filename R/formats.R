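#' Canonical variant key
#'
#' Variants are matched across calling runs by exact match on the
#' normalised `(chrom, pos, ref, alt)` tuple.
#'
#' @param chrom,pos,ref,alt Vectors describing variants.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Trim shared allele context from ref/alt pairs
#'
#' Removes bases shared by the reference and alternate allele — first the
#' common suffix, then the common prefix (always keeping at least one base
#' of each allele) — and shifts the position past the trimmed prefix. This
#' puts the padded indel representations produced by different calling
#' runs on a common key. Full left-alignment against the reference genome
#' is out of scope: it needs the FASTA, and trimming alone is sufficient
#' for callers that emit anchored indels.
#'
#' @param pos,ref,alt Parallel vectors (1-based position, allele strings).
#' @return A tibble with normalised `pos`, `ref`, `alt`.
#' @export
#' @examples
#' trim_alleles(100, "CTT", "CT")   # one-base deletion, trimmed to pos 101
trim_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) > nchar(ref) ~ "INS",
    nchar(alt) < nchar(ref) ~ "DEL",
    TRUE ~ "MNV"
  )
}

#' Read one calling run's VCF into a variant table
#'
#' Parses a VCF 4.2 file of tumor calls made against one unmatched normal
#' control. Multi-allelic rows are decomposed into one record per ALT
#' allele; stranded allele depths are taken from the per-sample `ADF` /
#' `ADR` FORMAT fields, with an optional fallback to a DP4-style INFO tag
#' (four comma-separated counts: ref-forward, ref-reverse, alt-forward,
#' alt-reverse). Alleles are normalised with [trim_alleles()] so the same
#' indel called in different runs shares a key.
#'
#' @param path Path to a VCF file.
#' @param run_id Identifier attached to every record of this run.
#' @param fallback_info INFO tag to use when `ADF`/`ADR` are absent, or
#'   `NULL` to disable the fallback.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `vclass`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`, `depth`,
#'   `alt_count`, `vaf`, `qscore`, `run_id`, sorted by
#'   `(chrom, pos, ref, alt)`.
#' @export
read_run_vcf <- function(path, run_id, fallback_info = "DP4") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix) # single-row VCF drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_variant_table())
  }
  pos_num <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos_num)) {
    bad <- which(is.na(pos_num))[1L]
    stop("malformed coordinate in ", path, ", data line ", bad,
         ": POS=", fix$POS[bad], call. = FALSE)
  }

  has_format <- ncol(vcf@gt) >= 2L
  adf <- adr <- NULL
  if (has_format) {
    fmt <- vcf@gt[, 1L]
    if (all(grepl("(^|:)ADF(:|$)", fmt)) && all(grepl("(^|:)ADR(:|$)", fmt))) {
      adf <- vcfR::extract.gt(vcf, element = "ADF")[, 1L]
      adr <- vcfR::extract.gt(vcf, element = "ADR")[, 1L]
    }
  }
  use_fallback <- is.null(adf)
  if (use_fallback) {
    if (is.null(fallback_info)) {
      stop("no stranded depths: FORMAT fields ADF/ADR absent in ", path,
           " and no fallback INFO tag configured", call. = FALSE)
    }
    dp4 <- vcfR::extract.info(vcf, element = fallback_info)
    if (all(is.na(dp4))) {
      stop("no stranded depths: FORMAT fields ADF/ADR and INFO tag ",
           fallback_info, " absent in ", path, call. = FALSE)
    }
  }

  qual <- suppressWarnings(as.numeric(fix$QUAL))
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (use_fallback) {
      cnt <- as.numeric(strsplit(dp4[i], ",", fixed = TRUE)[[1L]])
      if (length(cnt) != 4L || anyNA(cnt)) {
        stop("malformed ", fallback_info, " INFO tag in ", path,
             ", data line ", i, call. = FALSE)
      }
      # DP4 carries a single alt; applies to the first ALT allele only
      per_alt_f <- c(cnt[3L], rep(NA_real_, max(0L, length(alts) - 1L)))
      per_alt_r <- c(cnt[4L], rep(NA_real_, max(0L, length(alts) - 1L)))
      rf <- cnt[1L]
      rr <- cnt[2L]
    } else {
      f <- as.numeric(strsplit(adf[i], ",", fixed = TRUE)[[1L]])
      r <- as.numeric(strsplit(adr[i], ",", fixed = TRUE)[[1L]])
      if (length(f) != length(alts) + 1L || length(r) != length(alts) + 1L) {
        stop("ADF/ADR length does not match allele count in ", path,
             ", data line ", i, call. = FALSE)
      }
      rf <- f[1L]
      rr <- r[1L]
      per_alt_f <- f[-1L]
      per_alt_r <- r[-1L]
    }
    norm <- trim_alleles(rep(pos_num[i], length(alts)),
                         rep(fix$REF[i], length(alts)), alts)
    tibble(
      chrom = fix$CHROM[i],
      pos = norm$pos,
      ref = norm$ref,
      alt = norm$alt,
      ref_fwd = rf,
      ref_rev = rr,
      alt_fwd = per_alt_f,
      alt_rev = per_alt_r,
      qscore = qual[i]
    )
  })

  rows %>%
    mutate(
      key = variant_key(chrom, pos, ref, alt),
      vclass = variant_class(ref, alt),
      depth = ref_fwd + ref_rev + alt_fwd + alt_rev,
      alt_count = alt_fwd + alt_rev,
      vaf = alt_count / depth,
      run_id = run_id
    ) %>%
    select(chrom, pos, ref, alt, key, vclass, ref_fwd, ref_rev,
           alt_fwd, alt_rev, depth, alt_count, vaf, qscore, run_id) %>%
    arrange(chrom, pos, ref, alt)
}

empty_variant_table <- function() {
  tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), key = character(0), vclass = character(0),
    ref_fwd = numeric(0), ref_rev = numeric(0), alt_fwd = numeric(0),
    alt_rev = numeric(0), depth = numeric(0), alt_count = numeric(0),
    vaf = numeric(0), qscore = numeric(0), run_id = character(0)
  )
}

#' Read a targeted-capture interval file (BED)
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read, then sorted and merged (adjacent
#' intervals coalesce).
#'
#' @param path Path to a BED file (first three columns used).
#' @return A tibble `chrom`, `start`, `end` (1-based inclusive), merged.
#' @export
read_targets <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  start0 <- suppressWarnings(as.numeric(raw[[2L]]))
  end0 <- suppressWarnings(as.numeric(raw[[3L]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)
  if (length(bad) > 0L) {
    stop("invalid BED interval at line ", bad[1L], " of ", path,
         call. = FALSE)
  }
  merge_intervals(tibble(chrom = raw[[1L]],
                         start = as.integer(start0) + 1L,
                         end = as.integer(end0)))
}

#' Write intervals as a BED file
#'
#' Converts the package's 1-based inclusive intervals back to 0-based
#' half-open BED on write (used e.g. to export hard-to-map intervals).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- tibble(chrom = intervals$chrom,
               start = intervals$start - 1L,
               end = intervals$end)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read per-control normal genotype tables
#'
#' Each control contributes a TSV with columns `chrom`, `pos`, `ref`,
#' `alt`, `n_ref`, `n_alt` (ref/alt read depths at the tumor's detected
#' loci in that control).
#'
#' @param paths Named character vector: names are control identifiers,
#'   values are file paths.
#' @return A tibble with `control_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `key`, `n_ref`, `n_alt`, `depth`, `nvaf`.
#' @export
read_normal_genotypes <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  purrr::imap_dfr(paths, function(p, id) {
    df <- readr::read_tsv(p, show_col_types = FALSE,
                          col_types = readr::cols(
                            chrom = "c", pos = "i", ref = "c", alt = "c",
                            n_ref = "d", n_alt = "d"))
    df %>%
      mutate(control_id = id,
             key = variant_key(chrom, pos, ref, alt),
             depth = n_ref + n_alt,
             nvaf = n_alt / depth) %>%
      select(control_id, chrom, pos, ref, alt, key, n_ref, n_alt,
             depth, nvaf)
  })
}

#' Read the per-locus annotation table
#'
#' A prepared TSV with one row per variant: population allele frequencies
#' from two germline databases (`af_db1`, `af_db2`; missing allowed),
#' somatic-database recurrence (`cosmic_count`), mappability (`umap`),
#' reference-patch flag (`grc_patch`) and predicted impact class
#' (`impact` in HIGH/MODERATE/LOW/MODIFIER).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble keyed by `key`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = "c", pos = "i", ref = "c", alt = "c",
                          af_db1 = "d", af_db2 = "d", cosmic_count = "i",
                          umap = "d", grc_patch = "l", impact = "c"))
  ok <- c(df$af_db1, df$af_db2)
  if (any(!is.na(ok) & (ok < 0 | ok > 1))) {
    stop("population allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  df %>% mutate(key = variant_key(chrom, pos, ref, alt))
}

#' Write and read the verdict table
#'
#' The verdict table is serialised as TSV; `read_verdicts()` restores it
#' with the same column types so that a write/read round trip reproduces
#' the table field for field.
#'
#' @param verdicts A verdict tibble from [apply_ladder()].
#' @param path Output path.
#' @return `write_verdicts()`: `path`, invisibly. `read_verdicts()`: the
#'   verdict tibble.
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_tsv(verdicts, path, na = "NA")
  invisible(path)
}

#' @rdname write_verdicts
#' @export
read_verdicts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", pos = "i", ref = "c", alt = "c",
                    key = "c", vclass = "c", artifact = "c",
                    cluster_id = "i", segment_id = "i",
                    n_support = "i", n_runs_present = "i", n_runs = "i",
                    .default = readr::col_guess()))
}

# FILTER tags, bit-exact: PASS, BASE_QC, H2M, VIGE, OXOG, STRANDBIAS,
# FFPE, NOCONSENSUS.
filter_string <- function(v) {
  if (v$final_pass) return("PASS")
  tags <- c(
    if (!v$base_pass) "BASE_QC",
    if (!v$h2m_pass) "H2M",
    if (!v$vige_pass) "VIGE",
    if (!v$oxog_pass) "OXOG",
    if (!v$strand_pass) "STRANDBIAS",
    if (!v$ffpe_pass) "FFPE",
    if (!v$consensus_pass) "NOCONSENSUS"
  )
  if (length(tags) == 0L) "NOCONSENSUS" else paste(tags, collapse = ";")
}

#' Write the filtered call set as a VCF
#'
#' Emits a VCF 4.2 whose FILTER column carries the verdict of every
#' variant: `PASS` for retained variants (including COSMIC-rescued ones)
#' and a semicolon-joined subset of `BASE_QC`, `H2M`, `VIGE`, `OXOG`,
#' `STRANDBIAS`, `FFPE`, `NOCONSENSUS` otherwise. The germline-equilibrium
#' posterior and consensus fraction are carried in INFO.
#'
#' @param verdicts Verdict tibble from [apply_ladder()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(verdicts, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=umnvar",
    "##FILTER=<ID=BASE_QC,Description=\"Fails depth/quality/target/impact/population-frequency criteria\">",
    "##FILTER=<ID=H2M,Description=\"Located in a hard-to-map interval\">",
    "##FILTER=<ID=VIGE,Description=\"Germline-equilibrium posterior above threshold\">",
    "##FILTER=<ID=OXOG,Description=\"Member of an oxoG-characterised allele-fraction cluster\">",
    "##FILTER=<ID=STRANDBIAS,Description=\"Fisher strand-bias test below alpha\">",
    "##FILTER=<ID=FFPE,Description=\"Member of an FFPE-characterised allele-fraction cluster\">",
    "##FILTER=<ID=NOCONSENSUS,Description=\"Called in too small a fraction of control runs\">",
    "##INFO=<ID=VIGE_P,Number=1,Type=Float,Description=\"Germline-equilibrium posterior\">",
    "##INFO=<ID=CONSENSUS,Number=1,Type=Float,Description=\"Fraction of QC-passing runs with this call\">",
    "##INFO=<ID=RESCUE,Number=0,Type=Flag,Description=\"Retained by somatic-database recurrence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ord <- order(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
  v <- verdicts[ord, ]
  body <- vapply(seq_len(nrow(v)), function(i) {
    row <- v[i, ]
    info <- paste0(
      "VIGE_P=", ifelse(is.na(row$gamma_vige), ".",
                        format(row$gamma_vige, digits = 6)),
      ";CONSENSUS=", format(row$consensus_fraction, digits = 6),
      if (isTRUE(row$cosmic_rescued)) ";RESCUE" else ""
    )
    paste(row$chrom, row$pos, ".", row$ref, row$alt,
          format(row$qscore, digits = 6), filter_string(row), info,
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
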