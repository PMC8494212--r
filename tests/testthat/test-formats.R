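test_that("stranded depths, total depth and VAF come from ADF/ADR", {
  p <- write_test_vcf("chr1\t100\t.\tA\tG\t30\t.\t.\tADF:ADR\t9,5:11,5")
  v <- read_run_vcf(p, "N01")
  expect_equal(nrow(v), 1L)
  expect_equal(v$depth, 30)
  expect_equal(v$alt_count, 10)
  expect_equal(v$vaf, 1 / 3)
  expect_equal(v$ref_fwd, 9)
  expect_equal(v$alt_rev, 5)
  expect_equal(v$qscore, 30)
  expect_equal(v$vclass, "SNV")
  expect_equal(v$run_id, "N01")
})

test_that("an empty VCF body yields an empty variant table", {
  p <- write_test_vcf(character(0))
  v <- read_run_vcf(p, "N01")
  expect_equal(nrow(v), 0L)
  expect_true(all(c("key", "depth", "vaf", "run_id") %in% names(v)))
})

test_that("multi-allelic rows decompose into per-ALT records conserving reads", {
  p <- write_test_vcf("chr1\t100\t.\tA\tG,T\t50\t.\t.\tADF:ADR\t10,4,2:10,6,3")
  v <- read_run_vcf(p, "N01")
  # hand-decomposed: two records sharing chrom/pos/ref, differing alt
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("G", "T"))
  expect_equal(v$pos, c(100L, 100L))
  expect_equal(v$alt_count, c(10, 5))
  # read conservation: ref depth + sum of per-alt depths = site total
  site_total <- 10 + 4 + 2 + 10 + 6 + 3
  expect_equal(unique(v$ref_fwd + v$ref_rev) + sum(v$alt_count), site_total)
})

test_that("missing stranded-depth fields raise an error naming the tags", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tG\t30\t.\t.\tGT\t0/1"
  ), p)
  expect_error(read_run_vcf(p, "N01", fallback_info = NULL), "ADF/ADR")
  expect_error(read_run_vcf(p, "N01", fallback_info = "DP4"), "DP4")
})

test_that("a DP4-style INFO tag serves as stranded-depth fallback", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t30\t.\tDP4=9,11,5,5"
  ), p)
  v <- read_run_vcf(p, "N01")
  expect_equal(v$depth, 30)
  expect_equal(v$alt_count, 10)
})

test_that("allele trimming normalises padded indels onto a shared key", {
  # suffix-padded deletion CTT>CT reduces to the anchored form CT>C, so
  # both spellings share one key
  tr <- trim_alleles(100L, "CTT", "CT")
  expect_equal(tr$pos, 100L)
  expect_equal(tr$ref, "CT")
  expect_equal(tr$alt, "C")
  tr_b <- trim_alleles(100L, "CT", "C")
  expect_identical(tr, tr_b)
  # suffix-padded SNV
  tr2 <- trim_alleles(50L, "AG", "CG")
  expect_equal(tr2$ref, "A")
  expect_equal(tr2$alt, "C")
  expect_equal(tr2$pos, 50L)
  # at least one base is always kept
  tr3 <- trim_alleles(10L, "A", "A")
  expect_equal(tr3$ref, "A")
})

test_that("overlapping, adjacent and unsorted BED intervals merge correctly", {
  p <- write_test_bed(c("chr1\t10\t20", "chr1\t15\t30"))
  tg <- read_targets(p)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$start, 11L) # 0-based 10 -> 1-based 11
  expect_equal(tg$end, 30L)

  # adjacent-but-not-overlapping intervals coalesce; oracle = brute-force
  # membership over positions 0..40 in BED coordinates
  p2 <- write_test_bed(c("chr1\t20\t30", "chr1\t10\t20"))
  tg2 <- read_targets(p2)
  expect_equal(nrow(tg2), 1L)
  member_in <- function(pos0) {
    (pos0 >= 10 & pos0 < 20) | (pos0 >= 20 & pos0 < 30)
  }
  member_out <- in_intervals(rep("chr1", 41), 0:40 + 1L, tg2)
  expect_equal(member_out, member_in(0:40))
})

test_that("invalid BED intervals are rejected with their line number", {
  p <- write_test_bed(c("chr1\t10\t20", "chr1\t30\t30"))
  expect_error(read_targets(p), "line 2")
})

test_that("verdict tables round-trip through TSV field for field", {
  b <- simulate_cohort(small_sim(seed = 3))
  res <- screen_and_run(b, n_use = 8, draw_seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(res$verdicts, path)
  back <- read_verdicts(path)
  orig <- as.data.frame(dplyr::ungroup(res$verdicts))
  class(orig) <- "data.frame"
  back <- as.data.frame(back)
  expect_equal(back, orig, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the filtered VCF carries the exact FILTER tags of each verdict", {
  b <- simulate_cohort(small_sim(seed = 3))
  res <- screen_and_run(b, n_use = 8, draw_seed = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_filtered_vcf(res$verdicts, path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  key <- variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
  v <- res$verdicts[match(key, res$verdicts$key), ]
  expect_equal(fix$FILTER == "PASS", v$final_pass)
  # a variant failing only strand bias carries exactly STRANDBIAS
  only_sb <- !v$final_pass & v$base_pass & v$h2m_pass & v$vige_pass &
    v$oxog_pass & !v$strand_pass & v$ffpe_pass & v$consensus_pass
  if (any(only_sb)) {
    expect_true(all(fix$FILTER[only_sb] == "STRANDBIAS"))
  }
  allowed <- c("PASS", "BASE_QC", "H2M", "VIGE", "OXOG", "STRANDBIAS",
               "FFPE", "NOCONSENSUS")
  expect_true(all(unlist(strsplit(fix$FILTER, ";")) %in% allowed))
})
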