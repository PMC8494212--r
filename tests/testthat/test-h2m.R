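make_obs <- function(chrom, pos, control_id, n_alt, depth, label) {
  tibble::tibble(chrom = chrom, pos = pos, control_id = control_id,
                 n_alt = n_alt, n_ref = depth - n_alt, label = label)
}

test_that("pooling keeps het/noise observations and drops error/hom loci", {
  obs <- dplyr::bind_rows(
    make_obs("chr1", 100L, c("a", "b", "c"), c(48, 52, 50), 100, "het"),
    make_obs("chr1", 200L, c("a", "b", "c"), c(99, 100, 98), 100, "hom"),
    make_obs("chr1", 300L, c("a", "b"), c(20, 80), 100, "noise"),
    make_obs("chr1", 300L, "c", 0, 100, "error")
  )
  pooled <- pool_nvafs(obs)
  expect_equal(sort(unique(pooled$pos)), c(100L, 300L))
  expect_equal(sum(pooled$pos == 100L), 3L)
  expect_equal(sum(pooled$pos == 300L), 2L) # the error obs is dropped
  expect_equal(pooled$nvaf[pooled$pos == 100L], c(0.48, 0.52, 0.50))
})

test_that("pooled locus count equals a brute-force recount", {
  set.seed(21)
  controls <- sprintf("c%02d", 1:20)
  grid <- tidyr::expand_grid(pos = seq(100L, 500L, by = 100L),
                             control_id = controls)
  labels <- sample(c("het", "noise", "hom", "error"), nrow(grid),
                   replace = TRUE, prob = c(0.4, 0.1, 0.3, 0.2))
  obs <- make_obs("chr1", grid$pos, grid$control_id,
                  rbinom(nrow(grid), 100, 0.5), 100, labels)
  pooled <- pool_nvafs(obs)
  # oracle: count (locus, control) pairs with a retained label per locus
  keep <- labels %in% c("het", "noise")
  expect_equal(nrow(pooled), sum(keep))
  expect_equal(sort(unique(pooled$pos)),
               sort(unique(grid$pos[keep])))
  # locus indices are dense ranks of position within chromosome
  expect_equal(pooled$locus_idx,
               match(pooled$pos, sort(unique(pooled$pos))))
})

flat_pooled <- function(n_loci, depth, p = 0.5, chrom = "chr1",
                        controls = 4L, start = 1000L) {
  grid <- tidyr::expand_grid(pos = start + 50L * (seq_len(n_loci) - 1L),
                             control_id = sprintf("c%d", seq_len(controls)))
  n_alt <- rbinom(nrow(grid), depth, p)
  pool_nvafs(make_obs(chrom, grid$pos, grid$control_id, n_alt, depth, "het"))
}

test_that("a homogeneous chromosome forms a single segment", {
  set.seed(31)
  pooled <- flat_pooled(40, 800)
  segs <- segment_loci(pooled)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_loci, 40L)
  expect_equal(segs$idx_start, 1L)
  expect_equal(segs$idx_end, 40L)
})

test_that("a level shift is segmented at the true boundary", {
  set.seed(32)
  grid <- tidyr::expand_grid(pos = 1000L + 50L * (0:39),
                             control_id = sprintf("c%d", 1:4))
  p <- ifelse(grid$pos < 1000L + 50L * 20L, 0.5, 0.2) # m ~ 0.01 then ~ 0.30
  obs <- make_obs("chr1", grid$pos, grid$control_id,
                  rbinom(nrow(grid), 500, p), 500, "het")
  pooled <- pool_nvafs(obs)
  segs <- segment_loci(pooled)
  expect_equal(nrow(segs), 2L)
  expect_lte(abs(segs$idx_end[1] - 20L), 2L)

  # oracle: exhaustive single-change-point least-squares scan
  m <- pooled |>
    dplyr::group_by(locus_idx) |>
    dplyr::summarise(m = mean(abs(nvaf - 0.5))) |>
    dplyr::pull(m)
  sse <- function(x) sum((x - mean(x))^2)
  scan <- vapply(5:35, function(k) sse(m[1:k]) + sse(m[(k + 1):40]),
                 numeric(1))
  k_best <- (5:35)[which.min(scan)]
  expect_equal(segs$idx_end[1], k_best)
})

test_that("an empty chromosome yields no segments", {
  pooled <- pool_nvafs(make_obs(character(0), integer(0), character(0),
                                integer(0), integer(0), character(0)))
  segs <- segment_loci(pooled)
  expect_equal(nrow(segs), 0L)
})

test_that("segments partition the ordered locus list deterministically", {
  set.seed(33)
  pooled <- dplyr::bind_rows(flat_pooled(25, 600, chrom = "chr1"),
                             flat_pooled(18, 600, p = 0.3, chrom = "chr2"))
  s1 <- segment_loci(pooled)
  s2 <- segment_loci(pooled)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  for (ch in unique(pooled$chrom)) {
    loci <- sort(unique(pooled$locus_idx[pooled$chrom == ch]))
    seg <- s1[s1$chrom == ch, ]
    covered <- unlist(purrr::map2(seg$idx_start, seg$idx_end, seq))
    expect_equal(sort(covered), loci) # each locus in exactly one segment
  }
})

test_that("the majority-deviant rule flags segments as hard-to-map", {
  set.seed(34)
  # Mendelian segment: nvaf from Binomial(500, 0.5)
  pooled_ok <- flat_pooled(20, 500)
  segs_ok <- flag_h2m(segment_loci(pooled_ok), pooled_ok)
  expect_false(any(segs_ok$h2m))

  # deviant segment: nvafs alternating around 0.2 / 0.8 at depth 500
  grid <- tidyr::expand_grid(pos = 1000L + 50L * (0:19),
                             control_id = sprintf("c%d", 1:4))
  p <- ifelse((grid$pos / 50L) %% 2 == 0, 0.2, 0.8)
  obs <- make_obs("chr1", grid$pos, grid$control_id,
                  rbinom(nrow(grid), 500, p), 500, "noise")
  pooled_bad <- pool_nvafs(obs)
  segs_bad <- flag_h2m(segment_loci(pooled_bad), pooled_bad)
  expect_true(all(segs_bad$h2m))

  # oracle: direct evaluation of the deviance rule per observation
  alpha <- default_config()$h2m$alpha
  lo <- qbinom(alpha / 2, 500, 0.5)
  hi <- qbinom(1 - alpha / 2, 500, 0.5)
  frac <- mean(pooled_bad$n_alt < lo | pooled_bad$n_alt > hi)
  expect_equal(sum(segs_bad$frac_deviant * segs_bad$n_loci * 4) /
                 sum(segs_bad$n_loci * 4), frac, tolerance = 1e-9)
})

test_that("a single deviant locus gives frac_deviant 1 and an H2M flag", {
  pooled <- pool_nvafs(make_obs("chr1", 100L, "c1", 450, 500, "noise"))
  segs <- flag_h2m(segment_loci(pooled), pooled)
  expect_equal(segs$frac_deviant, 1)
  expect_true(segs$h2m)
})

test_that("H2M intervals merge flagged segments and cover their loci", {
  segs <- tibble::tibble(
    segment_id = 1:4,
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    idx_start = c(1L, 11L, 21L, 1L), idx_end = c(10L, 20L, 30L, 5L),
    pos_start = c(100L, 600L, 1100L, 50L),
    pos_end = c(550L, 1050L, 1600L, 90L),
    n_loci = c(10L, 10L, 10L, 5L), baf_hat = 0.4,
    frac_deviant = c(0.9, 0.8, 0.1, 0.7),
    h2m = c(TRUE, TRUE, FALSE, TRUE)
  )
  iv <- h2m_intervals(segs)
  # adjacent flagged segments merge into one interval per chromosome
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start[iv$chrom == "chr1"], 100L)
  expect_equal(iv$end[iv$chrom == "chr1"], 1050L)
  # brute-force containment of every flagged locus position
  expect_true(all(in_intervals(c("chr1", "chr1", "chr2"),
                               c(100L, 1050L, 70L), iv)))
  expect_false(any(in_intervals("chr1", 1100L, iv)))

  expect_equal(nrow(h2m_intervals(dplyr::mutate(segs, h2m = FALSE))), 0L)
})

test_that("injected deviant regions are detected and clean regions are not", {
  # scaled-down version of the detection property (the acceptance suite
  # runs the full replication)
  set.seed(35)
  hits <- 0L
  false_frac <- numeric(0)
  for (rep in 1:20) {
    n <- 60L
    grid <- tidyr::expand_grid(pos = 1000L + 50L * (seq_len(n) - 1L),
                               control_id = sprintf("c%d", 1:6))
    deviant_window <- grid$pos >= 1000L + 50L * 25L &
      grid$pos < 1000L + 50L * 37L # 12 loci
    p <- ifelse(deviant_window,
                0.5 + sample(c(-1, 1), nrow(grid), TRUE) *
                  runif(nrow(grid), 0.15, 0.3),
                0.5)
    obs <- make_obs("chr1", grid$pos, grid$control_id,
                    rbinom(nrow(grid), 300, p), 300, "het")
    pooled <- pool_nvafs(obs)
    iv <- h2m_intervals(flag_h2m(segment_loci(pooled), pooled))
    dev_pos <- unique(grid$pos[deviant_window])
    clean_pos <- unique(grid$pos[!deviant_window])
    if (mean(in_intervals(rep("chr1", 12), dev_pos, iv)) > 0.5) {
      hits <- hits + 1L
    }
    false_frac <- c(false_frac, mean(in_intervals(rep("chr1", 48),
                                                  clean_pos, iv)))
  }
  expect_gte(hits, 19L)
  expect_lte(mean(false_frac), 0.05)
})
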