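test_that("balanced and degenerate tables carry no strand-bias evidence", {
  expect_equal(strand_bias_test(10, 10, 10, 10), 1)
  expect_equal(strand_bias_test(0, 0, 5, 5), 1)
  expect_equal(strand_bias_test(0, 0, 0, 0), 1)
})

test_that("a one-sided alt strand distribution is significant", {
  p <- strand_bias_test(50, 50, 20, 0)
  expect_lt(p, 0.05)
  expect_equal(p, fisher_oracle(50, 50, 20, 0), tolerance = 1e-12)
})

test_that("p-values agree with stats::fisher.test to 1e-12", {
  set.seed(61)
  m <- matrix(sample(0:40, 4 * 300, replace = TRUE), ncol = 4)
  m <- m[m[, 3] + m[, 4] >= 1, ]
  ours <- strand_bias_test(m[, 1], m[, 2], m[, 3], m[, 4])
  ref <- vapply(seq_len(nrow(m)), function(i) {
    stats::fisher.test(matrix(m[i, ], 2, byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the test is invariant to swapping strand labels on both alleles", {
  set.seed(62)
  m <- matrix(sample(0:30, 4 * 100, replace = TRUE), ncol = 4)
  expect_equal(strand_bias_test(m[, 1], m[, 2], m[, 3], m[, 4]),
               strand_bias_test(m[, 2], m[, 1], m[, 4], m[, 3]),
               tolerance = 1e-14)
})

test_that("tumor allele-fraction clustering recovers planted cluster centers", {
  set.seed(63)
  v <- tibble::tibble(
    alt_count = c(rbinom(60, 500, 0.02), rbinom(40, 500, 0.35)),
    depth = 500
  )
  cl <- cluster_tumor_vafs(v)
  td <- tidy(cl$model)
  occupied <- td[!is.na(td$p) & td$n_assigned > 5, ]
  expect_equal(nrow(occupied), 2L)
  expect_lt(abs(min(occupied$p) - 0.02), 0.01)
  expect_lt(abs(max(occupied$p) - 0.35), 0.01)
  # planted memberships are recovered
  expect_equal(length(unique(cl$assignments[1:60])), 1L)
  expect_equal(length(unique(cl$assignments[61:100])), 1L)
})

test_that("degenerate clustering inputs are handled", {
  # all variants at one allele fraction: a single occupied cluster
  v <- tibble::tibble(alt_count = rbinom(50, 400, 0.25), depth = 400)
  set.seed(64)
  cl <- cluster_tumor_vafs(v)
  tab <- table(cl$assignments)
  expect_equal(length(tab[tab > 2]), 1L)
  # empty input: no assignments
  cl0 <- cluster_tumor_vafs(v[0, ])
  expect_equal(length(cl0$assignments), 0L)
  # too few variants: single cluster, no model
  cl1 <- cluster_tumor_vafs(v[1:5, ])
  expect_equal(cl1$assignments, rep(1L, 5))
  expect_null(cl1$model)
})

test_that("clusters characterised by a substitution class are flagged", {
  # cluster 1: 40 variants, 38 in the oxoG class; background class rate
  # beyond the cluster is ~0.15
  set.seed(65)
  mk <- function(n, frac_class) {
    k <- round(n * frac_class)
    pick <- c(sample(c("CA", "GT"), k, TRUE),
              sample(c("AT", "TA", "CG", "GC", "CT", "GA"), n - k, TRUE))
    tibble::tibble(ref = substr(pick, 1, 1), alt = substr(pick, 2, 2),
                   vclass = "SNV")
  }
  v <- dplyr::bind_rows(mk(40, 38 / 40), mk(160, 0.15))
  assignments <- rep(c(1L, 2L), c(40L, 160L))
  fl <- flag_substitution_cluster(v, assignments, "OXOG")
  in_class <- substr(paste0(v$ref, v$alt), 1, 2) %in% c("CA", "GT")
  expect_true(all(fl$flagged[1:40][in_class[1:40]]))
  expect_false(any(fl$flagged[41:200]))
  # oracle: one-sided binomial tail for cluster 1
  bg <- mean(in_class)
  x <- sum(in_class[1:40])
  want <- sum(dbinom(x:40, 40, bg))
  expect_equal(unique(fl$enrich_pvalue[1:40]), want, tolerance = 1e-9)

  # a cluster at exactly the background rate is not characterised
  v2 <- dplyr::bind_rows(mk(40, 0.15), mk(160, 0.15))
  fl2 <- flag_substitution_cluster(v2, assignments, "OXOG")
  expect_false(any(fl2$flagged))

  # no class members anywhere: nothing flagged
  v3 <- dplyr::bind_rows(mk(40, 0), mk(160, 0))
  fl3 <- flag_substitution_cluster(v3, assignments, "OXOG")
  expect_false(any(fl3$flagged))
})

test_that("indels join characterised FFPE clusters but never oxoG", {
  set.seed(66)
  pick <- sample(c("CT", "GA"), 30, TRUE)
  v <- dplyr::bind_rows(
    tibble::tibble(ref = substr(pick, 1, 1), alt = substr(pick, 2, 2),
                   vclass = "SNV"),
    tibble::tibble(ref = c("AT", "A"), alt = c("A", "AG"),
                   vclass = c("DEL", "INS")),
    tibble::tibble(ref = rep("A", 100), alt = rep("C", 100), vclass = "SNV")
  )
  assignments <- rep(c(1L, 2L), c(32L, 100L))
  ff <- flag_substitution_cluster(v, assignments, "FFPE")
  expect_true(all(ff$flagged[31:32])) # the indels in the FFPE cluster
  ox <- flag_substitution_cluster(v, assignments, "OXOG")
  expect_false(any(ox$flagged[31:32]))
})

test_that("planted oxoG clusters are recovered with few mislabels", {
  set.seed(67)
  labelled <- 0L
  total_art <- 0L
  mislabelled <- 0L
  total_clean <- 0L
  for (rep in 1:50) {
    n_art <- 30L
    n_som <- 60L
    pick_art <- sample(c("CA", "GT"), n_art, TRUE)
    keep_art <- runif(n_art) < 0.93 # class purity just above 0.9
    pick_art[!keep_art] <- sample(c("AT", "CT", "GA", "TA"),
                                  sum(!keep_art), TRUE)
    pick_som <- sample(c("CA", "GT", "CT", "GA", "AT", "TA", "CG", "GC"),
                       n_som, TRUE)
    d <- 600
    v <- tibble::tibble(
      ref = substr(c(pick_art, pick_som), 1, 1),
      alt = substr(c(pick_art, pick_som), 2, 2),
      vclass = "SNV",
      alt_count = c(pmax(rbinom(n_art, d, runif(n_art, 0.01, 0.03)), 1),
                    rbinom(n_som, d, 0.30)),
      depth = d,
      ref_fwd = 200, ref_rev = 200, alt_fwd = 5, alt_rev = 5
    )
    out <- call_artifacts(v)
    is_art <- seq_len(n_art + n_som) <= n_art
    truly_class <- substr(c(pick_art, pick_som), 1, 2) %in% c("CA", "GT")
    labelled <- labelled + sum(out$is_oxog[is_art & truly_class])
    total_art <- total_art + sum(is_art & truly_class)
    mislabelled <- mislabelled + sum(out$is_oxog[!is_art])
    total_clean <- total_clean + sum(!is_art)
  }
  expect_gte(labelled / total_art, 0.9)
  expect_lte(mislabelled / total_clean, 0.02)
})

test_that("artifact labels follow the ladder precedence", {
  set.seed(68)
  d <- 500
  pick <- sample(c("CA", "GT"), 30, TRUE)
  v <- dplyr::bind_rows(
    tibble::tibble(ref = substr(pick, 1, 1), alt = substr(pick, 2, 2),
                   vclass = "SNV",
                   alt_count = pmax(rbinom(30, d, 0.02), 1), depth = d,
                   ref_fwd = 245, ref_rev = 245,
                   alt_fwd = NA, alt_rev = 0),
    tibble::tibble(ref = "A", alt = "C", vclass = "SNV",
                   alt_count = rbinom(40, d, 0.3), depth = d,
                   ref_fwd = 175, ref_rev = 175, alt_fwd = 75, alt_rev = 75)
  )
  v$alt_fwd[1:30] <- v$alt_count[1:30] # all alt reads on one strand
  out <- call_artifacts(v)
  # oxoG members that are also strand-biased stay labelled OXOG
  both <- out$is_oxog & out$is_strandbias
  if (any(both)) expect_true(all(out$artifact[both] == "OXOG"))
  expect_true(all(out$artifact[out$is_oxog] == "OXOG"))
})
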