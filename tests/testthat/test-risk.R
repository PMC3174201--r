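# independent oracle: solve the per-genotype disease probabilities on a
# grid refined by bisection over the baseline odds, then form LRs directly
oracle_lrs <- function(or, f, prev) {
  gfreq <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  pen <- function(o0) { o <- o0 * or^(0:2); o / (1 + o) }
  lo <- 1e-12; hi <- 1e12
  for (k in 1:200) {
    mid <- sqrt(lo * hi)
    if (sum(gfreq * pen(mid)) > prev) hi <- mid else lo <- mid
  }
  p <- pen(sqrt(lo * hi))
  (gfreq * p / prev) / (gfreq * (1 - p) / (1 - prev))
}

test_that("genotype LRs from summary statistics match the numeric oracle", {
  expect_equal(unname(genotype_lrs_from_summary(1, 0.3, 0.1)), rep(1, 3),
               tolerance = 1e-9)

  got <- genotype_lrs_from_summary(2, 0.3, 0.1)
  want <- oracle_lrs(2, 0.3, 0.1)
  expect_equal(unname(got), want, tolerance = 1e-6)

  # multiplicative model: LR(ab)^2 ~ LR(aa) * LR(bb)
  expect_equal(got[["1"]]^2 / (got[["0"]] * got[["2"]]), 1, tolerance = 0.02)

  # normalization of both arms
  f <- 0.3; prev <- 0.1
  gfreq <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  # LR(g) * P(g|ctrl) = P(g|case); both must sum to 1 given HWE weights
  expect_error(genotype_lrs_from_summary(-1, 0.3, 0.1))
})

test_that("composite LR multiplies per-locus LRs with sensible edge cases", {
  assoc <- data.frame(rsid = c("rs1", "rs2"), disease = "D",
                      lr0 = c(0.8, 1.0), lr1 = c(1.5, 2.0),
                      lr2 = c(2.5, 0.5),
                      n_studies = 3, n_total = 5000)
  g <- c(rs1 = "ab", rs2 = "bb")
  r <- composite_lr(g, assoc)
  expect_equal(r$composite_lr, 1.5 * 0.5)
  expect_equal(r$log10_lr, log10(0.75))

  # empty locus set
  r0 <- composite_lr(g, assoc[0, ])
  expect_equal(r0$composite_lr, 1)
  expect_equal(r0$log10_lr, 0)

  # cancellation
  assoc2 <- assoc; assoc2$lr1 <- c(2, 0.5)
  expect_equal(composite_lr(c(rs1 = "ab", rs2 = "ab"),
                            assoc2)$composite_lr, 1)

  # missing genotype contributes 1
  r2 <- composite_lr(c(rs1 = "ab"), assoc)
  expect_equal(r2$composite_lr, 1.5)

  # order invariance
  expect_equal(composite_lr(g, assoc[2:1, ])$composite_lr, r$composite_lr)

  # a null locus changes nothing
  null_assoc <- rbind(assoc, data.frame(rsid = "rs3", disease = "D",
                                        lr0 = 1, lr1 = 1, lr2 = 1,
                                        n_studies = 5, n_total = 9000))
  expect_equal(composite_lr(c(g, rs3 = "bb"), null_assoc)$composite_lr,
               r$composite_lr)

  # five-locus product against hand arithmetic
  a5 <- data.frame(rsid = paste0("rs", 1:5), disease = "D",
                   lr0 = 1, lr1 = c(1.2, 0.9, 2, 1.1, 0.7), lr2 = 1,
                   n_studies = 3, n_total = 5000)
  g5 <- setNames(rep("ab", 5), a5$rsid)
  expect_equal(composite_lr(g5, a5)$composite_lr,
               prod(c(1.2, 0.9, 2, 1.1, 0.7)))

  # post-test probability via odds, monotone in the LR
  rpost <- composite_lr(g, assoc, pre_probability = 0.1)
  odds <- 0.1 / 0.9 * rpost$composite_lr
  expect_equal(rpost$post_probability, odds / (1 + odds))
  rbig <- composite_lr(c(rs1 = "bb", rs2 = "ab"), assoc,
                       pre_probability = 0.1)
  expect_gt(rbig$composite_lr, rpost$composite_lr)
  expect_gt(rbig$post_probability, rpost$post_probability)
})

test_that("inclusion rule and duplicate collapsing", {
  assoc <- data.frame(rsid = c("rs1", "rs1", "rs2", "rs3"),
                      disease = "D",
                      lr0 = 1, lr1 = c(2, 3, 2, 2), lr2 = 4,
                      n_studies = c(3, 4, 2, 5),
                      n_total = c(5000, 8000, 5000, 1500))
  q <- qualify_associations(assoc)
  # rs2 fails the >2 studies rule; rs3 fails n_total > 2000;
  # duplicate rs1 keeps the better-powered row
  expect_equal(q$rsid, "rs1")
  expect_equal(q$lr1, 3)
})

test_that("percentiles match the sorting oracle with half-counted ties", {
  cohort <- c(0.5, 0.8, 1.0, 1.0, 1.5, 2.0, 2.2, 3.0, 4.0, 9.0)
  expect_equal(percentile_vs_cohort(10, cohort), 100)
  expect_equal(percentile_vs_cohort(1.0, cohort),
               100 * (2 + 0.5 * 2) / 10)
  for (x in c(0.6, 1.7, 2.5)) {
    expect_equal(percentile_vs_cohort(x, cohort),
                 100 * mean(cohort < x))
  }
  expect_error(percentile_vs_cohort(1, c(1)), "at least 2")

  # self-percentiles of a tie-free cohort are uniform
  set.seed(4)
  vals <- sort(runif(50))
  pct <- vapply(vals, percentile_vs_cohort, numeric(1), cohort_lrs = vals)
  expect_equal(sort(pct), 100 * (seq_len(50) - 0.5) / 50)
})

test_that("cohort scoring runs the same associations per person", {
  assoc <- data.frame(rsid = c("rs1", "rs2"), disease = "D",
                      lr0 = 0.8, lr1 = 1.5, lr2 = 2.5,
                      n_studies = 3, n_total = 5000)
  cohort <- rbind(c("aa", "ab"), c("bb", "bb"), c("ab", NA))
  colnames(cohort) <- c("rs1", "rs2")
  lrs <- cohort_composite_lrs(cohort, assoc)
  expect_equal(lrs, c(0.8 * 1.5, 2.5 * 2.5, 1.5))
})

test_that("parental contribution attributes risk alleles by haplotype", {
  phased <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                       ref = "A", alt = "G",
                       gF = "ab", gM = "ab",
                       gC1 = c("ab", "ab", "bb", "ab"),
                       gC2 = "ab",
                       C1_pat = c("b", "a", "b", NA),
                       C1_mat = c("a", "b", "b", NA),
                       C2_pat = NA, C2_mat = NA,
                       F_t1 = NA, M_t1 = NA,
                       F_contig = 1L, M_contig = 2L, C1_contig = 3L,
                       C2_contig = 4L, stringsAsFactors = FALSE)
  assoc <- data.frame(rsid = paste0("rs", 1:4), chrom = "chr1",
                      pos = c(100L, 200L, 300L, 400L))
  r <- parental_contribution(phased, "C1", assoc)
  # paternal: site1 (b) + site3 hom (b); maternal: site2 + site3; site4
  # unphased het counted separately
  expect_equal(r$paternal, 2L)
  expect_equal(r$maternal, 2L)
  expect_equal(r$unphased, 1L)

  # attribution matches simulator truth exactly
  cfg <- sim_config(chrom_length = 1e6, seed = 61, base_error_rate = 0,
                    compression_regions = no_compression())
  sim <- simulate_quartet(cfg)
  blocks <- decode_states(sim$sites)
  ph <- phase_quartet(sim$sites, blocks)
  sel <- which(!is.na(ph$C1_pat))[1:50]
  assoc2 <- data.frame(rsid = paste0("rs", seq_along(sel)),
                       chrom = "chr1", pos = ph$pos[sel])
  r2 <- parental_contribution(ph, "C1", assoc2)
  pat_truth <- truth_child_allele(sim$truth, "chr1", "C1", "pat")[sel]
  mat_truth <- truth_child_allele(sim$truth, "chr1", "C1", "mat")[sel]
  expect_equal(r2$paternal, sum(pat_truth == "b"))
  expect_equal(r2$maternal, sum(mat_truth == "b"))
})
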