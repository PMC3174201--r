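test_that("crossover windows follow the sharing-relation algebra", {
  blocks <- data.frame(chrom = "chr1",
                       state = c("paternal_identical", "nonidentical"),
                       first_index = c(1L, 11L), last_index = c(10L, 20L),
                       first_pos = c(100L, 1100L),
                       last_pos = c(1000L, 2000L),
                       n_sites = c(10L, 10L))
  w <- extract_crossovers(blocks)
  # children keep sharing nothing maternally; the paternal relation changed
  expect_equal(nrow(w), 1L)
  expect_equal(w$parent, "paternal")
  expect_equal(w$left_bound, 1000L)
  expect_equal(w$right_bound, 1100L)
  expect_equal(w$width, 100L)

  single <- blocks[1, ]
  expect_equal(nrow(extract_crossovers(single)), 0L)

  # identical <-> nonidentical changes both relations: two windows
  both <- blocks
  both$state <- c("identical", "nonidentical")
  w2 <- extract_crossovers(both)
  expect_setequal(w2$parent, c("paternal", "maternal"))

  dup <- blocks
  dup$state <- c("identical", "identical")
  expect_error(extract_crossovers(dup), "invariant")
})

test_that("error-free simulation yields one window per true state boundary", {
  cfg <- sim_config(chrom_length = 4e6, seed = 57, crossover_rate = 2,
                    base_error_rate = 0, n_ancestral = 100,
                    ld_block_strength = 0,
                    compression_regions = no_compression())
  sim <- simulate_quartet(cfg)
  blocks <- decode_states(sim$sites)
  w <- extract_crossovers(blocks, sim$sites)
  # oracle from truth: boundaries of the true per-site state sequence
  ts <- rle(truth_states(sim$truth))
  expected_windows <- 0L
  for (k in seq_len(length(ts$values) - 1L)) {
    b1 <- ts$values[k]; b2 <- ts$values[k + 1L]
    bits <- function(st) switch(st, identical = c(TRUE, TRUE),
                                paternal_identical = c(TRUE, FALSE),
                                maternal_identical = c(FALSE, TRUE),
                                nonidentical = c(FALSE, FALSE))
    expected_windows <- expected_windows + sum(bits(b1) != bits(b2))
  }
  expect_equal(nrow(w), expected_windows)
  # localization: every window brackets a true crossover of its parent
  co <- sim$truth$crossovers
  for (k in seq_len(nrow(w))) {
    hits <- co$parent == w$parent[k] &
      co$position >= w$left_bound[k] & co$position <= w$right_bound[k]
    expect_true(any(hits))
  }
})

test_that("resolution statistics are order statistics of window width", {
  w <- data.frame(width = c(100, 963, 5000))
  expect_equal(resolution_stats(w)$median, 963)
  expect_equal(resolution_stats(data.frame(width = 42))$median, 42)
  expect_error(resolution_stats(data.frame(width = numeric(0))), "no crossover")
})

test_that("hotspot enrichment behaves at the extremes", {
  w <- data.frame(chrom = "chr1", parent = "paternal",
                  left_bound = c(1000L, 5000L), right_bound = c(1200L, 5300L),
                  width = c(200L, 300L))
  callable <- intervals("chr1", 0, 1e5)
  none <- no_compression()
  r0 <- hotspot_enrichment(w, none, callable, n_permutations = 100, seed = 1)
  expect_equal(r0$n_in_hotspot, 0L)
  expect_equal(r0$p_value, 1)

  # hotspots covering all callable territory: saturation, p = 1 (every
  # permutation ties the observed maximum under the add-one estimator)
  all_hs <- intervals("chr1", 0, 1e5, rate = 50)
  r1 <- hotspot_enrichment(w, all_hs, callable, n_permutations = 100, seed = 1)
  expect_equal(r1$n_in_hotspot, 2L)
  expect_equal(r1$p_value, 1)

  # hotspots below the 10 cM/Mbp definition threshold are ignored
  weak <- intervals("chr1", 0, 1e5, rate = 5)
  r2 <- hotspot_enrichment(w, weak, callable, n_permutations = 100, seed = 1)
  expect_equal(r2$n_in_hotspot, 0L)
})

test_that("chance expectation matches the binomial oracle", {
  w <- data.frame(chrom = "chr1", parent = "paternal",
                  left_bound = 500L, right_bound = 501L, width = 1L)
  hs <- intervals("chr1", 400, 500, rate = 20)
  callable <- intervals("chr1", 0, 1000)
  r <- hotspot_enrichment(w, hs, callable, n_permutations = 10000, seed = 7)
  # a width-1 window placed uniformly on 1000 bp hits a 100 bp hotspot ~10%
  expect_lt(abs(r$expected_by_chance - 0.1), 0.02)
  expect_equal(r$genome_fraction_in_hotspots, 0.1)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(33)
  callable <- intervals("chr1", 0, 2e5)
  hs <- intervals("chr1", seq(0, 1.9e5, 2e4), seq(0, 1.9e5, 2e4) + 2000,
                  rate = 20)
  n_rep <- 150
  pvals <- replicate(n_rep, {
    starts <- floor(runif(5) * (2e5 - 500))
    w <- data.frame(chrom = "chr1", parent = "paternal",
                    left_bound = starts + 1L, right_bound = starts + 500L,
                    width = 499L)
    hotspot_enrichment(w, hs, callable, n_permutations = 99,
                       seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    mc_tol <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals <= alpha), alpha + mc_tol)
  }
})

test_that("modifier-locus haplotypes are read off the phase contigs", {
  phased <- data.frame(chrom = "chr1", pos = c(1000L, 18000L),
                       ref = c("C", "T"), alt = c("T", "C"),
                       gF = c("ab", "ab"), gM = c("ab", "bb"),
                       gC1 = c("ab", "ab"), gC2 = c("aa", "ab"),
                       C1_pat = c("a", "b"), C1_mat = c("b", "a"),
                       C2_pat = NA, C2_mat = NA,
                       F_t1 = c("a", "b"), M_t1 = c("b", "b"),
                       F_contig = 1L, M_contig = 2L,
                       C1_contig = 3L, C2_contig = 4L,
                       stringsAsFactors = FALSE)
  markers <- data.frame(chrom = "chr1", pos = c(1000L, 18000L))
  out <- annotate_recomb_modifier_haplotypes(phased, markers)
  # child C1 phased: [C, C] on the paternal copy (ref at 1, alt at 2)
  expect_equal(out$C1$status, "phased")
  expect_equal(unname(out$C1$haplotypes[1, ]), c("C", "C"))
  expect_equal(unname(out$C1$haplotypes[2, ]), c("T", "T"))
  # mother het at site 1, hom at site 2: phased via transmitted allele
  expect_equal(out$M$status, "phased")
  expect_equal(unname(out$M$haplotypes[1, ]), c("T", "C"))
  # child C2 heterozygous but unphased at site 2: ambiguous
  expect_equal(out$C2$status, "ambiguous")

  # homozygous at both markers: single haplotype, no phase needed
  hom <- phased
  hom$gC2 <- c("aa", "bb")
  out2 <- annotate_recomb_modifier_haplotypes(hom, markers)
  expect_equal(out2$C2$status, "homozygous")
  expect_equal(unname(out2$C2$haplotypes[1, ]), c("C", "C"))

  # absent marker
  out3 <- annotate_recomb_modifier_haplotypes(
    phased, data.frame(chrom = "chr1", pos = c(1000L, 99999L)))
  expect_equal(out3$C1$status, "missing")
})
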