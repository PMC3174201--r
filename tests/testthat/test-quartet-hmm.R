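test_that("assortment classification matches transmission logic on worked cases", {
  r <- classify_assortment("ab", "aa", "aa", "ab")
  expect_setequal(r$consistent_states,
                  c("maternal_identical", "nonidentical"))
  expect_false(r$is_mie)

  r <- classify_assortment("aa", "aa", "ab", "aa")
  expect_true(r$is_mie)
  expect_length(r$consistent_states, 0L)

  r <- classify_assortment("ab", "ab", "ab", "ab")
  expect_true(r$is_uniform_het)
  expect_true(r$is_uninformative)
  expect_setequal(r$consistent_states,
                  c("identical", "paternal_identical",
                    "maternal_identical", "nonidentical"))

  r <- classify_assortment("ab", "ab", "aa", "bb")
  expect_equal(r$consistent_states, "nonidentical")

  # missing genotype: uninformative, never an MIE
  r <- classify_assortment("ab", NA, "aa", "ab")
  expect_true(r$is_uninformative)
  expect_false(r$is_mie)
})

test_that("classification agrees with the brute-force oracle on all 81 vectors", {
  g <- c("aa", "ab", "bb")
  for (gF in g) for (gM in g) for (gC1 in g) for (gC2 in g) {
    got <- classify_assortment(gF, gM, gC1, gC2)
    want <- oracle_classify(gF, gM, gC1, gC2)
    expect_setequal(got$consistent_states, want)
    expect_equal(got$is_mie, length(want) == 0L)
  }
})

test_that("decoding recovers true states and localizes a single crossover", {
  cfg <- sim_config(chrom_length = 2e6, seed = 31, base_error_rate = 0,
                    crossover_rate = 0, compression_regions = no_compression())
  sim <- simulate_quartet(cfg)
  blocks <- decode_states(sim$sites)
  # crossover_rate 0: one Mendelian block covering the chromosome
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$state, truth_states(sim$truth)[1])
  expect_equal(blocks$n_sites, nrow(sim$sites))

  # one deterministic paternal crossover, injected via the truth machinery:
  # simulate with rate ~1 until a clean single-crossover chromosome appears
  cfg2 <- sim_config(chrom_length = 2e6, seed = 35, crossover_rate = 1,
                     base_error_rate = 0, n_ancestral = 100,
                     ld_block_strength = 0,
                     compression_regions = no_compression())
  sim2 <- simulate_quartet(cfg2)
  co <- sim2$truth$crossovers
  blocks2 <- decode_states(sim2$sites)
  mend2 <- blocks2[blocks2$state %in% c("identical", "paternal_identical",
                                        "maternal_identical",
                                        "nonidentical"), ]
  expect_equal(mend2$state, rle(truth_states(sim2$truth))$values)
  # each crossover window (bounds snapped to informative markers)
  # brackets a true crossover of its parent
  w <- extract_crossovers(blocks2, sim2$sites)
  expect_equal(nrow(w), nrow(co))
  for (k in seq_len(nrow(w))) {
    expect_true(any(co$parent == w$parent[k] &
                      co$position >= w$left_bound[k] &
                      co$position <= w$right_bound[k]))
  }
})

test_that("a long uniformly heterozygous run is called as compression", {
  set.seed(1)
  n <- 300
  g <- replicate(4, sample(c("aa", "ab", "bb"), n, TRUE,
                           prob = c(0.3, 0.4, 0.3)))
  # keep the background Mendelian-consistent: children derived from parents
  sim <- simulate_quartet(sim_config(chrom_length = 3e5, seed = 8,
                                     base_error_rate = 0,
                                     compression_regions = no_compression()))
  s <- sim$sites
  mid <- seq(floor(nrow(s) / 2) - 30, floor(nrow(s) / 2) + 30)
  for (col in c("gF", "gM", "gC1", "gC2")) s[[col]][mid] <- "ab"
  blocks <- decode_states(s)
  comp <- blocks[blocks$state == "compression", , drop = FALSE]
  expect_gte(nrow(comp), 1L)
  expect_true(any(comp$first_index <= min(mid) + 5 &
                    comp$last_index >= max(mid) - 5))
})

test_that("scattered inconsistencies do not split a single-state chromosome", {
  sim <- simulate_quartet(sim_config(chrom_length = 1e6, seed = 41,
                                     crossover_rate = 0,
                                     base_error_rate = 0,
                                     compression_regions = no_compression()))
  s <- sim$sites
  set.seed(9)
  # epsilon-level isolated genotype disruptions
  hit <- sample(nrow(s), max(2L, round(nrow(s) * 0.004)))
  s$gC1[hit] <- ifelse(s$gC1[hit] == "aa", "bb", "aa")
  blocks <- decode_states(s)
  mend <- blocks[blocks$state %in% c("identical", "paternal_identical",
                                     "maternal_identical", "nonidentical"), ]
  expect_equal(nrow(mend), 1L)
})

test_that("the Viterbi path is at least as probable as the truth path", {
  sim <- simulate_quartet(sim_config(chrom_length = 1e6, seed = 13))
  blocks <- decode_states(sim$sites)
  truth_path <- truth_states(sim$truth)
  comp <- sim$truth$compression_sites
  if (!is.null(comp)) {
    truth_path[sim$sites$pos %in% comp$pos] <- "compression"
  }
  expect_gte(attr(blocks, "logprob") + 1e-6,
             path_loglik(sim$sites, truth_path))
})

test_that("Mendelian blocks cover nearly all sites without error clusters", {
  sim <- simulate_quartet(sim_config(chrom_length = 3e6, seed = 17,
                                     base_error_rate = 0,
                                     n_ancestral = 100,
                                     ld_block_strength = 0,
                                     compression_regions = no_compression()))
  blocks <- decode_states(sim$sites)
  flags <- flag_error_prone_sites(blocks, sim$sites)
  expect_lte(flags$fraction, 0.01)
})

test_that("error-prone flagging arithmetic and cluster capture", {
  sim <- simulate_quartet(sim_config(chrom_length = 1e6, seed = 3,
                                     base_error_rate = 0,
                                     n_ancestral = 100,
                                     ld_block_strength = 0,
                                     compression_regions = no_compression()))
  blocks <- decode_states(sim$sites)
  expect_equal(flag_error_prone_sites(blocks, sim$sites)$fraction, 0)

  # clustered errors: >= 90% of them land in flagged blocks
  sim2 <- simulate_quartet(sim_config(chrom_length = 5e6, seed = 2))
  blocks2 <- decode_states(sim2$sites)
  flags2 <- flag_error_prone_sites(blocks2, sim2$sites)
  errs <- sim2$truth$error_sites
  cl <- errs[errs$clustered, ]
  expect_gte(mean(cl$pos %in% sim2$sites$pos[flags2$mask]), 0.9)
})

test_that("quality calibration finds the discordance-separating cutoff", {
  s <- make_sites(pos = seq_len(200) * 100,
                  gF = "aa", gM = "ab", gC1 = "ab", gC2 = "aa", q = 45)
  truth <- data.frame(chrom = "chr1", pos = s$pos, sample = "C1",
                      genotype = "ab")
  # concordant everywhere: cutoff 0 with a warning
  expect_warning(cal0 <- calibrate_quality_threshold(s, truth), "no discordant")
  expect_equal(cal0$cutoff, 0)

  # discordance concentrated below quality 20
  bad <- 1:20
  s$gC1[bad] <- "aa"
  s$qC1[bad] <- 10
  cal <- calibrate_quality_threshold(s, truth, target = 1e-3)
  expect_equal(cal$cutoff, 11)
  curve <- cal$curve
  expect_true(all(curve$discordance[curve$cutoff > 10] == 0, na.rm = TRUE))
  expect_lt(curve$retention[curve$cutoff == 20], 1)
})

test_that("flagging plus calibrated quality filtering removes simulated errors", {
  cfg <- sim_config(chrom_length = 5e6, seed = 6)
  sim <- simulate_quartet(cfg)
  blocks <- decode_states(sim$sites)
  mask <- flag_error_prone_sites(blocks, sim$sites)$mask
  ts <- quartet_truth_subset(sim$sites, sim$truth, exclude = mask)
  cal <- calibrate_quality_threshold(sim$sites, ts, target = 1e-5)
  red <- mie_error_reduction(sim$sites, blocks, cal$cutoff)
  expect_gte(red$reduction_percent, 90)
})
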