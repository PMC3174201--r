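test_that("rare/novel partition is exhaustive and mutually exclusive", {
  catalog <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                        ref = "A", alt = "G",
                        freq = c(0.30, 0.02, 0.50))
  v <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                  ref = "A", alt = "G")
  out <- filter_rare_novel(v, catalog)
  expect_equal(out$class, c("common", "rare", "common", "novel"))

  # 10-variant toy set against exhaustive set logic
  set.seed(7)
  freqs <- runif(6)
  cat10 <- data.frame(chrom = "chr1", pos = 1:6 * 10, ref = "C", alt = "T",
                      freq = freqs)
  v10 <- data.frame(chrom = "chr1", pos = 1:10 * 10, ref = "C", alt = "T")
  out10 <- filter_rare_novel(v10, cat10)
  want <- ifelse(v10$pos > 60, "novel",
                 ifelse(freqs < 0.05, "rare", "common"))
  expect_equal(out10$class, want)
  expect_true(all(table(out10$class)[unique(out10$class)] > 0))
  expect_equal(sum(out10$class %in% c("common", "rare", "novel")), 10L)
})

test_that("consequence annotation covers the coding and splice taxonomy", {
  # gene on chr1, + strand: exon1 101-160 (CDS 121-160), intron,
  # exon2 201-260 (CDS 201-240, then 3' UTR)
  models <- data.frame(
    gene = "G1", transcript = "T1", chrom = "chr1", strand = "+",
    feature = c("exon", "exon", "CDS", "CDS"),
    start = c(101L, 201L, 121L, 201L),
    end = c(160L, 260L, 160L, 240L))
  base <- paste(rep("ACGT", 100), collapse = "")
  # build a reference whose CDS begins ATG and contains a TAC codon we can
  # break: place a custom sequence
  ref_chars <- strsplit(base, "")[[1]]
  cds_seq <- paste0("ATG", strsplit("TACGGATTCAAGCTTGACCCAGTAAGGTGCCTAATG", "")[[1]][1:36] |> paste(collapse = ""))
  ref_chars[121:160] <- strsplit(substr(paste0(cds_seq, "A"), 1, 40), "")[[1]]
  reference <- list(chr1 = paste(ref_chars, collapse = ""))

  # codon 2 is TAC (Tyr): 124-126. C->G at 126 gives TAG = stop
  v <- list(chrom = "chr1", pos = 126L, ref = substr(reference$chr1, 126, 126),
            alt = "G")
  out <- annotate_consequence(v, models, reference)
  expect_equal(out$category, "nonsense")
  expect_equal(out$gene, "G1")

  # synonymous: TAC -> TAT (both Tyr)
  v2 <- list(chrom = "chr1", pos = 126L, ref = "C", alt = "T")
  expect_equal(annotate_consequence(v2, models, reference)$category,
               "synonymous")

  # missense: TAC -> GAC (Asp)
  v3 <- list(chrom = "chr1", pos = 124L, ref = "T", alt = "G")
  expect_equal(annotate_consequence(v3, models, reference)$category,
               "missense")

  # splice acceptor: 2 intronic bases before exon2 start on + strand
  v4 <- list(chrom = "chr1", pos = 199L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v4, models, reference)$category,
               "splice_3prime")
  v4b <- list(chrom = "chr1", pos = 200L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v4b, models, reference)$category,
               "splice_3prime")

  # splice donor after exon1 end
  v5 <- list(chrom = "chr1", pos = 161L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v5, models, reference)$category,
               "splice_5prime")

  # deep intron
  v6 <- list(chrom = "chr1", pos = 180L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v6, models, reference)$category,
               "intronic")

  # 5' UTR (exonic, before CDS on + strand) and 3' UTR
  v7 <- list(chrom = "chr1", pos = 110L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v7, models, reference)$category, "utr5")
  v8 <- list(chrom = "chr1", pos = 250L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v8, models, reference)$category, "utr3")

  # coding indels: 4 bp deletion shifts frame; 3 bp does not
  v9 <- list(chrom = "chr1", pos = 130L, ref = "ACGTA", alt = "A")
  expect_equal(annotate_consequence(v9, models, reference)$category,
               "frameshift_indel")
  v10 <- list(chrom = "chr1", pos = 130L, ref = "ACGT", alt = "A")
  expect_equal(annotate_consequence(v10, models, reference)$category,
               "coding_indel")

  # intergenic
  v11 <- list(chrom = "chr1", pos = 350L, ref = "A", alt = "C")
  expect_equal(annotate_consequence(v11, models, reference)$category,
               "intergenic")
})

test_that("minus-strand codons are evaluated on the coding strand", {
  # gene on -, single exon 101-130, CDS 101-130; coding sequence is the
  # reverse complement of the genomic window
  models <- data.frame(gene = "G2", transcript = "T2", chrom = "chr1",
                       strand = "-", feature = c("exon", "CDS"),
                       start = 101L, end = 130L)
  ref_chars <- rep("A", 200)
  # genomic 101-130 reverse-complement must start with ATG: genomic end
  # must be CAT reading backwards
  ref_chars[128:130] <- c("C", "A", "T")
  # next codon (genomic 125-127) revcomp: choose GTA -> revcomp TAC (Tyr)
  ref_chars[125:127] <- c("G", "T", "A")
  reference <- list(chr1 = paste(ref_chars, collapse = ""))
  # mutate genomic 125 (A on coding strand at codon2 pos3): G->C makes
  # codon TAG (stop)
  v <- list(chrom = "chr1", pos = 125L, ref = "G", alt = "C")
  out <- annotate_consequence(v, models, reference)
  expect_equal(out$category, "nonsense")
  expect_equal(out$ref_codon, "TAC")
  expect_equal(out$alt_codon, "TAG")
})

test_that("Fitch counts match hand cases and the exhaustive oracle", {
  tree4 <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  col <- c(s1 = "A", s2 = "A", s3 = "T", s4 = "T")
  r <- fitch_rate(col, tree4)
  expect_equal(r$substitutions, 1L)
  expect_equal(r$span, 6)
  expect_equal(r$rate, 1 / 6)

  expect_equal(fitch_rate(c(s1 = "A", s2 = "A", s3 = "A", s4 = "A"),
                          tree4)$substitutions, 0L)

  # gapped species are pruned with their branches
  r2 <- fitch_rate(c(s1 = "A", s2 = "-", s3 = "T", s4 = "T"), tree4)
  expect_equal(r2$substitutions, 1L)
  expect_lt(r2$span, 6)

  expect_true(is.na(fitch_rate(c(s1 = "A", s2 = "-", s3 = "-", s4 = "-"),
                               tree4)$substitutions))

  # brute force: minimum substitutions over all internal labelings
  brute_fitch <- function(col, tree) {
    tr <- ape::reorder.phylo(tree, "postorder")
    states <- unique(col)
    n_tip <- length(tr$tip.label)
    internal <- unique(tr$edge[, 1])
    combos <- expand.grid(rep(list(states), length(internal)),
                          stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      lab <- c(col[tr$tip.label], setNames(unlist(combos[r, ]), internal))
      names(lab)[seq_len(n_tip)] <- seq_len(n_tip)
      cost <- sum(lab[as.character(tr$edge[, 1])] !=
                    lab[as.character(tr$edge[, 2])])
      best <- min(best, cost)
    }
    best
  }
  set.seed(3)
  for (k in 1:12) {
    ntax <- sample(4:8, 1)
    tr <- ape::rtree(ntax)
    col <- setNames(sample(c("A", "C", "G", "T"), ntax, TRUE),
                    tr$tip.label)
    expect_equal(fitch_rate(col, tr)$substitutions, brute_fitch(col, tr))
    # bound from the spec: (distinct residues - 1) * (taxa - 1)
    expect_lte(fitch_rate(col, tr)$substitutions,
               (length(unique(col)) - 1) * (ntax - 1))
  }
})

test_that("rubric scoring assembles configured fields and withholds missing", {
  f5 <- list(inheritance = "Incomplete dominant", onset_earliest = 4,
             onset_median = 4, severity = 4, actionability = 5,
             lifetime_risk = 2, variant_pathogenicity = 7)
  r <- score_variant_rubric(f5)
  expect_true(r$complete)
  expect_equal(r$scores$onset_earliest, 4)
  expect_equal(r$scores$severity, 4)
  expect_equal(r$scores$actionability, 5)
  expect_equal(r$scores$lifetime_risk, 2)
  expect_equal(r$scores$variant_pathogenicity, 7)

  mthfr <- list(inheritance = "AR", onset_earliest = 1, onset_median = 1,
                severity = 1, actionability = 6, lifetime_risk = 2,
                variant_pathogenicity = 7)
  r2 <- score_variant_rubric(mthfr)
  expect_equal(r2$scores$actionability, 6)
  expect_equal(r2$scores$variant_pathogenicity, 7)

  # "variable" lifetime risk is a legal label
  habp2 <- list(inheritance = "AD", onset_earliest = 4, onset_median = 4,
                severity = 1, actionability = 5, lifetime_risk = "variable",
                variant_pathogenicity = 7)
  expect_true(score_variant_rubric(habp2)$complete)

  r3 <- score_variant_rubric(list())
  expect_false(r3$complete)
  expect_true("severity" %in% r3$withheld)

  # out-of-scale value is withheld, not clamped
  bad <- f5; bad$severity <- 11
  expect_true("severity" %in% score_variant_rubric(bad)$withheld)
})

test_that("compound heterozygosity requires rare hits on both haplotypes", {
  phased <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                       ref = "A", alt = "G", gF = "ab", gM = "ab",
                       gC1 = "ab", gC2 = "ab",
                       C1_pat = c("b", "a", "b", "a"),
                       C1_mat = c("a", "b", "a", "a"),
                       C2_pat = NA, C2_mat = NA, F_t1 = NA, M_t1 = NA,
                       F_contig = 1L, M_contig = 2L, C1_contig = 3L,
                       C2_contig = 4L, stringsAsFactors = FALSE)
  vg <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                   gene = c("GENE1", "GENE1", "GENE2", "GENE2"))
  out <- compound_heterozygous(phased, "C1", vg)
  expect_true(out$compound_het[out$gene == "GENE1"])
  expect_false(out$compound_het[out$gene == "GENE2"])
})
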