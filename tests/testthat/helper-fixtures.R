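# shared fixture builders for the test suite

# a minimal quartet_sites table with uniform metadata
make_sites <- function(pos, gF, gM, gC1, gC2, chrom = "chr1",
                       q = 40, ref = "A", alt = "G") {
  quartet_sites(chrom = chrom, pos = pos, ref = ref, alt = alt,
                gF = gF, gM = gM, gC1 = gC1, gC2 = gC2,
                qF = q, qM = q, qC1 = q, qC2 = q)
}

# write a small 4-sample VCF and return its path
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           samples = c("FA", "MO", "K1", "K2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t")))
  writeLines(c(header, records), path)
  path
}

# independent brute-force assortment oracle (coded differently from the
# implementation): enumerates explicit parental haplotype vectors and
# index choices, with the uniform-het-is-uninformative convention
oracle_classify <- function(gF, gM, gC1, gC2) {
  pair_of <- list(aa = c("a", "a"), ab = c("a", "b"), bb = c("b", "b"))
  fa <- pair_of[[gF]]; mo <- pair_of[[gM]]
  states <- character(0)
  sharing <- list(identical = c(TRUE, TRUE),
                  paternal_identical = c(TRUE, FALSE),
                  maternal_identical = c(FALSE, TRUE),
                  nonidentical = c(FALSE, FALSE))
  for (st in names(sharing)) {
    found <- FALSE
    for (p1 in 1:2) for (m1 in 1:2) for (p2 in 1:2) for (m2 in 1:2) {
      if ((p1 == p2) != sharing[[st]][1]) next
      if ((m1 == m2) != sharing[[st]][2]) next
      c1 <- paste(sort(c(fa[p1], mo[m1])), collapse = "")
      c2 <- paste(sort(c(fa[p2], mo[m2])), collapse = "")
      if (c1 == gC1 && c2 == gC2) found <- TRUE
    }
    if (found) states <- c(states, st)
  }
  if (all(c(gF, gM, gC1, gC2) == "ab")) states <- names(sharing)
  states
}

# truth inheritance state per site from a sim_truth (single chromosome)
truth_states <- function(truth, chrom = "chr1") {
  trm <- truth$transmitted[[chrom]]
  pat_same <- trm$FC1 == trm$FC2
  mat_same <- trm$MC1 == trm$MC2
  ifelse(pat_same & mat_same, "identical",
         ifelse(pat_same, "paternal_identical",
                ifelse(mat_same, "maternal_identical", "nonidentical")))
}

# child truth alleles ("a"/"b") on the requested parental haplotype
truth_child_allele <- function(truth, chrom, child = "C1",
                               parent = c("pat", "mat")) {
  parent <- match.arg(parent)
  f <- truth$founders[[chrom]]
  trm <- truth$transmitted[[chrom]]
  key <- paste0(if (parent == "pat") "F" else "M", child)
  rows <- (if (parent == "pat") 0L else 2L) + trm[[key]]
  c("a", "b")[f[cbind(rows, seq_len(ncol(f)))] + 1L]
}

no_compression <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             rate = numeric(0))
}
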