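# Readers/writers for the external formats the pipeline touches.
#
# Coordinate conventions: VCF-derived site tables are 1-based; interval logic
# (BED, hotspots, error clusters, compression regions) is 0-based half-open.
# These readers/writers are the only places the two conventions meet.

#' Read a four-sample VCF into a quartet site table
#'
#' Samples are mapped by name, not column order. Biallelic SNV and indel
#' records are kept; multi-allelic records are skipped (their count is
#' attached as the `n_multiallelic_skipped` attribute). Missing genotypes
#' (`./.`) are preserved as `NA`.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param sample_order character(4): names of father, mother, child 1,
#'   child 2 as they appear in the VCF header.
#' @return a [quartet_sites] data frame sorted by (chrom, pos).
#' @export
read_quartet_vcf <- function(path, sample_order) {
  stopifnot(length(sample_order) == 4L)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  missing_samples <- setdiff(sample_order, samples)
  if (length(missing_samples))
    stop("sample(s) not in VCF: ", paste(missing_samples, collapse = ", "))
  fix <- v@fix
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0)
    warning(n_multi, " multi-allelic record(s) skipped")
  keep <- !multi
  fmt <- gt[keep, "FORMAT", drop = TRUE]
  parse_one <- function(sample) {
    cells <- gt[keep, sample, drop = TRUE]
    gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                     function(f) match("GT", f), integer(1))
    gq_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                     function(f) match("GQ", f), integer(1))
    parts <- strsplit(cells, ":", fixed = TRUE)
    gts <- mapply(function(p, i) if (is.na(i) || length(p) < i) NA_character_
                  else p[i], parts, gt_idx)
    gqs <- mapply(function(p, i) if (is.na(i) || length(p) < i) NA_character_
                  else p[i], parts, gq_idx)
    code <- gsub("|", "/", gts, fixed = TRUE)
    code <- vapply(strsplit(code, "/", fixed = TRUE), function(a) {
      if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a))))
        return(NA_character_)
      n_alt <- sum(as.integer(a))
      GENOTYPES[n_alt + 1L]
    }, character(1))
    list(gt = unname(code), gq = suppressWarnings(as.numeric(gqs)))
  }
  pf <- parse_one(sample_order[1]); pm <- parse_one(sample_order[2])
  p1 <- parse_one(sample_order[3]); p2 <- parse_one(sample_order[4])
  out <- quartet_sites(chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       ref = fix[keep, "REF"], alt = alt[keep],
                       gF = pf$gt, gM = pm$gt, gC1 = p1$gt, gC2 = p2$gt,
                       qF = pf$gq, qM = pm$gq, qC1 = p1$gq, qC2 = p2$gq)
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Read a BED3/BED4 file as 0-based half-open intervals
#'
#' The optional 4th column is parsed as a numeric payload (for hotspot files,
#' the interval's recombination rate in cM/Mbp).
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start` (0-based inclusive), `end`
#'   (exclusive) and `rate` (NA when absent).
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), rate = numeric(0)))
  fields <- strsplit(lines, "[ \t]+")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L))
    stop("BED line ", which(n_col < 3L)[1], ": fewer than 3 columns")
  start <- as.integer(vapply(fields, `[`, character(1), 2))
  end <- as.integer(vapply(fields, `[`, character(1), 3))
  bad <- is.na(start) | is.na(end) | start >= end | start < 0
  if (any(bad))
    stop("BED line ", which(bad)[1], ": invalid interval (need 0 <= start < end)")
  rate <- rep(NA_real_, length(lines))
  has4 <- n_col >= 4L
  rate[has4] <- suppressWarnings(as.numeric(
    vapply(fields[has4], `[`, character(1), 4)))
  data.frame(chrom = vapply(fields, `[`, character(1), 1),
             start = start, end = end, rate = rate)
}

#' Construct an interval table programmatically
#' @param chrom,start,end 0-based half-open intervals.
#' @param rate optional numeric payload.
#' @export
intervals <- function(chrom, start, end, rate = NA_real_) {
  stopifnot(all(start >= 0), all(start < end))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), rate = as.numeric(rate))
}

# 1-based positions falling inside 0-based half-open intervals (same chrom)
pos_in_intervals <- function(chrom, pos, iv) {
  hit <- logical(length(pos))
  if (nrow(iv) == 0L) return(hit)
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (chrom == iv$chrom[k] & pos > iv$start[k] & pos <= iv$end[k])
  }
  hit
}

.vcf_gt_code <- function(allele) c(a = "0", b = "1")[allele]

#' Write phased quartet genotypes as VCF
#'
#' Phased genotypes use the `|` separator with a `PS` (phase set) FORMAT tag
#' equal to the phase-contig id; unphased genotypes keep `/`. For the
#' children the first allele is paternal and the second maternal; for the
#' parents the first allele is the one transmitted to child 1 within the
#' parent's phase contig.
#'
#' @param phased a `phased_quartet` data frame from [phase_quartet()].
#' @param path output path (plain text).
#' @export
write_phased_vcf <- function(phased, path) {
  p <- phased
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     "F\tM\tC1\tC2"))
  enc_child <- function(pat, mat, g, contig) {
    ifelse(!is.na(pat) & !is.na(mat),
           {
             if (any(!is.na(pat) & is.na(contig)))
               stop("phased site without a phase-contig id")
             paste0(.vcf_gt_code(pat), "|", .vcf_gt_code(mat), ":", contig)
           },
           ifelse(is.na(g), "./.",
                  c(aa = "0/0", ab = "0/1", bb = "1/1")[g]))
  }
  fC1 <- enc_child(p$C1_pat, p$C1_mat, p$gC1, p$C1_contig)
  fC2 <- enc_child(p$C2_pat, p$C2_mat, p$gC2, p$C2_contig)
  enc_parent <- function(t1, t2, g, contig) {
    # parent hap1 = transmitted-to-C1; hap2 = the remaining allele
    other <- function(tr, g) {
      pair <- c(aa = "aa", ab = "ab", bb = "bb")[g]
      ifelse(tr == "a" & pair == "ab", "b",
             ifelse(tr == "b" & pair == "ab", "a", tr))
    }
    ifelse(!is.na(t1) & !is.na(g),
           paste0(.vcf_gt_code(t1), "|", .vcf_gt_code(other(t1, g)),
                  ":", contig),
           ifelse(is.na(g), "./.",
                  c(aa = "0/0", ab = "0/1", bb = "1/1")[g]))
  }
  fF <- enc_parent(p$F_t1, NULL, p$gF, p$F_contig)
  fM <- enc_parent(p$M_t1, NULL, p$gM, p$M_contig)
  body <- paste(p$chrom, p$pos, ".", p$ref, p$alt, ".", ".", ".", "GT:PS",
                fF, fM, fC1, fC2, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a phased quartet VCF written by [write_phased_vcf()]
#'
#' @param path VCF path.
#' @return data frame with genotype, child paternal/maternal alleles, parent
#'   transmitted alleles and phase-contig ids (NA where unphased).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  fix <- v@fix
  dec <- function(cells) {
    parts <- strsplit(cells, ":", fixed = TRUE)
    g <- vapply(parts, `[`, character(1), 1)
    ps <- vapply(parts, function(x) if (length(x) >= 2) x[2] else
      NA_character_, character(1))
    phased <- grepl("|", g, fixed = TRUE)
    al <- strsplit(gsub("[|/]", " ", g), " ")
    code <- function(x) ifelse(x == "0", "a", ifelse(x == "1", "b", NA))
    h1 <- code(vapply(al, `[`, character(1), 1))
    h2 <- code(vapply(al, `[`, character(1), 2))
    gcode <- ifelse(is.na(h1) | is.na(h2), NA_character_,
                    paste0(pmin(h1, h2), pmax(h1, h2)))
    list(g = gcode, h1 = ifelse(phased, h1, NA),
         h2 = ifelse(phased, h2, NA),
         contig = ifelse(phased, suppressWarnings(as.integer(ps)), NA))
  }
  dF <- dec(gt[, "F"]); dM <- dec(gt[, "M"])
  d1 <- dec(gt[, "C1"]); d2 <- dec(gt[, "C2"])
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             gF = dF$g, gM = dM$g, gC1 = d1$g, gC2 = d2$g,
             F_t1 = dF$h1, M_t1 = dM$h1,
             C1_pat = d1$h1, C1_mat = d1$h2,
             C2_pat = d2$h1, C2_mat = d2$h2,
             F_contig = dF$contig, M_contig = dM$contig,
             C1_contig = d1$contig, C2_contig = d2$contig,
             stringsAsFactors = FALSE)
}
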