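# Rare/novel variant filtering, consequence annotation against gene models,
# Fitch-parsimony evolutionary rates on alignment columns, and clinical
# rubric scoring.

#' Partition variants into common / rare / novel
#'
#' Novel variants are absent from both the frequency catalog and the
#' known-variant catalog; rare variants are present with population
#' frequency below the cutoff; the rest are common. The partition is
#' exhaustive and mutually exclusive.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param freq_catalog data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `freq`.
#' @param known_catalog data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (e.g. a dbSNP extract); defaults to the frequency catalog.
#' @param rare_cutoff frequency below which a cataloged variant is rare.
#' @return `variants` with added `freq` (NA if uncataloged) and `class`
#'   in {"common", "rare", "novel"}.
#' @export
filter_rare_novel <- function(variants, freq_catalog,
                              known_catalog = freq_catalog,
                              rare_cutoff = 0.05) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  f_idx <- match(key(variants), key(freq_catalog))
  known <- key(variants) %in% key(known_catalog) | !is.na(f_idx)
  freq <- freq_catalog$freq[f_idx]
  cls <- ifelse(!known, "novel",
                ifelse(!is.na(freq) & freq < rare_cutoff, "rare", "common"))
  # cataloged as known but frequency-less: call it rare only if < cutoff is
  # knowable; otherwise common (it is a known variant)
  cls[known & is.na(freq)] <- "common"
  variants$freq <- freq
  variants$class <- cls
  variants
}

# severity order used to pick the primary consequence across transcripts
.CONSEQUENCE_ORDER <- c("nonsense", "frameshift_indel", "coding_indel",
                        "missense", "splice_5prime", "splice_3prime",
                        "synonymous", "mature_mirna", "mirna_target",
                        "pri_mirna", "utr5", "utr3", "intronic",
                        "intergenic")

.revcomp_base <- function(b) chartr("ACGT", "TGCA", b)

.transcript_cds <- function(model, reference) {
  cds <- model[model$feature == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  chrom_seq <- reference[[cds$chrom[1]]]
  seq_fwd <- paste(vapply(seq_len(nrow(cds)), function(i)
    substr(chrom_seq, cds$start[i], cds$end[i]), character(1)),
    collapse = "")
  # genomic positions of CDS bases in ascending order
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    cds$start[i]:cds$end[i]))
  if (model$strand[1] == "-") {
    seq_cod <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq_fwd),
                                  "")[[1]]), collapse = "")
    gpos <- rev(gpos)
  } else seq_cod <- seq_fwd
  list(seq = seq_cod, gpos = gpos)
}

#' Annotate the molecular consequence of a variant against gene models
#'
#' Categories: coding (missense / nonsense / synonymous / coding_indel /
#' frameshift_indel, with frameshift iff indel length mod 3 != 0), splice
#' donor/acceptor (the 2 intronic bases at each internal exon boundary,
#' named relative to the transcript: `splice_5prime` = donor side),
#' 5'/3' UTR, miRNA features, intronic, or intergenic. Codons are
#' evaluated on the coding strand.
#'
#' @param variant list/row with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models data.frame with `gene`, `transcript`, `chrom`,
#'   `strand` ("+"/"-"), `feature` ("exon", "CDS", "mature_mirna",
#'   "pri_mirna", "mirna_target"), `start`, `end` (1-based inclusive).
#' @param reference named list/character of chromosome sequences (needed
#'   only to evaluate coding SNV codons).
#' @return list: `category`, `gene`, `transcript`, and for coding SNVs
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
annotate_consequence <- function(variant, gene_models, reference = NULL) {
  pos <- variant$pos
  chrom <- variant$chrom
  is_indel <- nchar(variant$ref) != nchar(variant$alt)
  indel_len <- abs(nchar(variant$ref) - nchar(variant$alt))
  results <- list()
  for (tx in unique(gene_models$transcript)) {
    m <- gene_models[gene_models$transcript == tx &
                       gene_models$chrom == chrom, , drop = FALSE]
    if (!nrow(m)) next
    span <- range(c(m$start, m$end))
    mir <- m$feature %in% c("mature_mirna", "pri_mirna", "mirna_target")
    if (any(mir)) {
      for (i in which(mir)) {
        if (pos >= m$start[i] && pos <= m$end[i])
          results[[length(results) + 1L]] <-
            list(category = m$feature[i], gene = m$gene[1], transcript = tx)
      }
      next
    }
    if (pos < span[1] - 2 || pos > span[2] + 2) next
    exons <- m[m$feature == "exon", , drop = FALSE]
    exons <- exons[order(exons$start), , drop = FALSE]
    cds <- m[m$feature == "CDS", , drop = FALSE]
    strand <- m$strand[1]
    in_exon <- any(pos >= exons$start & pos <= exons$end)
    in_cds <- nrow(cds) > 0 && any(pos >= cds$start & pos <= cds$end)
    cat <- NULL; extra <- list()
    if (in_cds && is_indel) {
      cat <- if (indel_len %% 3 != 0) "frameshift_indel" else "coding_indel"
    } else if (in_cds) {
      if (is.null(reference))
        stop("reference sequence required to evaluate coding SNVs")
      tc <- .transcript_cds(m, reference)
      ci <- match(pos, tc$gpos)
      codon_i <- (ci - 1) %/% 3
      off <- (ci - 1) %% 3
      ref_codon <- substr(tc$seq, codon_i * 3 + 1, codon_i * 3 + 3)
      alt_base <- if (strand == "-") .revcomp_base(variant$alt)
                  else variant$alt
      alt_codon <- ref_codon
      substr(alt_codon, off + 1, off + 1) <- alt_base
      code <- Biostrings::GENETIC_CODE
      ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
      cat <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
             else if (ref_aa == alt_aa) "synonymous" else "missense"
      extra <- list(ref_codon = ref_codon, alt_codon = alt_codon,
                    ref_aa = ref_aa, alt_aa = alt_aa)
    } else if (!in_exon) {
      # splice sites: 2 intronic bases at internal exon boundaries
      n_ex <- nrow(exons)
      donor <- acceptor <- FALSE
      if (n_ex > 1) {
        if (strand == "+") {
          donor <- any(pos %in% c(exons$end[-n_ex] + 1,
                                  exons$end[-n_ex] + 2))
          acceptor <- any(pos %in% c(exons$start[-1] - 1,
                                     exons$start[-1] - 2))
        } else {
          donor <- any(pos %in% c(exons$start[-1] - 1,
                                  exons$start[-1] - 2))
          acceptor <- any(pos %in% c(exons$end[-n_ex] + 1,
                                     exons$end[-n_ex] + 2))
        }
      }
      cat <- if (donor) "splice_5prime"
             else if (acceptor) "splice_3prime"
             else if (pos >= span[1] && pos <= span[2]) "intronic"
             else NULL
    } else {
      # exonic, non-coding: UTR side relative to the CDS
      if (nrow(cds) == 0) cat <- "intronic"  # non-coding transcript body
      else {
        cds_span <- range(c(cds$start, cds$end))
        before <- pos < cds_span[1]
        cat <- if ((before && strand == "+") || (!before && strand == "-"))
          "utr5" else "utr3"
      }
    }
    if (!is.null(cat))
      results[[length(results) + 1L]] <-
        c(list(category = cat, gene = m$gene[1], transcript = tx), extra)
  }
  if (!length(results))
    return(list(category = "intergenic", gene = NA, transcript = NA))
  sev <- vapply(results, function(r)
    match(r$category, .CONSEQUENCE_ORDER), integer(1))
  results[[which.min(sev)]]
}

#' Fitch-parsimony substitution count and evolutionary rate of an
#' alignment column
#'
#' Prunes species with gaps (or absent from the column) together with
#' their branches, runs the Fitch bottom-up pass to count the minimum
#' number of substitutions, and divides by the total branch length (time
#' span) of the pruned tree.
#'
#' @param residues named character vector (names = tree tip labels);
#'   gaps "-" and NA are pruned.
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return list: `substitutions`, `span`, `rate`; `NULL` rate (with
#'   `substitutions = NA`) when fewer than 2 ungapped residues remain.
#' @export
fitch_rate <- function(residues, tree) {
  keep <- names(residues)[!is.na(residues) & residues != "-"]
  keep <- intersect(keep, tree$tip.label)
  if (length(keep) < 2)
    return(list(substitutions = NA_integer_, span = NA_real_,
                rate = NA_real_))
  tr <- ape::keep.tip(tree, keep)
  res <- residues[tr$tip.label]
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  sets <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- res[i]
  count <- 0L
  post <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    parent <- post[k, 1]; child <- post[k, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[parent]], sets[[child]])
      if (length(inter)) sets[[parent]] <- inter
      else {
        sets[[parent]] <- union(sets[[parent]], sets[[child]])
        count <- count + 1L
      }
    }
  }
  span <- sum(tr$edge.length)
  list(substitutions = count, span = span, rate = count / span)
}

#' Default clinical rubric configuration
#'
#' Integer scales for scoring rare variants by disease phenotype features
#' and variant pathogenicity: onset (earliest and median), severity,
#' actionability, lifetime risk and variant pathogenicity on 1-7 scales,
#' plus the free-text inheritance mode. Lifetime risk additionally accepts
#' the label "variable".
#'
#' @export
rubric_config <- function() {
  list(inheritance = list(type = "label"),
       onset_earliest = list(type = "integer", scale = c(1, 7)),
       onset_median = list(type = "integer", scale = c(1, 7)),
       severity = list(type = "integer", scale = c(1, 7)),
       actionability = list(type = "integer", scale = c(1, 7)),
       lifetime_risk = list(type = "integer", scale = c(1, 7),
                            labels = "variable"),
       variant_pathogenicity = list(type = "integer", scale = c(1, 7)))
}

#' Score a variant against the clinical rubric
#'
#' Deterministic assembly of the configured rubric fields from a variant's
#' disease annotation; any missing field withholds the score with a
#' reason.
#'
#' @param annotation named list of annotation fields for the variant.
#' @param config a [rubric_config()]-shaped list.
#' @return list with `scores` (named), `complete` (logical), `withheld`
#'   (character vector of missing/invalid fields).
#' @export
score_variant_rubric <- function(annotation, config = rubric_config()) {
  scores <- list()
  withheld <- character(0)
  for (field in names(config)) {
    spec_f <- config[[field]]
    v <- annotation[[field]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      withheld <- c(withheld, field)
      next
    }
    if (spec_f$type == "integer" &&
        !(is.character(v) && v %in% spec_f$labels)) {
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v) || v < spec_f$scale[1] || v > spec_f$scale[2]) {
        withheld <- c(withheld, field)
        next
      }
    }
    scores[[field]] <- v
  }
  list(scores = scores, complete = length(withheld) == 0L,
       withheld = withheld)
}

#' Detect compound heterozygosity from phased rare variants
#'
#' Two distinct rare variants in the same gene on opposite parental
#' haplotypes of one child constitute a compound heterozygote.
#'
#' @param phased a `phased_quartet` data frame.
#' @param child "C1" or "C2".
#' @param variant_genes data.frame with `chrom`, `pos`, `gene` for the
#'   (rare) variants of interest.
#' @return data.frame of genes with `n_paternal`, `n_maternal`,
#'   `compound_het` (logical).
#' @export
compound_heterozygous <- function(phased, child, variant_genes) {
  idx <- match(paste(variant_genes$chrom, variant_genes$pos),
               paste(phased$chrom, phased$pos))
  pat <- phased[[paste0(child, "_pat")]][idx]
  mat <- phased[[paste0(child, "_mat")]][idx]
  carries_pat <- !is.na(pat) & pat == "b"
  carries_mat <- !is.na(mat) & mat == "b"
  genes <- unique(variant_genes$gene)
  out <- data.frame(
    gene = genes,
    n_paternal = vapply(genes, function(g)
      sum(carries_pat[variant_genes$gene == g]), integer(1)),
    n_maternal = vapply(genes, function(g)
      sum(carries_mat[variant_genes$gene == g]), integer(1)))
  out$compound_het <- out$n_paternal > 0 & out$n_maternal > 0
  rownames(out) <- NULL
  out
}
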