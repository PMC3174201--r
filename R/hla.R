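# Tag-haplotype HLA typing over phased data.
#
# Classical HLA alleles are proxied by short tag-SNP haplotypes; each
# chromosome copy of each family member is typed by nearest (Hamming)
# tag haplotype, with an iterative leave-one-out tie-break.

#' Extract one chromosome copy's bases at tag sites
#'
#' Reads the bases carried by the requested parental copy of a sample at
#' the given tag positions. Copies: for the children, 1 = paternal and
#' 2 = maternal haplotype; for the parents, 1 = the haplotype transmitted
#' to child 1 (contig-oriented) and 2 = the other haplotype. Unphased or
#' missing positions yield `NA`. When the tag span crosses a phase-contig
#' break of the relevant parent (e.g. a crossover window), only the largest
#' contig's sites are returned as called; the split is reported in the
#' `spans` attribute.
#'
#' @param phased a `phased_quartet` data frame.
#' @param tag_sites data.frame with `chrom`, `pos`.
#' @param sample one of "F", "M", "C1", "C2".
#' @param copy 1 or 2 (see above).
#' @return character vector of bases (NA = missing), with attribute
#'   `spans` (contig id per tag site) and `split` (logical).
#' @export
extract_phased_haplotype <- function(phased, tag_sites, sample, copy = 1L) {
  stopifnot(sample %in% SAMPLES, copy %in% 1:2)
  idx <- match(paste(tag_sites$chrom, tag_sites$pos),
               paste(phased$chrom, phased$pos))
  k <- length(idx)
  allele <- rep(NA_character_, k)
  contig <- rep(NA_integer_, k)
  found <- !is.na(idx)
  if (sample %in% c("C1", "C2")) {
    col <- paste0(sample, if (copy == 1L) "_pat" else "_mat")
    allele[found] <- phased[[col]][idx[found]]
    contig[found] <- phased[[paste0(sample, "_contig")]][idx[found]]
    # fall back to the genotype for homozygous (trivially phased) sites
    g <- phased[[paste0("g", sample)]][idx[found]]
    hom <- !is.na(g) & g %in% c("aa", "bb") & is.na(allele[found])
    allele[found][hom] <- substr(g[hom], 1, 1)
  } else {
    tcol <- paste0(sample, "_t1")
    gcol <- paste0("g", sample)
    t1 <- phased[[tcol]][idx[found]]
    g <- phased[[gcol]][idx[found]]
    other <- ifelse(!is.na(g) & g == "ab", .flip_allele(t1), t1)
    allele[found] <- if (copy == 1L) t1 else other
    contig[found] <- phased[[paste0(sample, "_contig")]][idx[found]]
    hom <- !is.na(g) & g %in% c("aa", "bb") & is.na(allele[found])
    allele[found][hom] <- substr(g[hom], 1, 1)
  }
  # contig consistency: phased calls are only comparable within one contig
  ph <- !is.na(allele) & !is.na(contig)
  split <- length(unique(contig[ph])) > 1L
  if (split) {
    tabulated <- table(contig[ph])
    main <- as.integer(names(tabulated)[which.max(tabulated)])
    hom_site <- !is.na(allele) & {
      g <- phased[[paste0("g", sample)]][idx]
      !is.na(g) & g != "ab"
    }
    drop_idx <- ph & contig != main & !hom_site
    allele[drop_idx] <- NA
  }
  bases <- ifelse(is.na(allele), NA_character_,
                  ifelse(allele == "a", phased$ref[idx], phased$alt[idx]))
  attr(bases, "spans") <- contig
  attr(bases, "split") <- split
  bases
}

#' Nearest tag haplotype with leave-one-out tie-breaking
#'
#' Hamming distance between the observed base vector and each panel
#' haplotype, computed over non-missing positions. A unique minimum gives
#' the call; on a tie, the single tag site whose removal maximizes the
#' best-versus-second-best margin is dropped and the search repeated until
#' the minimum is unique or sites are exhausted, in which case the
#' ambiguity set is returned.
#'
#' @param observed character vector of bases (NA = missing), one per tag
#'   site of the locus panel.
#' @param panel data.frame with `allele`, `pos`, `base`; all alleles of one
#'   locus share the same tag-site set.
#' @return list of class `hla_call`: `allele`, `distance`, `margin`,
#'   `ambiguity_set`, `n_scored`.
#' @export
nearest_tag_haplotype <- function(observed, panel) {
  pos <- sort(unique(panel$pos))
  stopifnot(length(observed) == length(pos))
  alleles <- unique(panel$allele)
  H <- vapply(alleles, function(a) {
    sub <- panel[panel$allele == a, ]
    sub$base[match(pos, sub$pos)]
  }, character(length(pos)))
  if (is.null(dim(H))) H <- matrix(H, nrow = length(pos))
  colnames(H) <- alleles
  active <- !is.na(observed)
  if (!any(active))
    return(structure(list(allele = NA_character_, distance = NA_real_,
                          margin = NA_real_, ambiguity_set = alleles,
                          n_scored = 0L), class = "hla_call"))
  dist_with <- function(use) colSums(H[use, , drop = FALSE] !=
                                       observed[use])
  use <- active
  repeat {
    d <- dist_with(use)
    o <- sort(d)
    best <- names(d)[d == o[1]]
    if (length(best) == 1L) {
      margin <- if (length(o) > 1) o[2] - o[1] else Inf
      return(structure(list(allele = best, distance = unname(o[1]),
                            margin = unname(margin),
                            ambiguity_set = best,
                            n_scored = sum(use)), class = "hla_call"))
    }
    if (sum(use) <= 1L)
      return(structure(list(allele = NA_character_, distance = unname(o[1]),
                            margin = 0, ambiguity_set = best,
                            n_scored = sum(use)), class = "hla_call"))
    # leave-one-out: drop the site whose removal maximizes the margin
    gains <- vapply(which(use), function(i) {
      u <- use; u[i] <- FALSE
      dd <- sort(dist_with(u))
      if (length(dd) > 1) dd[2] - dd[1] else Inf
    }, numeric(1))
    drop_site <- which(use)[which.max(gains)]
    new_use <- use; new_use[drop_site] <- FALSE
    d_new <- dist_with(new_use)
    if (sum(d_new == min(d_new)) >= length(best) && max(gains) <= 0)
      return(structure(list(allele = NA_character_,
                            distance = unname(min(d_new)), margin = 0,
                            ambiguity_set = best,
                            n_scored = sum(use)), class = "hla_call"))
    use <- new_use
  }
}

#' Type all eight chromosome copies of a quartet at tag-panel loci
#'
#' @param phased a `phased_quartet` data frame.
#' @param panel data.frame with `locus`, `allele`, `chrom`, `pos`, `base`.
#' @return data.frame: `sample`, `copy`, `locus`, `allele`, `distance`,
#'   `margin`, `ambiguous`.
#' @export
hla_type_quartet <- function(phased, panel) {
  out <- list()
  for (locus in unique(panel$locus)) {
    pl <- panel[panel$locus == locus, ]
    tag_sites <- unique(pl[order(pl$pos), c("chrom", "pos")])
    for (s in SAMPLES) for (copy in 1:2) {
      obs <- extract_phased_haplotype(phased, tag_sites, s, copy)
      call <- nearest_tag_haplotype(obs, pl[c("allele", "pos", "base")])
      out[[length(out) + 1L]] <- data.frame(
        sample = s, copy = copy, locus = locus,
        allele = if (is.na(call$allele)) NA_character_ else call$allele,
        distance = call$distance, margin = call$margin,
        ambiguous = is.na(call$allele), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
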