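#' quartetphase: phased interpretation of family-quartet genomes
#'
#' Analysis of whole-genome variant calls from a father-mother-two-children
#' quartet: major-allele reference construction, inheritance-state HMM error
#' control, sub-kilobase crossover mapping, three-tier long-range phasing,
#' tag-SNP HLA typing, composite likelihood-ratio disease risk, rare and
#' synonymous variant prioritization, and star-allele pharmacogenomics.
#' A synthetic quartet generator with full ground truth supports testing and
#' calibration of every stage.
#'
#' @docType package
#' @name quartetphase
#' @importFrom stats rpois runif rbinom rnorm rbeta median quantile uniroot
#'   setNames kmeans sd
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

# Genotype codes: "aa" (homozygous reference), "ab" (heterozygous),
# "bb" (homozygous alternate), NA (missing). "a" is always the reference
# allele, "b" the non-reference allele.
GENOTYPES <- c("aa", "ab", "bb")

# The four Mendelian inheritance states followed by the two error states.
# Order matters: it is the state index used throughout the HMM.
MENDELIAN_STATES <- c("identical", "paternal_identical",
                      "maternal_identical", "nonidentical")
ALL_STATES <- c(MENDELIAN_STATES, "compression", "mie_rich")

# sharing pattern (paternal_same, maternal_same) per Mendelian state
STATE_SHARING <- matrix(c(TRUE, TRUE,
                          TRUE, FALSE,
                          FALSE, TRUE,
                          FALSE, FALSE),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(MENDELIAN_STATES,
                                        c("paternal_same", "maternal_same")))

SAMPLES <- c("F", "M", "C1", "C2")

#' Construct a table of quartet variant sites
#'
#' The atomic record of the pipeline: one biallelic variant locus with the
#' four family genotypes. Genotypes are coded relative to the reference:
#' `"aa"` homozygous reference, `"ab"` heterozygous, `"bb"` homozygous
#' alternate, `NA` missing. Heterozygote order carries no phase information
#' until phasing assigns parental origin.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions (VCF convention).
#' @param ref,alt reference / alternate alleles (bases, or longer for indels).
#' @param gF,gM,gC1,gC2 genotype codes for father, mother, child 1, child 2.
#' @param qF,qM,qC1,qC2 per-sample genotype qualities (phred-like), optional.
#' @param is_indel logical; defaults to `nchar(ref) != nchar(alt)`.
#' @return a `data.frame` of class `quartet_sites`, sorted by (chrom, pos).
#' @export
quartet_sites <- function(chrom, pos, ref, alt, gF, gM, gC1, gC2,
                          qF = NA_real_, qM = NA_real_,
                          qC1 = NA_real_, qC2 = NA_real_,
                          is_indel = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), all(pos >= 1))
  chrom <- rep_len(as.character(chrom), n)
  check_gt <- function(g, who) {
    g <- as.character(g)
    bad <- !is.na(g) & !g %in% GENOTYPES
    if (any(bad))
      stop("invalid genotype code(s) for ", who, ": ",
           paste(unique(g[bad]), collapse = ", "))
    rep_len(g, n)
  }
  x <- data.frame(chrom = chrom, pos = as.integer(pos),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  gF = check_gt(gF, "father"), gM = check_gt(gM, "mother"),
                  gC1 = check_gt(gC1, "child1"), gC2 = check_gt(gC2, "child2"),
                  qF = rep_len(as.numeric(qF), n),
                  qM = rep_len(as.numeric(qM), n),
                  qC1 = rep_len(as.numeric(qC1), n),
                  qC2 = rep_len(as.numeric(qC2), n),
                  stringsAsFactors = FALSE)
  x$is_indel <- if (is.null(is_indel)) nchar(x$ref) != nchar(x$alt)
                else rep_len(is_indel, n)
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  if (anyDuplicated(x[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in quartet sites")
  rownames(x) <- NULL
  class(x) <- c("quartet_sites", "data.frame")
  x
}

# ---------------------------------------------------------------------------
# Assortment classification
#
# A Mendelian state is consistent with an observed genotype assortment iff
# there exists an assignment of parental haplotype indices transmitted to the
# two children, matching that state's sharing pattern, that reproduces both
# children's genotypes. Enumerated exhaustively over the 2^4 transmission
# choices; results are cached in a lookup table over the 81 genotype vectors.
# ---------------------------------------------------------------------------

.allele_pair <- function(g) switch(g, aa = c("a", "a"), ab = c("a", "b"),
                                   bb = c("b", "b"))

.classify_one <- function(gF, gM, gC1, gC2) {
  if (anyNA(c(gF, gM, gC1, gC2)))
    return(list(consistent = MENDELIAN_STATES, is_mie = FALSE,
                is_uniform_het = FALSE, is_uninformative = TRUE))
  fa <- .allele_pair(gF); mo <- .allele_pair(gM)
  sort_gt <- function(x, y) paste(sort(c(x, y)), collapse = "")
  consistent <- character(0)
  for (p1 in 1:2) for (p2 in 1:2) for (m1 in 1:2) for (m2 in 1:2) {
    if (sort_gt(fa[p1], mo[m1]) == gC1 && sort_gt(fa[p2], mo[m2]) == gC2) {
      st <- MENDELIAN_STATES[match(paste(p1 == p2, m1 == m2),
                                   paste(STATE_SHARING[, 1],
                                         STATE_SHARING[, 2]))]
      consistent <- union(consistent, st)
    }
  }
  uh <- all(c(gF, gM, gC1, gC2) == "ab")
  # Convention: a uniformly heterozygous assortment is uninformative —
  # treated as consistent with all four states. (Strict transmission
  # enumeration would give {identical, nonidentical}: under a
  # parent-identical state a doubly heterozygous parent pair cannot
  # produce two heterozygous children. But genotypes cannot tell the two
  # parental heterozygote orientations apart, compression artifacts
  # concentrate at exactly these sites, and the quartet literature scores
  # them as informationless; the package follows that convention.)
  if (uh) consistent <- MENDELIAN_STATES
  list(consistent = consistent,
       is_mie = length(consistent) == 0L,
       is_uniform_het = uh,
       is_uninformative = length(consistent) == 4L)
}

.assortment_env <- new.env(parent = emptyenv())

.assortment_table <- function() {
  if (!is.null(.assortment_env$tab)) return(.assortment_env$tab)
  grid <- expand.grid(gF = GENOTYPES, gM = GENOTYPES,
                      gC1 = GENOTYPES, gC2 = GENOTYPES,
                      stringsAsFactors = FALSE)
  tab <- lapply(seq_len(nrow(grid)), function(i)
    .classify_one(grid$gF[i], grid$gM[i], grid$gC1[i], grid$gC2[i]))
  names(tab) <- paste(grid$gF, grid$gM, grid$gC1, grid$gC2)
  .assortment_env$tab <- tab
  tab
}

#' Classify a quartet allele assortment against the Mendelian states
#'
#' Determines by exhaustive transmission enumeration which of the four
#' Mendelian inheritance states (identical, paternal-identical,
#' maternal-identical, nonidentical) are consistent with the observed
#' genotypes. An assortment consistent with no state is a Mendelian
#' inheritance error (MIE). A uniformly heterozygous assortment (all four
#' samples `"ab"`) is consistent with every state and is the signature
#' emitted by compression regions. Sites with any missing genotype are
#' treated as uninformative.
#'
#' @param gF,gM,gC1,gC2 genotype codes (vectors recycle to common length),
#'   or a `quartet_sites` data frame as the single first argument.
#' @return for scalar input a list with `consistent_states`, `is_mie`,
#'   `is_uniform_het`, `is_uninformative`; for vector input a data.frame with
#'   columns `consistent` (list column), `is_mie`, `is_uniform_het`,
#'   `is_uninformative`.
#' @export
classify_assortment <- function(gF, gM = NULL, gC1 = NULL, gC2 = NULL) {
  if (is.data.frame(gF)) {
    s <- gF
    return(classify_assortment(s$gF, s$gM, s$gC1, s$gC2))
  }
  n <- max(length(gF), length(gM), length(gC1), length(gC2))
  gF <- rep_len(gF, n); gM <- rep_len(gM, n)
  gC1 <- rep_len(gC1, n); gC2 <- rep_len(gC2, n)
  tab <- .assortment_table()
  key <- paste(gF, gM, gC1, gC2)
  miss <- is.na(gF) | is.na(gM) | is.na(gC1) | is.na(gC2)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- if (miss[i]) .classify_one(NA, NA, NA, NA) else tab[[key[i]]]
  }
  if (n == 1L) {
    r <- res[[1L]]
    return(list(consistent_states = r$consistent, is_mie = r$is_mie,
                is_uniform_het = r$is_uniform_het,
                is_uninformative = r$is_uninformative))
  }
  data.frame(consistent = I(lapply(res, `[[`, "consistent")),
             is_mie = vapply(res, `[[`, logical(1), "is_mie"),
             is_uniform_het = vapply(res, `[[`, logical(1), "is_uniform_het"),
             is_uninformative = vapply(res, `[[`, logical(1),
                                       "is_uninformative"))
}

# Pinned sharing-relation value per site for the given parent: TRUE/FALSE
# when the consistent-state set fixes that parent's sharing bit, NA when it
# does not (uninformative for that parent). Used for crossover-window
# bounds.
pinned_parent_bit <- function(sites, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  col <- if (parent == "paternal") "paternal_same" else "maternal_same"
  cls <- classify_assortment(sites)
  if (!is.null(cls$consistent_states))  # single-site scalar return
    cls <- list(consistent = list(cls$consistent_states))
  vapply(cls$consistent, function(cs) {
    if (length(cs) == 0L || length(cs) == 4L) return(NA)
    bits <- STATE_SHARING[cs, col]
    if (length(unique(bits)) == 1L) bits[1] else NA
  }, logical(1))
}

# TRUE where the assortment constrains the given parent's sharing relation
informative_for_parent <- function(sites, parent = c("paternal", "maternal")) {
  !is.na(pinned_parent_bit(sites, parent))
}
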