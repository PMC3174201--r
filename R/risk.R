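# Composite likelihood-ratio common-variant disease risk.
#
# Per-SNP genotype likelihood ratios are derived from a published odds
# ratio, the risk-allele frequency and the disease prevalence under a
# multiplicative (log-additive) genotype risk model; per-disease composite
# LRs multiply across (LD-pruned) loci; percentiles are taken against a
# reference cohort scored with the same associations; phased data
# attributes risk alleles to the parental haplotype of origin.

#' Genotype likelihood ratios from an odds ratio, allele frequency and
#' prevalence
#'
#' Genotype frequencies follow Hardy-Weinberg; the per-genotype disease
#' probabilities satisfy a multiplicative odds model
#' `odds(D | g) = odds0 * OR^g` (g = risk-allele count), with `odds0`
#' solved so the population prevalence is matched. LR(g) is then
#' `P(g | disease) / P(g | no disease)`.
#'
#' @param odds_ratio per-allele odds ratio (> 0).
#' @param risk_allele_freq population frequency of the risk allele (0, 1).
#' @param prevalence disease prevalence (0, 1).
#' @return named numeric: LRs for genotypes with 0, 1, 2 risk alleles
#'   (names `"0"`, `"1"`, `"2"`).
#' @export
genotype_lrs_from_summary <- function(odds_ratio, risk_allele_freq,
                                      prevalence) {
  stopifnot(odds_ratio > 0, risk_allele_freq > 0, risk_allele_freq < 1,
            prevalence > 0, prevalence < 1)
  f <- risk_allele_freq
  gfreq <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  penetrance <- function(log_odds0) {
    odds <- exp(log_odds0) * odds_ratio^(0:2)
    odds / (1 + odds)
  }
  eq <- function(log_odds0) sum(gfreq * penetrance(log_odds0)) - prevalence
  sol <- uniroot(eq, lower = -50, upper = 50, tol = 1e-12)
  p_g <- penetrance(sol$root)
  p_case <- gfreq * p_g / prevalence
  p_ctrl <- gfreq * (1 - p_g) / (1 - prevalence)
  if (any(p_case < 0) || any(p_ctrl < 0))
    stop("no valid solution for OR=", odds_ratio, ", freq=", f,
         ", prevalence=", prevalence)
  lr <- p_case / p_ctrl
  names(lr) <- c("0", "1", "2")
  lr
}

# risk-allele dosage of a genotype code given which allele carries risk
.risk_dosage <- function(genotype, risk_is_alt = TRUE) {
  d <- c(aa = 0, ab = 1, bb = 2)[genotype]
  if (!risk_is_alt) d <- 2 - d
  unname(d)
}

#' Filter an association table by the study inclusion rule
#'
#' Associations qualify when replicated in more than `min_studies` studies
#' with a total sample size above `min_total_n` (and, when the cohort is
#' supplied, genotyped in the reference panel). Duplicate rsids collapse to
#' the best-powered (largest total n) representative, as do loci in strong
#' mutual LD when an LD table is supplied.
#'
#' @param associations data.frame with at least `rsid`, `disease`,
#'   `n_studies`, `n_total` and either LR columns (`lr0`, `lr1`, `lr2`) or
#'   (`odds_ratio`, `risk_allele_freq`, `prevalence`).
#' @param min_studies,min_total_n inclusion thresholds.
#' @param ld optional LD records; pairs with r2 > `r2_prune` are pruned to
#'   the larger-n member.
#' @param r2_prune pruning threshold.
#' @export
qualify_associations <- function(associations, min_studies = 2,
                                 min_total_n = 2000, ld = NULL,
                                 r2_prune = 0.3) {
  a <- associations[associations$n_studies > min_studies &
                      associations$n_total > min_total_n, , drop = FALSE]
  a <- a[order(-a$n_total), , drop = FALSE]
  a <- a[!duplicated(paste(a$disease, a$rsid)), , drop = FALSE]
  if (!is.null(ld) && nrow(a) > 1 && all(c("pos") %in% names(a))) {
    drop <- rep(FALSE, nrow(a))
    strong <- ld[ld$r2 > r2_prune, , drop = FALSE]
    if (nrow(strong)) {
      for (i in seq_len(nrow(a))) {
        if (drop[i]) next
        linked <- strong$pos_b[strong$pos_a == a$pos[i]]
        linked <- c(linked, strong$pos_a[strong$pos_b == a$pos[i]])
        drop <- drop | (a$pos %in% linked & a$disease == a$disease[i] &
                          seq_len(nrow(a)) > i)
      }
      a <- a[!drop, , drop = FALSE]
    }
  }
  a
}

#' Composite likelihood ratio for one person and one disease
#'
#' Product of per-locus genotype LRs; a missing genotype contributes 1.
#' Associations may carry per-genotype LRs directly (`lr0`, `lr1`, `lr2`)
#' or summary statistics expanded via [genotype_lrs_from_summary()].
#'
#' @param genotypes named genotype vector (names = rsid, values "aa"/"ab"/
#'   "bb" with "b" the alternate allele) for one person.
#' @param associations qualifying associations for one disease; column
#'   `risk_is_alt` (logical, default TRUE) says whether the risk allele is
#'   the alternate allele.
#' @param pre_probability optional pre-test disease probability; when given,
#'   the post-test probability is computed via odds.
#' @return list of class `composite_risk`: `composite_lr`, `log10_lr`,
#'   `per_locus` (data.frame), `pre_probability`, `post_probability`.
#' @export
composite_lr <- function(genotypes, associations, pre_probability = NULL) {
  a <- associations
  if (!nrow(a)) {
    res <- list(composite_lr = 1, log10_lr = 0,
                per_locus = data.frame(), pre_probability = pre_probability,
                post_probability = pre_probability)
    class(res) <- "composite_risk"
    return(res)
  }
  a <- a[!duplicated(a$rsid), , drop = FALSE]
  risk_is_alt <- if ("risk_is_alt" %in% names(a)) a$risk_is_alt
                 else rep(TRUE, nrow(a))
  lr_locus <- numeric(nrow(a))
  dosage <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    lrs <- if (all(c("lr0", "lr1", "lr2") %in% names(a)) &&
               !is.na(a$lr0[i]))
      c(a$lr0[i], a$lr1[i], a$lr2[i])
    else genotype_lrs_from_summary(a$odds_ratio[i], a$risk_allele_freq[i],
                                   a$prevalence[i])
    g <- genotypes[a$rsid[i]]
    if (is.na(g)) { lr_locus[i] <- 1; dosage[i] <- NA; next }
    d <- .risk_dosage(g, risk_is_alt[i])
    dosage[i] <- d
    lr_locus[i] <- lrs[d + 1]
  }
  comp <- prod(lr_locus)
  post <- NULL
  if (!is.null(pre_probability)) {
    pre_odds <- pre_probability / (1 - pre_probability)
    post_odds <- pre_odds * comp
    post <- post_odds / (1 + post_odds)
  }
  res <- list(composite_lr = comp, log10_lr = log10(comp),
              per_locus = data.frame(rsid = a$rsid, lr = lr_locus,
                                     risk_dosage = dosage),
              pre_probability = pre_probability, post_probability = post)
  class(res) <- "composite_risk"
  res
}

#' Percentile of a composite LR against a reference cohort
#'
#' `100 * (#cohort members below the sample) / cohort size`, with ties
#' counted half.
#'
#' @param sample_lr the person's composite LR (or a `composite_risk`).
#' @param cohort_lrs numeric vector of cohort composite LRs (each scored
#'   with identical associations).
#' @export
percentile_vs_cohort <- function(sample_lr, cohort_lrs) {
  if (inherits(sample_lr, "composite_risk"))
    sample_lr <- sample_lr$composite_lr
  if (length(cohort_lrs) < 2) stop("cohort must contain at least 2 people")
  100 * (sum(cohort_lrs < sample_lr) + 0.5 * sum(cohort_lrs == sample_lr)) /
    length(cohort_lrs)
}

#' Score a cohort genotype matrix with one disease's associations
#'
#' @param cohort matrix/data.frame of genotype codes, people in rows,
#'   rsids in columns.
#' @param associations qualifying associations for the disease.
#' @return numeric vector of composite LRs, one per row.
#' @export
cohort_composite_lrs <- function(cohort, associations) {
  apply(cohort, 1L, function(row)
    composite_lr(setNames(as.character(row), colnames(cohort)),
                 associations)$composite_lr)
}

#' Parental haplotype attribution of a child's risk alleles
#'
#' Tallies, per disease, the number of risk alleles the child carries on
#' the paternal versus maternal haplotype; risk alleles at unphased
#' heterozygous loci are counted separately and never attributed.
#'
#' @param phased a `phased_quartet` data frame.
#' @param child "C1" or "C2".
#' @param associations associations with `rsid`, `chrom`, `pos` and
#'   optional `risk_is_alt`.
#' @return list: `paternal`, `maternal`, `unphased` risk-allele counts and
#'   `per_locus` detail.
#' @export
parental_contribution <- function(phased, child, associations) {
  stopifnot(child %in% c("C1", "C2"))
  idx <- match(paste(associations$chrom, associations$pos),
               paste(phased$chrom, phased$pos))
  risk_is_alt <- if ("risk_is_alt" %in% names(associations))
    associations$risk_is_alt else rep(TRUE, nrow(associations))
  risk_allele <- ifelse(risk_is_alt, "b", "a")
  g <- phased[[paste0("g", child)]][idx]
  pat <- phased[[paste0(child, "_pat")]][idx]
  mat <- phased[[paste0(child, "_mat")]][idx]
  hom <- !is.na(g) & g != "ab"
  pat[hom] <- substr(g[hom], 1, 1); mat[hom] <- substr(g[hom], 2, 2)
  pat_hit <- !is.na(pat) & pat == risk_allele
  mat_hit <- !is.na(mat) & mat == risk_allele
  unph <- !is.na(g) & g == "ab" & is.na(pat)
  unph_hits <- sum(unph)  # a het carries exactly one copy of either allele
  list(paternal = sum(pat_hit), maternal = sum(mat_hit),
       unphased = unph_hits,
       per_locus = data.frame(rsid = associations$rsid,
                              paternal = pat_hit, maternal = mat_hit,
                              unphased = unph))
}
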