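# Star-allele diplotyping, clinical PGx annotation, and config-driven
# warfarin dose prediction.

#' Call star-allele diplotypes for one sample and gene
#'
#' Each haplotype is matched against the allele definitions (an allele
#' matches when every defining variant is present on that haplotype); no
#' match defaults to *1 (whose defining set is empty). When the same
#' haplotype matches nested definitions, the most specific (largest
#' defining set) wins; a specificity tie is ambiguous. Unphased
#' heterozygous defining variants are handled by enumerating the
#' assignments consistent with the genotypes: a unique resulting diplotype
#' is called, otherwise the call is ambiguous.
#'
#' @param genotypes data.frame for one sample with `pos`, `genotype`
#'   ("aa"/"ab"/"bb", alt allele = defining allele), `hap1`, `hap2`
#'   (alleles "a"/"b", NA when unphased). Positions absent from the table
#'   are taken as homozygous reference.
#' @param definitions data.frame with `gene`, `allele`, `pos` (one row per
#'   defining variant; alleles with no rows need not appear — *1 is
#'   implicit), `activity` (per-allele label, repeated across rows).
#' @param gene gene symbol.
#' @param phenotype_map named character: phenotype per sorted
#'   activity-pair key "act1/act2" (see [default_phenotype_map()]).
#' @return list of class `diplotype_call`: `gene`, `alleles` (sorted pair),
#'   `phenotype`, `provisional`, `ambiguous`, `candidates`.
#' @export
call_star_alleles <- function(genotypes, definitions, gene,
                              phenotype_map = default_phenotype_map()) {
  defs <- definitions[definitions$gene == gene, , drop = FALSE]
  alleles <- unique(defs$allele)
  activity <- setNames(
    vapply(alleles, function(a)
      defs$activity[defs$allele == a][1], character(1)), alleles)
  activity <- c(activity, "*1" = "normal")
  g_at <- function(pos) {
    i <- match(pos, genotypes$pos)
    ifelse(is.na(i), "aa", genotypes$genotype[i])
  }
  hap_at <- function(pos, hap) {
    i <- match(pos, genotypes$pos)
    out <- rep("a", length(pos))
    out[!is.na(i)] <- genotypes[[hap]][i[!is.na(i)]]
    out
  }
  def_pos <- sort(unique(defs$pos))
  g <- g_at(def_pos)
  het <- def_pos[g == "ab"]
  unphased_het <- het[is.na(hap_at(het, "hap1"))]

  match_hap <- function(carried) {
    # carried: named logical over def_pos (TRUE = alt allele present)
    hits <- alleles[vapply(alleles, function(a) {
      need <- defs$pos[defs$allele == a]
      all(carried[as.character(need)])
    }, logical(1))]
    if (!length(hits)) return("*1")
    sizes <- vapply(hits, function(a) sum(defs$allele == a), integer(1))
    best <- hits[sizes == max(sizes)]
    if (length(best) > 1) return(NA_character_)  # specificity tie
    best
  }
  assign_from <- function(h1_carries, h2_carries) {
    a1 <- match_hap(h1_carries); a2 <- match_hap(h2_carries)
    if (is.na(a1) || is.na(a2)) return(NULL)
    sort(c(a1, a2))
  }
  base_carried <- function(hap) {
    carried <- setNames(g == "bb", as.character(def_pos))
    ph <- !def_pos %in% unphased_het & g == "ab"
    carried[as.character(def_pos[ph])] <-
      hap_at(def_pos[ph], hap) == "b"
    carried
  }
  h1 <- base_carried("hap1"); h2 <- base_carried("hap2")
  if (length(unphased_het) == 0L) {
    cand <- list(assign_from(h1, h2))
  } else {
    cand <- list()
    for (mask in seq_len(2^length(unphased_het)) - 1L) {
      bits <- as.logical(bitwAnd(mask, 2^(seq_along(unphased_het) - 1L)))
      a <- h1; b <- h2
      a[as.character(unphased_het)] <- bits
      b[as.character(unphased_het)] <- !bits
      cand[[length(cand) + 1L]] <- assign_from(a, b)
    }
  }
  cand <- unique(Filter(Negate(is.null), cand))
  if (length(cand) == 0L)
    return(structure(list(gene = gene, alleles = c(NA, NA),
                          phenotype = NA, provisional = FALSE,
                          ambiguous = TRUE, candidates = list()),
                     class = "diplotype_call"))
  ambiguous <- length(cand) > 1L
  pair <- cand[[1]]
  key <- paste(sort(c(activity[pair[1]], activity[pair[2]])),
               collapse = "/")
  phen <- phenotype_map[key]
  provisional <- !ambiguous && (is.na(phen) || grepl("provisional|undetermined",
                                                     phen, ignore.case = TRUE))
  structure(list(gene = gene,
                 alleles = if (ambiguous) c(NA, NA) else pair,
                 phenotype = if (ambiguous) NA else unname(phen),
                 provisional = provisional, ambiguous = ambiguous,
                 candidates = cand),
            class = "diplotype_call")
}

#' Default activity-pair to metabolizer-phenotype map
#'
#' Mixed increased-activity / loss-of-function diplotypes are deliberately
#' labelled undetermined (provisional): their in-vivo phenotype is not
#' settled.
#' @export
default_phenotype_map <- function() {
  c("normal/normal" = "normal metabolizer",
    "loss_of_function/normal" = "intermediate metabolizer",
    "loss_of_function/loss_of_function" = "poor metabolizer",
    "increased/normal" = "rapid metabolizer",
    "increased/increased" = "ultra metabolizer",
    "increased/loss_of_function" =
      "undetermined (provisional): 1 increased-activity and 1 loss-of-function allele")
}

#' Join sample genotypes against a clinical PGx annotation table
#'
#' @param genotypes data.frame with `rsid`, `genotype` (base-pair string or
#'   code matching the table's genotype column).
#' @param annotation data.frame keyed by `rsid` + `genotype` with columns
#'   `drug`, `category` (efficacy / adverse / dose), `direction`,
#'   `confidence`.
#' @return one report row per (genotype, drug) table entry, plus an
#'   "unknown" row per genotype with no table entry.
#' @export
annotate_pgx <- function(genotypes, annotation) {
  out <- list()
  for (i in seq_len(nrow(genotypes))) {
    hit <- annotation[annotation$rsid == genotypes$rsid[i] &
                        annotation$genotype == genotypes$genotype[i], ,
                      drop = FALSE]
    if (nrow(hit) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        rsid = genotypes$rsid[i], genotype = genotypes$genotype[i],
        drug = NA_character_, category = "no PGx action/phenotype unknown",
        direction = NA_character_, confidence = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        rsid = genotypes$rsid[i], genotype = genotypes$genotype[i],
        drug = hit$drug, category = hit$category,
        direction = hit$direction, confidence = hit$confidence,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict a warfarin dose from clinical covariates and genotypes
#'
#' Evaluates a linear dosing model supplied as configuration (for example
#' the published IWPC pharmacogenetic algorithm, shipped as
#' `system.file("extdata", "iwpc_coefficients.tsv", package =
#' "quartetphase")`). The linear predictor is evaluated on the named
#' covariate values; when the config's scale is `"sqrt_weekly"`, the
#' predictor is the square root of the weekly dose, so the weekly dose is
#' its square and the daily dose is that divided by 7.
#'
#' @param covariates named numeric list/vector: clinical covariates and
#'   genotype indicator variables, matching the config's `term` names
#'   (`(Intercept)` is implicit with value 1).
#' @param config data.frame with `term`, `coefficient`, plus attributes or
#'   columns `scale` ("sqrt_weekly" or "linear") — see
#'   [read_dosing_config()].
#' @return list: `linear_predictor`, `weekly_dose`, `daily_dose`.
#' @export
warfarin_dose <- function(covariates, config) {
  terms <- config$term
  needed <- setdiff(terms, "(Intercept)")
  missing_cov <- setdiff(needed, names(covariates))
  if (length(missing_cov))
    stop("missing mandatory covariate(s): ",
         paste(missing_cov, collapse = ", "))
  x <- c("(Intercept)" = 1, unlist(covariates))
  lp <- sum(config$coefficient * x[terms])
  scale <- attr(config, "scale")
  if (is.null(scale)) scale <- if ("scale" %in% names(config))
    config$scale[1] else "sqrt_weekly"
  if (scale == "sqrt_weekly") {
    weekly <- lp^2
  } else weekly <- lp
  list(linear_predictor = lp, weekly_dose = weekly,
       daily_dose = weekly / 7)
}

#' Read a dosing-model coefficient table
#'
#' Two-column TSV (`term`, `coefficient`); lines beginning `#scale=` set
#' the predictor scale.
#' @param path TSV path.
#' @export
read_dosing_config <- function(path) {
  lines <- readLines(path)
  scale <- sub("^#scale=", "", grep("^#scale=", lines, value = TRUE))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  attr(tab, "scale") <- if (length(scale)) scale else "sqrt_weekly"
  tab
}
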