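# Ethnicity-specific major-allele reference construction.
#
# At every position where the population's major allele differs from the
# reference base, the major allele is substituted; single-base
# substitutions only, so sequence lengths are preserved. A frequency tie
# (alternate-allele frequency exactly 0.5) keeps the reference base.

#' Build a major-allele reference for one population
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param freqs data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and one alternate-allele frequency column per population, named
#'   `freq_<population>` (or a plain `freq` column).
#' @param population population label selecting the frequency column.
#' @return list: `sequences` (same class as input), `substitutions`
#'   (data.frame: chrom, pos, original_base, major_base, major_freq) and
#'   `n_ties` (positions with frequency exactly 0.5, never substituted).
#' @export
build_major_allele_reference <- function(reference, freqs, population) {
  fcol <- if (paste0("freq_", population) %in% names(freqs))
    paste0("freq_", population)
  else if ("freq" %in% names(freqs)) "freq"
  else stop("no frequency column for population ", population)
  was_dss <- inherits(reference, "DNAStringSet")
  seqs <- if (was_dss) as.character(reference) else
    unlist(as.list(reference))
  f <- freqs[[fcol]]
  if (any(f < 0 | f > 1, na.rm = TRUE)) stop("frequencies must be in [0,1]")
  snv <- nchar(freqs$ref) == 1 & nchar(freqs$alt) == 1
  # verify the stated reference base at every record
  for (chrom in unique(freqs$chrom)) {
    if (!chrom %in% names(seqs)) stop("chromosome absent from reference: ",
                                      chrom)
    rows <- which(freqs$chrom == chrom & snv)
    if (!length(rows)) next
    have <- substring(seqs[[chrom]], freqs$pos[rows], freqs$pos[rows])
    bad <- have != freqs$ref[rows]
    if (any(bad))
      stop("reference base mismatch at ", chrom, ":",
           freqs$pos[rows[which(bad)[1]]], " (expected ",
           freqs$ref[rows[which(bad)[1]]], ", found ",
           have[which(bad)[1]], ")")
  }
  n_ties <- sum(snv & !is.na(f) & f == 0.5)
  sub_rows <- which(snv & !is.na(f) & f > 0.5)
  subs <- data.frame(chrom = freqs$chrom[sub_rows],
                     pos = freqs$pos[sub_rows],
                     original_base = freqs$ref[sub_rows],
                     major_base = freqs$alt[sub_rows],
                     population = rep(population, length(sub_rows)),
                     major_freq = f[sub_rows],
                     stringsAsFactors = FALSE)
  for (chrom in unique(subs$chrom)) {
    rows <- subs$chrom == chrom
    s <- strsplit(seqs[[chrom]], "")[[1]]
    s[subs$pos[rows]] <- subs$major_base[rows]
    seqs[[chrom]] <- paste(s, collapse = "")
  }
  rownames(subs) <- NULL
  out_seqs <- if (was_dss) Biostrings::DNAStringSet(seqs) else seqs
  list(sequences = out_seqs, substitutions = subs, n_ties = n_ties)
}

#' Per-chromosome substitution density (substitutions per Mbp)
#'
#' @param subs substitution table from [build_major_allele_reference()].
#' @param chrom_lengths named numeric: chromosome lengths in bp, covering
#'   every chromosome in `subs`.
#' @return data.frame: `chrom`, `n`, `per_mbp` (all chromosomes in
#'   `chrom_lengths`, zero where no substitutions).
#' @export
substitution_density <- function(subs, chrom_lengths) {
  unknown <- setdiff(unique(subs$chrom), names(chrom_lengths))
  if (length(unknown)) stop("unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  n <- vapply(names(chrom_lengths), function(chrom)
    sum(subs$chrom == chrom), integer(1))
  data.frame(chrom = names(chrom_lengths), n = unname(n),
             per_mbp = unname(n / (chrom_lengths / 1e6)),
             row.names = NULL)
}

#' Sharing of substituted positions among populations (Venn cells)
#'
#' @param subs_by_population named list of substitution tables (one per
#'   population).
#' @return data.frame: one row per non-empty population combination
#'   (`populations`, `+`-separated), with `n` exclusive positions in that
#'   exact combination; cells sum to the union size.
#' @export
population_sharing <- function(subs_by_population) {
  stopifnot(length(subs_by_population) >= 2)
  keys <- lapply(subs_by_population, function(s) paste(s$chrom, s$pos))
  all_pos <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_pos %in% k,
                   logical(length(all_pos)))
  if (length(all_pos) == 1L) member <- matrix(member, nrow = 1)
  combo <- apply(member, 1, function(row)
    paste(names(subs_by_population)[row], collapse = "+"))
  tab <- table(combo)
  data.frame(populations = names(tab), n = as.integer(tab),
             row.names = NULL)
}

#' Flag disease-associated sites where the reference carries the minor
#' allele
#'
#' A site is flagged when the reference base's frequency in the chosen
#' population is below 0.5; flagged sites are sub-stratified by
#' reference-base frequency below 5% and below 1%.
#'
#' @param disease_sites data.frame with `chrom`, `pos` (and any annotation
#'   columns, carried through).
#' @param freqs frequency table as in [build_major_allele_reference()].
#' @param population population label.
#' @param thresholds frequency strata (default `c(0.05, 0.01)`).
#' @return list: `flagged` (data.frame with `ref_freq` and one logical
#'   column per stratum), `n_flagged`, `n_unassessable`, and
#'   `strata_counts`.
#' @export
flag_minor_allele_disease_sites <- function(disease_sites, freqs, population,
                                            thresholds = c(0.05, 0.01)) {
  fcol <- if (paste0("freq_", population) %in% names(freqs))
    paste0("freq_", population) else "freq"
  idx <- match(paste(disease_sites$chrom, disease_sites$pos),
               paste(freqs$chrom, freqs$pos))
  ref_freq <- 1 - freqs[[fcol]][idx]
  assessable <- !is.na(ref_freq)
  flagged <- assessable & ref_freq < 0.5
  out <- disease_sites
  out$ref_freq <- ref_freq
  out$flagged <- flagged
  strata <- list()
  for (th in sort(thresholds, decreasing = TRUE)) {
    cn <- paste0("below_", th * 100, "pct")
    out[[cn]] <- flagged & ref_freq < th
    strata[[cn]] <- sum(out[[cn]])
  }
  list(flagged = out, n_flagged = sum(flagged),
       n_unassessable = sum(!assessable),
       strata_counts = unlist(strata))
}
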