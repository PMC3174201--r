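# Meiotic crossover windows from inheritance-state block boundaries,
# resolution statistics, and hotspot enrichment by Monte Carlo permutation.

# sharing bits of a Mendelian state
.state_bits <- function(state) STATE_SHARING[state, ]

#' Extract crossover windows from inheritance-state blocks
#'
#' Error-state blocks (compression, MIE-rich) are removed first — they are
#' potential sources of spurious recombination inferences — and adjacent
#' blocks left in the same Mendelian state are merged. Each boundary between
#' Mendelian blocks whose states differ in one parent's sharing relation
#' yields one window for that parent; a boundary where both relations change
#' (identical to nonidentical) yields one paternal and one maternal window
#' (a double crossover between informative markers). Window bounds are the
#' last / first markers of the flanking blocks informative for the changed
#' parent when `sites` is supplied, otherwise the block edge coordinates.
#'
#' @param blocks output of [decode_states()].
#' @param sites optional [quartet_sites] table used to snap window bounds to
#'   parent-informative markers.
#' @return data.frame: `chrom`, `parent`, `left_bound`, `right_bound`,
#'   `width`.
#' @export
extract_crossovers <- function(blocks, sites = NULL) {
  out <- list()
  pinned <- NULL
  if (!is.null(sites)) {
    pinned <- list(
      paternal = pinned_parent_bit(sites, "paternal"),
      maternal = pinned_parent_bit(sites, "maternal"))
  }
  for (chrom in unique(blocks$chrom)) {
    raw <- blocks[blocks$chrom == chrom, , drop = FALSE]
    if (nrow(raw) > 1L && any(raw$state[-1] == raw$state[-nrow(raw)]))
      stop("adjacent blocks share a state; block invariant violated")
    b <- raw[raw$state %in% MENDELIAN_STATES, , drop = FALSE]
    if (nrow(b) < 2L) next
    # merge runs left identical after error-block removal
    keep <- c(TRUE, b$state[-1] != b$state[-nrow(b)])
    merged <- b[keep, , drop = FALSE]
    grp <- cumsum(keep)
    merged$last_index <- tapply(b$last_index, grp, max)
    merged$last_pos <- tapply(b$last_pos, grp, max)
    b <- merged
    for (k in seq_len(nrow(b) - 1L)) {
      bits_l <- .state_bits(b$state[k]); bits_r <- .state_bits(b$state[k + 1])
      changed <- c("paternal", "maternal")[bits_l != bits_r]
      if (length(changed) == 0L)
        stop("adjacent blocks share a state; block invariant violated")
      for (parent in changed) {
        left <- b$last_pos[k]; right <- b$first_pos[k + 1]
        if (!is.null(pinned)) {
          # bounds: last/first markers whose assortment pins the changed
          # parent's sharing relation to the flanking block's own value
          pin <- pinned[[parent]]
          bit_col <- if (parent == "paternal") "paternal_same"
                     else "maternal_same"
          bit_l <- STATE_SHARING[b$state[k], bit_col]
          bit_r <- STATE_SHARING[b$state[k + 1], bit_col]
          li <- b$first_index[k]:b$last_index[k]
          ri <- b$first_index[k + 1]:b$last_index[k + 1]
          li_inf <- li[!is.na(pin[li]) & pin[li] == bit_l]
          ri_inf <- ri[!is.na(pin[ri]) & pin[ri] == bit_r]
          if (length(li_inf)) left <- sites$pos[max(li_inf)]
          if (length(ri_inf)) right <- sites$pos[min(ri_inf)]
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, parent = parent,
          left_bound = left, right_bound = right,
          width = right - left, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), parent = character(0),
                      left_bound = integer(0), right_bound = integer(0),
                      width = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolution statistics of crossover windows
#'
#' @param windows output of [extract_crossovers()].
#' @return list with `n`, `median`, `mean`, and `quantiles` (5/25/75/95%).
#' @export
resolution_stats <- function(windows) {
  if (nrow(windows) == 0L) stop("no crossover windows")
  w <- windows$width
  list(n = length(w), median = median(w), mean = mean(w),
       quantiles = quantile(w, c(0.05, 0.25, 0.75, 0.95)))
}

.overlaps_any <- function(chrom, left, right, iv) {
  # window [left, right] (1-based inclusive) vs 0-based half-open intervals
  if (nrow(iv) == 0L) return(rep(FALSE, length(left)))
  hit <- rep(FALSE, length(left))
  for (k in seq_len(nrow(iv)))
    hit <- hit | (chrom == iv$chrom[k] & right > iv$start[k] &
                    left <= iv$end[k])
  hit
}

#' Hotspot enrichment of crossover windows by Monte Carlo permutation
#'
#' Tests whether crossover windows overlap recombination hotspots more often
#' than expected by chance. The null re-places windows uniformly over the
#' callable territory of their own chromosome, preserving widths and
#' per-chromosome counts. The p-value uses the add-one estimator
#' `(1 + #permutations >= observed) / (1 + n_permutations)` and therefore
#' never returns 0; when saturated it is reported as `< 1/(1+N)` via the
#' `saturated` flag.
#'
#' @param windows output of [extract_crossovers()].
#' @param hotspots interval table with rate payload; only intervals with
#'   rate > `rate_threshold` cM/Mbp (or no rate) are used.
#' @param callable interval table of callable territory.
#' @param n_permutations number of Monte Carlo permutations.
#' @param seed RNG seed.
#' @param rate_threshold hotspot definition threshold (cM/Mbp).
#' @return list: `n_windows`, `n_in_hotspot`, `observed_fraction`,
#'   `expected_by_chance`, `expected_fraction`, `genome_fraction_in_hotspots`,
#'   `p_value`, `saturated`, `n_permutations`, `seed`.
#' @export
hotspot_enrichment <- function(windows, hotspots, callable,
                               n_permutations = 1000L, seed = 1L,
                               rate_threshold = 10) {
  set.seed(seed)
  hs <- hotspots[is.na(hotspots$rate) | hotspots$rate > rate_threshold, ,
                 drop = FALSE]
  n_w <- nrow(windows)
  observed <- sum(.overlaps_any(windows$chrom, windows$left_bound,
                                windows$right_bound, hs))
  null_counts <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    cnt <- 0L
    for (chrom in unique(windows$chrom)) {
      w <- windows[windows$chrom == chrom, , drop = FALSE]
      cal <- callable[callable$chrom == chrom, , drop = FALSE]
      if (nrow(cal) == 0L) stop("no callable territory for ", chrom)
      len <- cal$end - cal$start
      for (j in seq_len(nrow(w))) {
        width <- w$width[j]
        room <- pmax(0, len - width)
        if (all(room == 0)) stop("callable territory shorter than a window")
        iv <- sample.int(nrow(cal), 1L, prob = room + (len >= width))
        start <- cal$start[iv] + floor(runif(1) * max(1, len[iv] - width))
        cnt <- cnt + .overlaps_any(chrom, start + 1L, start + width + 1L, hs)
      }
    }
    null_counts[p] <- cnt
  }
  n_ge <- sum(null_counts >= observed)
  hs_len <- sum(as.numeric(hs$end - hs$start))
  cal_len <- sum(as.numeric(callable$end - callable$start))
  list(n_windows = n_w, n_in_hotspot = observed,
       observed_fraction = if (n_w > 0) observed / n_w else NA_real_,
       expected_by_chance = mean(null_counts),
       expected_fraction = if (n_w > 0) mean(null_counts) / n_w else NA_real_,
       genome_fraction_in_hotspots = if (cal_len > 0) hs_len / cal_len
                                     else NA_real_,
       p_value = (1 + n_ge) / (1 + n_permutations),
       saturated = n_ge == 0L,
       n_permutations = n_permutations, seed = seed)
}

#' Report haplotypes at recombination-modifier marker loci
#'
#' Reads two-locus (or k-locus) haplotypes for each family member off the
#' phased data, e.g. at the RNF212 SNPs whose haplotypes modify sex-specific
#' recombination rates. A sample homozygous at every marker needs no phase;
#' a heterozygous sample is reported as ambiguous unless all markers are
#' phased within one contig.
#'
#' @param phased a `phased_quartet` data frame from [phase_quartet()].
#' @param markers data.frame with `chrom`, `pos` (and optionally `label`).
#' @return list per sample: either `haplotypes` (character matrix, one row
#'   per chromosome copy, bases) or a `status` of "ambiguous" / "missing".
#' @export
annotate_recomb_modifier_haplotypes <- function(phased, markers) {
  idx <- match(paste(markers$chrom, markers$pos),
               paste(phased$chrom, phased$pos))
  if (anyNA(idx))
    return(lapply(setNames(nm = SAMPLES), function(s)
      list(status = "missing",
           missing_markers = markers$pos[is.na(idx)])))
  base_of <- function(allele, i)
    ifelse(allele == "a", phased$ref[i], phased$alt[i])
  out <- list()
  for (s in SAMPLES) {
    g <- phased[[paste0("g", s)]][idx]
    if (anyNA(g)) { out[[s]] <- list(status = "missing"); next }
    if (all(g != "ab")) {
      hap <- vapply(seq_along(idx), function(k)
        base_of(substr(g[k], 1, 1), idx[k]), character(1))
      out[[s]] <- list(haplotypes = rbind(hap, hap), status = "homozygous")
      next
    }
    h1 <- h2 <- character(length(idx))
    if (s %in% c("C1", "C2")) {
      pat <- phased[[paste0(s, "_pat")]][idx]
      mat <- phased[[paste0(s, "_mat")]][idx]
      contig <- phased[[paste0(s, "_contig")]][idx]
      ok <- !anyNA(pat) && !anyNA(mat) && length(unique(contig)) == 1L
      if (!ok) { out[[s]] <- list(status = "ambiguous"); next }
      h1 <- base_of(pat, idx); h2 <- base_of(mat, idx)
    } else {
      t1 <- phased[[paste0(s, "_t1")]][idx]
      contig <- phased[[paste0(s, "_contig")]][idx]
      ok <- !anyNA(t1) && length(unique(contig)) == 1L
      if (!ok) { out[[s]] <- list(status = "ambiguous"); next }
      other <- ifelse(g == "ab", ifelse(t1 == "a", "b", "a"), t1)
      h1 <- base_of(t1, idx); h2 <- base_of(other, idx)
    }
    out[[s]] <- list(haplotypes = rbind(h1, h2), status = "phased")
  }
  out
}

#' Expected fraction of markers informative for a parent's sharing relation
#'
#' Under balanced (frequency 1/2) biallelic markers with independent founder
#' alleles, enumerates the 16 founder allele configurations within each
#' Mendelian inheritance state and counts those whose quartet assortment
#' pins the parent's sharing relation. Averaged over the four states and
#' both parents this fraction is 5/16; it converts a target
#' informative-marker spacing into a polymorphic-site density for
#' resolution studies.
#'
#' @return scalar fraction.
#' @export
expected_informative_fraction <- function() {
  code <- c("a", "b")
  gt <- function(a, b) paste(sort(c(a, b)), collapse = "")
  total <- 0
  hits <- 0
  for (s in MENDELIAN_STATES) {
    bits <- STATE_SHARING[s, ]
    for (x1 in 0:1) for (x2 in 0:1) for (y1 in 0:1) for (y2 in 0:1) {
      px2 <- if (bits["paternal_same"]) x1 else x2
      my2 <- if (bits["maternal_same"]) y1 else y2
      site <- quartet_sites("chr1", 1, "A", "G",
                            gt(code[x1 + 1], code[x2 + 1]),
                            gt(code[y1 + 1], code[y2 + 1]),
                            gt(code[x1 + 1], code[y1 + 1]),
                            gt(code[px2 + 1], code[my2 + 1]))
      for (p in c("paternal", "maternal")) {
        total <- total + 1
        if (!is.na(pinned_parent_bit(site, p))) hits <- hits + 1
      }
    }
  }
  hits / total
}
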