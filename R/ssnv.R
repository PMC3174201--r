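# Functional scores for synonymous SNVs: mRNA folding-energy shift,
# codon-usage cluster shift, and splice-site creation/disruption under
# positional scoring models.

#' Base-pair maximization folding energy (Nussinov-style)
#'
#' The package's default mRNA energy proxy: a dynamic program maximizing
#' weighted Watson-Crick/wobble pairings (GC = 3, AU = 2, GU = 1) with a
#' minimum hairpin loop of 3 nt; energy is the negative of the optimal
#' pairing score, so more stable structure means lower energy. Any other
#' energy function (e.g. a thermodynamic folder wrapped in an R function)
#' can be plugged into [ssnv_energy_zscore()].
#'
#' @param seq a character string (DNA alphabet; T is treated as U).
#' @return numeric energy (arbitrary units, lower = more stable).
#' @export
pairing_energy <- function(seq) {
  s <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(s)
  if (n < 5) return(0)
  pair_score <- function(a, b) {
    k <- paste0(a, b)
    w <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)[k]
    ifelse(is.na(w), 0, w)
  }
  M <- matrix(0, n, n)
  for (len in 5:n) {
    i <- seq_len(n - len + 1)
    j <- i + len - 1L
    pairij <- pair_score(s[i], s[j])
    best <- pmax(M[cbind(pmin(i + 1, n), pmax(j - 1, 1))] + pairij,
                 M[cbind(i, j - 1L)])
    # bifurcation: max over split points, vectorized per diagonal
    for (t in seq_along(i)) {
      ii <- i[t]; jj <- j[t]
      ks <- ii:(jj - 1L)
      b2 <- max(M[ii, ks] + M[cbind(ks + 1L, jj)])
      if (b2 > best[t]) best[t] <- b2
    }
    M[cbind(i, j)] <- best
  }
  -M[1, n]
}

#' Folding-energy shift and Z-score for a synonymous SNV
#'
#' Compares the folding energy of a window centered on the SNV between the
#' reference and alternate sequence, against a background of windows whose
#' composition is identical except that a small interval containing the
#' SNV is shuffled. `zscore = (E(alt) - mean(background)) / sd(background)`.
#'
#' @param transcript_seq transcript (cDNA) sequence, 5' to 3'.
#' @param snv_pos 1-based position of the SNV in `transcript_seq`.
#' @param alt_base the alternate base.
#' @param window_nt window width centered on the SNV (truncated at
#'   transcript ends).
#' @param interval_nt width of the shuffled interval around the SNV.
#' @param n_background number of shuffled background windows.
#' @param seed RNG seed for the shuffles.
#' @param energy_fn function(character) -> numeric energy.
#' @return list: `delta_energy` (alt - ref), `zscore` (NA when the
#'   background is degenerate), `energy_ref`, `energy_alt`,
#'   `background_mean`, `background_sd`.
#' @export
ssnv_energy_zscore <- function(transcript_seq, snv_pos, alt_base,
                               window_nt = 51, interval_nt = 5,
                               n_background = 100, seed = 1,
                               energy_fn = pairing_energy) {
  s <- strsplit(toupper(transcript_seq), "")[[1]]
  stopifnot(snv_pos >= 1, snv_pos <= length(s))
  half <- (window_nt - 1) %/% 2
  lo <- max(1, snv_pos - half); hi <- min(length(s), snv_pos + half)
  wref <- s[lo:hi]
  center <- snv_pos - lo + 1L
  walt <- wref; walt[center] <- toupper(alt_base)
  e_ref <- energy_fn(paste(wref, collapse = ""))
  e_alt <- energy_fn(paste(walt, collapse = ""))
  ihalf <- (interval_nt - 1) %/% 2
  ilo <- max(1, center - ihalf); ihi <- min(length(wref), center + ihalf)
  set.seed(seed)
  bg <- vapply(seq_len(n_background), function(k) {
    w <- wref
    w[ilo:ihi] <- sample(w[ilo:ihi])
    energy_fn(paste(w, collapse = ""))
  }, numeric(1))
  m <- mean(bg); sdev <- sd(bg)
  list(delta_energy = e_alt - e_ref,
       zscore = if (is.na(sdev) || sdev == 0) NA_real_
                else (e_alt - m) / sdev,
       energy_ref = e_ref, energy_alt = e_alt,
       background_mean = m, background_sd = sdev)
}

#' Codon-usage cluster shift of a synonymous codon change
#'
#' Codons are embedded as (scaled position, usage frequency) points and
#' clustered by k-means fitted on the reference transcript; the alternate
#' transcript's centroids reuse the reference memberships (only the mutated
#' codon's usage coordinate moves), and the score is the largest centroid
#' displacement. With `include_position = FALSE` the embedding is usage
#' frequency alone (sorted before clustering, so the score is invariant to
#' codon order).
#'
#' @param codons_ref,codons_alt character vectors of codons (equal length,
#'   differing at exactly one position for a single synonymous change).
#' @param usage named numeric: usage frequency per codon.
#' @param k number of clusters.
#' @param include_position include the scaled codon index in the embedding.
#' @param seed seed for k-means initialization.
#' @return list: `shift` (max centroid displacement), `changed_index`.
#' @export
codon_usage_shift <- function(codons_ref, codons_alt, usage, k = 3,
                              include_position = TRUE, seed = 1) {
  stopifnot(length(codons_ref) == length(codons_alt))
  n <- length(codons_ref)
  if (n < k) return(list(shift = NA_real_, changed_index = NA_integer_))
  diff_idx <- which(codons_ref != codons_alt)
  u_ref <- unname(usage[codons_ref]); u_alt <- unname(usage[codons_alt])
  if (anyNA(u_ref) || anyNA(u_alt)) stop("codon absent from usage table")
  if (include_position) {
    X_ref <- cbind(seq_len(n) / n, u_ref)
    X_alt <- cbind(seq_len(n) / n, u_alt)
  } else {
    ord <- order(u_ref)
    X_ref <- cbind(u_ref[ord]); X_alt <- cbind(u_alt[ord])
  }
  set.seed(seed)
  if (k == 1) {
    c_ref <- colMeans(X_ref); c_alt <- colMeans(X_alt)
    return(list(shift = sqrt(sum((c_ref - c_alt)^2)),
                changed_index = if (length(diff_idx)) diff_idx else NA))
  }
  km <- kmeans(X_ref, centers = k, nstart = 5)
  c_ref <- km$centers
  c_alt <- c_ref
  for (j in seq_len(k)) {
    members <- km$cluster == j
    c_alt[j, ] <- colMeans(X_alt[members, , drop = FALSE])
  }
  disp <- sqrt(rowSums((c_ref - c_alt)^2))
  list(shift = max(disp),
       changed_index = if (length(diff_idx)) diff_idx else NA)
}

.pwm_logodds <- function(counts, pseudo = 0.25) {
  # counts: 4 x width matrix (A, C, G, T rows) of base frequencies
  p <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  log2(p / 0.25)
}

#' Built-in first-order donor splice-site scoring matrix (9-mer)
#'
#' Positions -3..-1 exonic, +1..+6 intronic, consensus (C/A)AG | GTAAGT.
#' Intended for testing and as a template; production max-entropy tables
#' can be supplied to [splice_delta_logodds()] in the same matrix form.
#' @export
default_donor_pwm <- function() {
  cons <- c("M", "A", "G", "G", "T", "A", "A", "G", "T")
  .consensus_pwm(cons)
}

#' Built-in first-order acceptor splice-site scoring matrix (23-mer)
#'
#' 20 intronic positions (polypyrimidine tract + AG) followed by 3 exonic.
#' @export
default_acceptor_pwm <- function() {
  cons <- c(rep("Y", 18), "A", "G", "N", "N", "N")
  .consensus_pwm(cons)
}

.consensus_pwm <- function(cons, strength = 8) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(1, 4, length(cons), dimnames = list(bases, NULL))
  for (i in seq_along(cons)) {
    hit <- switch(cons[i], A = "A", C = "C", G = "G", T = "T",
                  M = c("A", "C"), Y = c("C", "T"), R = c("A", "G"),
                  N = bases)
    counts[hit, i] <- counts[hit, i] + strength / length(hit)
  }
  .pwm_logodds(counts, pseudo = 0)
}

.scan_pwm <- function(s, pwm, positions) {
  # best score among windows covering each position in `positions`
  w <- ncol(pwm)
  n <- length(s)
  best <- -Inf
  starts <- max(1, min(positions) - w + 1):min(n - w + 1, max(positions))
  for (st in starts) {
    idx <- cbind(match(s[st:(st + w - 1)], rownames(pwm)), seq_len(w))
    if (anyNA(idx[, 1])) next
    best <- max(best, sum(pwm[idx]))
  }
  best
}

#' Splice-site creation/disruption score of an SNV
#'
#' Scans every donor- and acceptor-model window overlapping the SNV in the
#' reference and alternate sequence; the delta is the change in the best
#' (maximum) log-odds score per model. A site is created when the alternate
#' best score crosses the odds threshold from below, and disrupted when the
#' reference best score crosses from above.
#'
#' @param context_ref,context_alt character strings; equal length, differing
#'   at `snv_offset`.
#' @param snv_offset 1-based position of the SNV within the context.
#' @param donor_pwm,acceptor_pwm 4 x width log-odds matrices with rownames
#'   A, C, G, T.
#' @param threshold log-odds threshold defining a predicted site.
#' @return list per model (`donor`, `acceptor`): `delta`, `ref_best`,
#'   `alt_best`, `created`, `disrupted`; models whose window does not fit
#'   the context are `NULL`.
#' @export
splice_delta_logodds <- function(context_ref, context_alt, snv_offset,
                                 donor_pwm = default_donor_pwm(),
                                 acceptor_pwm = default_acceptor_pwm(),
                                 threshold = 4) {
  sr <- strsplit(toupper(context_ref), "")[[1]]
  sa <- strsplit(toupper(context_alt), "")[[1]]
  stopifnot(length(sr) == length(sa))
  one <- function(pwm) {
    if (length(sr) < ncol(pwm)) return(NULL)
    rb <- .scan_pwm(sr, pwm, snv_offset)
    ab <- .scan_pwm(sa, pwm, snv_offset)
    list(delta = ab - rb, ref_best = rb, alt_best = ab,
         created = ab > threshold && rb <= threshold,
         disrupted = rb > threshold && ab <= threshold)
  }
  list(donor = one(donor_pwm), acceptor = one(acceptor_pwm))
}
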