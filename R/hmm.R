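# Six-state inheritance-state HMM.
#
# States: the four Mendelian inheritance states (identical,
# paternal-identical, maternal-identical, nonidentical) plus two error
# states — "compression" (collapsed structural variation, manifest as runs
# of uniformly heterozygous assortments) and "mie_rich" (systematic
# sequencing/mapping error, manifest as runs enriched for Mendelian
# inheritance errors). Decoding is by Viterbi so that blocks are contiguous
# by construction; ties are broken toward remaining in the current state.

#' HMM parameters for inheritance-state decoding
#'
#' @param emission_epsilon probability that a site inside a Mendelian state
#'   shows an assortment inconsistent with that state (genotype error).
#' @param recomb_rate_per_bp expected crossover intensity per bp per meiosis
#'   (default 1.2e-8, i.e. ~1.2 cM/Mbp). Between adjacent sites separated by
#'   d bp a parent's sharing relation flips with the probability that an odd
#'   number of crossovers occurred in that parent's two meioses,
#'   (1 - exp(-4 d r)) / 2.
#' @param error_state_entry per-site prior probability of entering each
#'   error state.
#' @param error_state_exit per-site probability of leaving an error state.
#' @param mie_emission_boost probability of an MIE assortment inside an
#'   MIE-rich block.
#' @param het_emission_boost probability of a uniformly heterozygous
#'   assortment inside a compression block.
#' @param het_background baseline probability of a uniformly heterozygous
#'   assortment inside Mendelian states (uniform hets are consistent with
#'   all four states and genuinely common; without a baseline the
#'   compression state could never be preferred).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(emission_epsilon = 0.005,
                       recomb_rate_per_bp = 1.2e-8,
                       error_state_entry = 1e-4,
                       error_state_exit = 1e-2,
                       mie_emission_boost = 0.3,
                       het_emission_boost = 0.5,
                       het_background = 0.15) {
  p <- list(emission_epsilon = emission_epsilon,
            recomb_rate_per_bp = recomb_rate_per_bp,
            error_state_entry = error_state_entry,
            error_state_exit = error_state_exit,
            mie_emission_boost = mie_emission_boost,
            het_emission_boost = het_emission_boost,
            het_background = het_background)
  vals <- unlist(p)
  if (any(vals <= 0 | vals >= 1)) stop("all HMM parameters must be in (0, 1)")
  class(p) <- "hmm_params"
  p
}

# per-site log emission for the 6 states; obs categories:
#   "mie", "uhet", "none" (missing/uninformative), or a consistent-state set
.emission_loglik <- function(sites, params) {
  cls <- classify_assortment(sites)
  eps <- params$emission_epsilon
  u <- params$het_background
  boost_m <- params$mie_emission_boost
  boost_h <- params$het_emission_boost
  n <- nrow(sites)
  E <- matrix(0, n, 6L, dimnames = list(NULL, ALL_STATES))
  miss <- cls$is_uninformative &
    (is.na(sites$gF) | is.na(sites$gM) | is.na(sites$gC1) | is.na(sites$gC2))
  for (i in seq_len(n)) {
    if (miss[i]) next  # emitted with probability 1 in every state
    if (cls$is_mie[i]) {
      E[i, MENDELIAN_STATES] <- log(eps / 2)
      E[i, "compression"] <- log(0.05)
      E[i, "mie_rich"] <- log(boost_m)
    } else if (cls$is_uniform_het[i]) {
      E[i, MENDELIAN_STATES] <- log(u)
      E[i, "compression"] <- log(boost_h)
      E[i, "mie_rich"] <- log(0.05)  # errors rarely mimic uniform hets
    } else {
      cons <- cls$consistent[[i]]
      E[i, MENDELIAN_STATES] <- ifelse(MENDELIAN_STATES %in% cons,
                                       log(1 - eps - u), log(eps / 2))
      E[i, "compression"] <- log(1 - boost_h - 0.05)
      E[i, "mie_rich"] <- log(1 - boost_m - 0.05)
    }
  }
  E
}

# 6x6 log transition matrix for a gap of d bp
.transition_logmat <- function(d, params) {
  r <- params$recomb_rate_per_bp
  qp <- (1 - exp(-4 * d * r)) / 2   # parent sharing-relation flip prob
  entry <- params$error_state_entry
  exit <- params$error_state_exit
  A <- matrix(0, 6, 6, dimnames = list(ALL_STATES, ALL_STATES))
  base <- 1 - 2 * entry
  for (i in seq_len(4)) for (j in seq_len(4)) {
    flips <- sum(STATE_SHARING[i, ] != STATE_SHARING[j, ])
    A[i, j] <- base * qp^flips * (1 - qp)^(2 - flips)
  }
  A[1:4, "compression"] <- entry
  A[1:4, "mie_rich"] <- entry
  for (e in c("compression", "mie_rich")) {
    A[e, 1:4] <- exit / 4
    A[e, e] <- 1 - exit - entry
    A[e, setdiff(c("compression", "mie_rich"), e)] <- entry
  }
  log(A)
}

#' Decode the inheritance-state sequence of a quartet chromosome
#'
#' Viterbi decoding of the six-state HMM over sorted sites of one or more
#' chromosomes (chromosomes are decoded independently). Mendelian-to-
#' Mendelian transition probabilities depend on the physical gap between
#' adjacent sites through the crossover intensity.
#'
#' @param sites a [quartet_sites] table.
#' @param params an [hmm_params()] list.
#' @return data.frame of state blocks: `chrom`, `state`, `first_index`,
#'   `last_index` (row indices into `sites`), `first_pos`, `last_pos`,
#'   `n_sites`. The per-site decoded path is attached as attribute `path`,
#'   and its Viterbi log-probability as attribute `logprob`.
#' @export
decode_states <- function(sites, params = hmm_params()) {
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(0), state = character(0),
                      first_index = integer(0), last_index = integer(0),
                      first_pos = integer(0), last_pos = integer(0),
                      n_sites = integer(0)))
  blocks <- list()
  path_all <- character(nrow(sites))
  logprob <- 0
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    s <- sites[idx, , drop = FALSE]
    if (is.unsorted(s$pos)) stop("sites must be sorted by position")
    E <- .emission_loglik(s, params)
    n <- nrow(s)
    k <- 6L
    # initial distribution: Mendelian states equiprobable, small error prior
    init <- log(c(rep((1 - 2 * params$error_state_entry) / 4, 4),
                  rep(params$error_state_entry, 2)))
    V <- init + E[1L, ]
    back <- matrix(0L, n, k)
    for (t in seq_len(n)[-1]) {
      d <- s$pos[t] - s$pos[t - 1L]
      lA <- .transition_logmat(d, params)
      cand <- V + lA  # cand[i, j]: from i to j
      for (j in seq_len(k)) {
        col <- cand[, j]
        m <- max(col)
        best <- which(col >= m - 1e-12)
        pick <- if (j %in% best) j else best[1L]  # tie: prefer staying
        back[t, j] <- pick
        col_m <- col[pick]
        V[j] <- col_m + E[t, j]
      }
    }
    end_state <- which.max(V)
    logprob <- logprob + max(V)
    path <- integer(n)
    path[n] <- end_state
    if (n > 1) for (t in rev(seq_len(n - 1L))) path[t] <- back[t + 1L, path[t + 1L]]
    path_all[idx] <- ALL_STATES[path]
    r <- rle(ALL_STATES[path])
    last <- cumsum(r$lengths)
    first <- c(1L, head(last, -1L) + 1L)
    blocks[[chrom]] <- data.frame(
      chrom = chrom, state = r$values,
      first_index = idx[first], last_index = idx[last],
      first_pos = s$pos[first], last_pos = s$pos[last],
      n_sites = r$lengths, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "path") <- path_all
  attr(out, "logprob") <- logprob
  out
}

#' Log-probability of a given state path under the HMM
#'
#' Used to check Viterbi optimality against the simulator's truth path.
#'
#' @param sites a [quartet_sites] table (single chromosome).
#' @param path character vector of states, one per site.
#' @param params an [hmm_params()].
#' @export
path_loglik <- function(sites, path, params = hmm_params()) {
  stopifnot(length(path) == nrow(sites), length(unique(sites$chrom)) <= 1L)
  E <- .emission_loglik(sites, params)
  st <- match(path, ALL_STATES)
  init <- log(c(rep((1 - 2 * params$error_state_entry) / 4, 4),
                rep(params$error_state_entry, 2)))
  ll <- init[st[1]] + E[1, st[1]]
  for (t in seq_len(nrow(sites))[-1]) {
    lA <- .transition_logmat(sites$pos[t] - sites$pos[t - 1], params)
    ll <- ll + lA[st[t - 1], st[t]] + E[t, st[t]]
  }
  ll
}

#' Flag sites falling in error-prone (MIE-rich or compression) blocks
#'
#' Decoded error blocks are padded by `pad_bp` on each side before masking:
#' an error-prone region's boundary is only localized to the nearest
#' decodable signal (an inconsistent or uniformly heterozygous assortment),
#' and errors that happen to produce Mendelian-consistent assortments
#' cluster just beyond it.
#'
#' @param blocks output of [decode_states()].
#' @param sites the [quartet_sites] the blocks were decoded from.
#' @param pad_bp bp added to each side of every decoded error block.
#' @return list with `mask` (logical per site, TRUE = error-prone) and
#'   `fraction` (fraction of variant positions in error-prone blocks).
#' @export
flag_error_prone_sites <- function(blocks, sites, pad_bp = 5000) {
  mask <- logical(nrow(sites))
  err <- blocks[blocks$state %in% c("compression", "mie_rich"), ,
                drop = FALSE]
  for (k in seq_len(nrow(err))) {
    on_chr <- sites$chrom == err$chrom[k]
    mask[on_chr & sites$pos >= err$first_pos[k] - pad_bp &
           sites$pos <= err$last_pos[k] + pad_bp] <- TRUE
  }
  list(mask = mask,
       fraction = if (nrow(sites) > 0) mean(mask) else 0)
}

#' Calibrate a genotype-quality cutoff against orthogonal truth genotypes
#'
#' Finds the smallest quality cutoff at which the discordance rate between
#' retained calls and an orthogonal truth subset falls below a target,
#' reporting the full discordance/retention curve.
#'
#' @param sites a [quartet_sites] table.
#' @param truth_subset data.frame with `chrom`, `pos`, `sample` (one of
#'   "F", "M", "C1", "C2") and `genotype` — genotypes from an orthogonal
#'   technology for a subset of sites.
#' @param target maximum tolerated discordance rate among retained calls.
#' @param cutoffs candidate cutoffs (default 0..60).
#' @return list with `cutoff` and `curve` (data.frame: cutoff, discordance,
#'   retention).
#' @export
calibrate_quality_threshold <- function(sites, truth_subset, target = 1e-3,
                                        cutoffs = 0:60) {
  stopifnot(nrow(truth_subset) > 0)
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(truth_subset$chrom, truth_subset$pos), key)
  if (anyNA(idx)) stop("truth subset contains sites absent from the call set")
  gcol <- paste0("g", truth_subset$sample)
  qcol <- paste0("q", truth_subset$sample)
  call_gt <- mapply(function(i, cl) sites[[cl]][i], idx, gcol)
  call_q <- mapply(function(i, cl) sites[[cl]][i], idx, qcol)
  discordant <- !is.na(call_gt) & call_gt != truth_subset$genotype
  if (!any(discordant)) {
    warning("truth subset contains no discordant calls; cutoff 0")
    curve <- data.frame(cutoff = cutoffs, discordance = 0,
                        retention = vapply(cutoffs, function(cc)
                          mean(call_q >= cc, na.rm = TRUE), numeric(1)))
    return(list(cutoff = 0, curve = curve))
  }
  curve <- do.call(rbind, lapply(cutoffs, function(cc) {
    keep <- !is.na(call_q) & call_q >= cc
    data.frame(cutoff = cc,
               discordance = if (any(keep)) mean(discordant[keep]) else NA,
               retention = mean(keep))
  }))
  ok <- !is.na(curve$discordance) & curve$discordance < target
  cutoff <- if (any(ok)) curve$cutoff[which(ok)[1]] else max(cutoffs)
  list(cutoff = cutoff, curve = curve)
}
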