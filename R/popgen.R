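# Population-genetic summary statistics: MIE rates, call-set concordance,
# and Watterson's theta.

#' Mendelian inheritance error rate of a quartet call set
#'
#' @param sites a [quartet_sites] table.
#' @return list with `n_mie`, `n_variants`, `rate` (per variant) and
#'   `rate_per_10k`. With zero variants the rates are `NA`.
#' @export
mie_rate <- function(sites) {
  n <- nrow(sites)
  if (n == 0L)
    return(list(n_mie = 0L, n_variants = 0L, rate = NA_real_,
                rate_per_10k = NA_real_))
  is_mie <- classify_assortment(sites)$is_mie
  n_mie <- sum(is_mie)
  list(n_mie = n_mie, n_variants = n, rate = n_mie / n,
       rate_per_10k = 1e4 * n_mie / n)
}

#' Relative increase of one rate over another, in percent
#'
#' `100 * (rate_a - rate_b) / rate_b`, rounded to the nearest integer for
#' reporting (the `percent_exact` element carries the unrounded value).
#'
#' @param rate_a,rate_b rates on a common scale; `rate_b` must be positive.
#' @export
relative_rate_increase <- function(rate_a, rate_b) {
  if (rate_b <= 0) stop("rate_b must be positive")
  pct <- 100 * (rate_a - rate_b) / rate_b
  list(percent = round(pct), percent_exact = pct)
}

#' Concordance between two genotype call sets
#'
#' Fraction of compared genotypes that agree; pairs with a missing genotype
#' in either set are excluded from the denominator. Symmetric in its two
#' arguments.
#'
#' @param calls,truth_calls equal-length genotype vectors (or data frames
#'   with identical layout whose genotype columns are compared cell-wise).
#' @return list with `n_concordant`, `n_compared`, `fraction`, and
#'   `percent` rounded to 1 decimal.
#' @export
concordance_rate <- function(calls, truth_calls) {
  a <- unlist(calls, use.names = FALSE)
  b <- unlist(truth_calls, use.names = FALSE)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(list(n_concordant = 0L, n_compared = 0L,
                            fraction = NA_real_, percent = NA_real_))
  conc <- sum(a[ok] == b[ok])
  list(n_concordant = conc, n_compared = sum(ok),
       fraction = conc / sum(ok),
       percent = round(100 * conc / sum(ok), 1))
}

#' Watterson's estimator of the population mutation rate
#'
#' theta per bp = S / (a_n * L), with a_n the (n-1)-th harmonic number over
#' the number of sampled haplotypes.
#'
#' @param S segregating-site count.
#' @param n_haplotypes number of sampled haplotypes (for a quartet the four
#'   parental haplotypes; the children are non-independent recombinants of
#'   them, so the default analyses use n = 4).
#' @param L callable sequence length in bp.
#' @return list with `S`, `n_haplotypes`, `L`, `a_n`, `theta_per_bp`.
#' @export
watterson_theta <- function(S, n_haplotypes, L) {
  if (n_haplotypes < 2) stop("n_haplotypes must be at least 2")
  stopifnot(S >= 0, L > 0)
  a_n <- sum(1 / seq_len(n_haplotypes - 1))
  list(S = S, n_haplotypes = n_haplotypes, L = L, a_n = a_n,
       theta_per_bp = S / (a_n * L))
}
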