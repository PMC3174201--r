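# Synthetic quartet generator.
#
# Emulates the statistical structure of a sequenced nuclear quartet: founder
# haplotypes with linkage disequilibrium from a first-order copying process,
# Poisson crossovers concentrated in recombination hotspots, genotype
# observation with clustered (MIE-rich) errors, quality scores correlated
# with correctness, and compression regions of uniform heterozygosity.
# Every stage of the pipeline can be scored against the returned ground
# truth.

#' Configuration for the synthetic quartet generator
#'
#' Defaults emulate the variant-site statistics of deep-coverage quartet
#' sequencing: one polymorphic site per ~500 bp, ~50% of crossovers falling
#' in hotspots covering ~4% of the chromosome, a per-genotype error rate of
#' 1e-3 with 60% of errors concentrated in 10-50 kbp clusters, and
#' compression regions forcing uniform heterozygosity.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_chromosomes number of independent chromosomes to simulate.
#' @param site_density expected polymorphic sites per bp.
#' @param alt_freq_distribution function(n) drawing per-site population
#'   alternate-allele frequencies.
#' @param n_ancestral size of the ancestral haplotype pool the founders
#'   and LD panel are mosaics of (small pool = strong haplotype-block LD).
#' @param ld_block_strength probability an ancestral-pool allele column is
#'   carried over unchanged to the next site; runs of carried columns form
#'   haplotype blocks in near-perfect mutual LD.
#' @param ld_strength per-site probability that the haplotype copying
#'   process keeps its current template (controls LD decay).
#' @param copy_mutation probability a copied allele is redrawn from the
#'   site frequency (controls maximal r-squared).
#' @param crossover_rate expected crossovers per meiosis per chromosome.
#' @param hotspot_map interval table (see [intervals()]) with rate payload,
#'   or `NULL` to auto-place 2 kbp hotspots every 50 kbp (4% coverage).
#' @param hotspot_mass fraction of crossovers falling inside hotspots.
#' @param base_error_rate per-genotype error probability.
#' @param error_cluster_fraction fraction of errors placed in clusters.
#' @param cluster_length_range bp range of error-cluster lengths.
#' @param compression_regions interval table, or `NULL` to auto-place one
#'   25 kbp region per 2.5 Mbp.
#' @param quality_correct,quality_error `c(mean, sd)` of genotype quality
#'   for correct and erroneous genotypes (clipped to [1, 60]).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 5e6,
                       n_chromosomes = 1L,
                       site_density = 1 / 500,
                       alt_freq_distribution = function(n) runif(n, 0.05, 0.95),
                       n_ancestral = 6L,
                       ld_block_strength = 0.98,
                       ld_strength = 0.98,
                       copy_mutation = 0.02,
                       crossover_rate = 2,
                       hotspot_map = NULL,
                       hotspot_mass = 0.5,
                       base_error_rate = 1e-3,
                       error_cluster_fraction = 0.6,
                       cluster_length_range = c(1e4, 5e4),
                       compression_regions = NULL,
                       quality_correct = c(45, 8),
                       quality_error = c(12, 6),
                       seed = 1L) {
  cfg <- list(chrom_length = chrom_length, n_chromosomes = n_chromosomes,
              site_density = site_density,
              alt_freq_distribution = alt_freq_distribution,
              n_ancestral = as.integer(n_ancestral),
              ld_block_strength = ld_block_strength,
              ld_strength = ld_strength, copy_mutation = copy_mutation,
              crossover_rate = crossover_rate, hotspot_map = hotspot_map,
              hotspot_mass = hotspot_mass,
              base_error_rate = base_error_rate,
              error_cluster_fraction = error_cluster_fraction,
              cluster_length_range = cluster_length_range,
              compression_regions = compression_regions,
              quality_correct = quality_correct,
              quality_error = quality_error, seed = as.integer(seed))
  probs <- c(ld_strength, ld_block_strength, copy_mutation, hotspot_mass,
             base_error_rate, error_cluster_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (chrom_length <= 0) stop("chrom_length must be positive")
  class(cfg) <- "sim_config"
  cfg
}

.default_hotspots <- function(chrom, L) {
  starts <- seq(25000L, L - 2000L, by = 50000L)
  intervals(chrom, starts, starts + 2000L, rate = 15)
}

.empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             rate = numeric(0))
}

.default_compression <- function(chrom, L) {
  n <- max(0L, floor(L / 2.5e6))
  if (n == 0L) return(.empty_intervals())
  starts <- as.integer(seq(L * 0.3, L * 0.9, length.out = n))
  intervals(chrom, starts, starts + 25000L)
}

# Founder/panel haplotype model: every haplotype is a first-order mosaic
# copy of a small ancestral pool. The pool's alleles are independent
# Bernoulli(f) draws per site; a copying haplotype keeps its template with
# probability ld_strength per site and redraws from the site frequency with
# probability copy_mutation. A small pool gives haplotype-block LD (high
# local r-squared, both D signs) with exact marginal frequencies and no
# urn-style frequency drift.
.ancestral_pool <- function(m, f, persist) {
  n <- length(f)
  pool <- matrix(0L, m, n)
  pool[, 1] <- rbinom(m, 1L, f[1])
  fresh <- c(TRUE, runif(n - 1) >= persist)
  for (i in seq_len(n)[-1]) {
    pool[, i] <- if (fresh[i]) rbinom(m, 1L, f[i]) else pool[, i - 1L]
  }
  pool
}

.mosaic_haps <- function(pool, k, f, rho, mut) {
  n <- length(f)
  m <- nrow(pool)
  out <- matrix(0L, k, n)
  for (h in seq_len(k)) {
    switch_pt <- runif(n) < (1 - rho)
    switch_pt[1L] <- TRUE
    seg <- cumsum(switch_pt)
    templates <- sample.int(m, max(seg), replace = TRUE)
    tmpl <- templates[seg]
    allele <- pool[cbind(tmpl, seq_len(n))]
    redraw <- runif(n) < mut
    allele[redraw] <- rbinom(sum(redraw), 1L, f[redraw])
    out[h, ] <- allele
  }
  out
}

.draw_crossover_positions <- function(n_co, L, hotspots, hotspot_mass) {
  if (n_co == 0L) return(numeric(0))
  in_hot <- if (nrow(hotspots) > 0) runif(n_co) < hotspot_mass
            else rep(FALSE, n_co)
  pos <- numeric(n_co)
  if (any(in_hot)) {
    w <- (hotspots$end - hotspots$start) *
      ifelse(is.na(hotspots$rate), 1, hotspots$rate)
    idx <- sample.int(nrow(hotspots), sum(in_hot), replace = TRUE,
                      prob = w)
    pos[in_hot] <- hotspots$start[idx] +
      runif(sum(in_hot)) * (hotspots$end[idx] - hotspots$start[idx])
  }
  pos[!in_hot] <- runif(sum(!in_hot)) * L
  sort(pos)
}

.gt_from_alleles <- function(a1, a2) GENOTYPES[a1 + a2 + 1L]

#' Simulate a family quartet with known ground truth
#'
#' Generates founder haplotypes by a first-order copying process (tunable
#' LD), transmits them through four meioses with hotspot-concentrated
#' Poisson crossovers, and observes genotypes with clustered errors,
#' quality-correlated scores, and compression regions.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (a [quartet_sites] table) and `truth`
#'   (class `sim_truth`): founder haplotypes, transmitted haplotype
#'   mosaics, exact crossover positions, injected error sites, compression
#'   sites, true genotypes and the per-site allele frequencies.
#' @export
simulate_quartet <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  per_chrom <- lapply(chrom_names, function(chrom)
    .simulate_one_chrom(chrom, config))
  sites <- do.call(rbind, lapply(per_chrom, `[[`, "sites"))
  class(sites) <- c("quartet_sites", "data.frame")
  rownames(sites) <- NULL
  truth <- list(
    founders = lapply(per_chrom, `[[`, "founders"),
    ancestral_pool = lapply(per_chrom, `[[`, "pool"),
    transmitted = lapply(per_chrom, `[[`, "transmitted"),
    crossovers = do.call(rbind, lapply(per_chrom, `[[`, "crossovers")),
    error_sites = do.call(rbind, lapply(per_chrom, `[[`, "error_sites")),
    compression_sites = do.call(rbind,
                                lapply(per_chrom, `[[`, "compression_sites")),
    true_genotypes = do.call(rbind, lapply(per_chrom, `[[`, "true_genotypes")),
    alt_freq = lapply(per_chrom, `[[`, "alt_freq"),
    error_clusters = do.call(rbind, lapply(per_chrom, `[[`, "error_clusters")),
    chrom_names = chrom_names,
    config = config)
  names(truth$founders) <- chrom_names
  names(truth$ancestral_pool) <- chrom_names
  names(truth$transmitted) <- chrom_names
  names(truth$alt_freq) <- chrom_names
  class(truth) <- "sim_truth"
  list(sites = sites, truth = truth)
}

.simulate_one_chrom <- function(chrom, cfg) {
  L <- cfg$chrom_length
  hotspots <- cfg$hotspot_map
  if (is.null(hotspots)) hotspots <- .default_hotspots(chrom, L)
  hotspots <- hotspots[hotspots$chrom == chrom | cfg$n_chromosomes == 1L |
                         is.null(cfg$hotspot_map), , drop = FALSE]
  if (nrow(hotspots) > 0 && any(hotspots$end > L))
    stop("hotspot_map extends beyond the chromosome")
  comp <- cfg$compression_regions
  if (is.null(comp)) comp <- .default_compression(chrom, L)
  comp <- merge_intervals(comp)

  n_sites <- rpois(1L, L * cfg$site_density)
  pos <- sort(sample.int(L, min(n_sites, L)))
  n <- length(pos)
  f <- cfg$alt_freq_distribution(n)

  pool <- .ancestral_pool(cfg$n_ancestral, f, cfg$ld_block_strength)
  founders <- .mosaic_haps(pool, 4L, f, cfg$ld_strength, cfg$copy_mutation)
  rownames(founders) <- c("F1", "F2", "M1", "M2")

  meioses <- list(FC1 = 1:2, FC2 = 1:2, MC1 = 3:4, MC2 = 3:4)
  transmitted <- list()
  crossovers <- list()
  for (m in names(meioses)) {
    n_co <- rpois(1L, cfg$crossover_rate)
    co_pos <- .draw_crossover_positions(n_co, L, hotspots, cfg$hotspot_mass)
    start_idx <- sample(1:2, 1L)
    # haplotype index (1 or 2 within the parent) at each site
    flips <- findInterval(pos, co_pos)
    idx_12 <- 1L + (start_idx - 1L + flips) %% 2L
    transmitted[[m]] <- idx_12
    if (n_co > 0)
      crossovers[[m]] <- data.frame(
        chrom = chrom,
        parent = if (substr(m, 1, 1) == "F") "paternal" else "maternal",
        child = substr(m, 2, 3), position = co_pos)
  }
  hap_allele <- function(m) {
    rows <- meioses[[m]][transmitted[[m]]]
    founders[cbind(rows, seq_len(n))]
  }
  aFC1 <- hap_allele("FC1"); aFC2 <- hap_allele("FC2")
  aMC1 <- hap_allele("MC1"); aMC2 <- hap_allele("MC2")
  true_gt <- data.frame(
    chrom = chrom, pos = pos,
    gF = .gt_from_alleles(founders[1, ], founders[2, ]),
    gM = .gt_from_alleles(founders[3, ], founders[4, ]),
    gC1 = .gt_from_alleles(aFC1, aMC1),
    gC2 = .gt_from_alleles(aFC2, aMC2),
    stringsAsFactors = FALSE)

  obs <- true_gt
  # compression regions: uniform heterozygosity across the quartet
  comp_hit <- pos_in_intervals(chrom, pos, comp)
  for (g in c("gF", "gM", "gC1", "gC2")) obs[[g]][comp_hit] <- "ab"

  # error injection
  n_geno <- 4L * n
  n_err <- rbinom(1L, n_geno, cfg$base_error_rate)
  n_clustered <- round(n_err * cfg$error_cluster_fraction)
  clusters <- NULL
  err <- NULL
  eligible <- which(!comp_hit)
  if (n_clustered > 0 && length(eligible) > 0) {
    mean_len <- mean(cfg$cluster_length_range)
    sites_per_cluster <- mean_len * cfg$site_density
    n_clusters <- max(1L, round(n_clustered / (0.6 * sites_per_cluster)))
    len <- runif(n_clusters, cfg$cluster_length_range[1],
                 cfg$cluster_length_range[2])
    cl_start <- floor(runif(n_clusters) * (L - len))
    clusters <- intervals(chrom, cl_start, cl_start + ceiling(len))
    in_cl <- which(pos_in_intervals(chrom, pos, clusters) & !comp_hit)
    if (length(in_cl) > 0) {
      pick_site <- sample(in_cl, n_clustered, replace = TRUE)
      pick_sample <- sample(SAMPLES, n_clustered, replace = TRUE)
      err <- unique(data.frame(site = pick_site, sample = pick_sample))
    }
  }
  n_scatter <- n_err - n_clustered
  if (n_scatter > 0 && length(eligible) > 0) {
    pick_site <- sample(eligible, min(n_scatter, length(eligible)))
    pick_sample <- sample(SAMPLES, length(pick_site), replace = TRUE)
    err <- unique(rbind(err, data.frame(site = pick_site,
                                        sample = pick_sample)))
  }
  error_sites <- NULL
  if (!is.null(err) && nrow(err) > 0) {
    gcol <- paste0("g", err$sample)
    truegt <- mapply(function(i, cl) true_gt[[cl]][i], err$site, gcol)
    newgt <- vapply(truegt, function(g)
      sample(setdiff(GENOTYPES, g), 1L), character(1))
    for (k in seq_len(nrow(err)))
      obs[[gcol[k]]][err$site[k]] <- newgt[k]
    error_sites <- data.frame(chrom = chrom, pos = pos[err$site],
                              sample = err$sample, true_genotype = truegt,
                              observed_genotype = newgt,
                              clustered = pos_in_intervals(
                                chrom, pos[err$site],
                                if (is.null(clusters)) .empty_intervals()
                                else clusters),
                              stringsAsFactors = FALSE)
  }

  # quality scores: correlated with correctness
  clip <- function(x) pmin(60, pmax(1, x))
  q <- matrix(clip(rnorm(4L * n, cfg$quality_correct[1],
                         cfg$quality_correct[2])), nrow = n)
  colnames(q) <- SAMPLES
  if (!is.null(error_sites) && nrow(error_sites) > 0) {
    idx <- cbind(match(error_sites$pos, pos), match(error_sites$sample,
                                                    SAMPLES))
    q[idx] <- clip(rnorm(nrow(idx), cfg$quality_error[1],
                         cfg$quality_error[2]))
  }

  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, n, replace = TRUE)
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L), character(1))

  sites <- quartet_sites(chrom = chrom, pos = pos, ref = refb, alt = altb,
                         gF = obs$gF, gM = obs$gM,
                         gC1 = obs$gC1, gC2 = obs$gC2,
                         qF = q[, "F"], qM = q[, "M"],
                         qC1 = q[, "C1"], qC2 = q[, "C2"])

  list(sites = sites, founders = founders, pool = pool,
       transmitted = transmitted,
       crossovers = if (length(crossovers)) do.call(rbind, crossovers)
                    else NULL,
       error_sites = error_sites,
       compression_sites = if (any(comp_hit))
         data.frame(chrom = chrom, pos = pos[comp_hit]) else NULL,
       true_genotypes = true_gt, alt_freq = f, error_clusters = clusters)
}

#' Merge overlapping 0-based intervals
#' @param iv interval table.
#' @return merged, sorted interval table (payload dropped on merge).
#' @export
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv$chrom[k] == out$chrom[last] && iv$start[k] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[k])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a population LD panel consistent with the quartet's founders
#'
#' Extends the founder haplotypes to a larger population by the same
#' copying process used to generate them, then reports pairwise r-squared
#' and the in-phase allele pairing for site pairs within a window. The
#' founders seed the panel's ancestry, so panel LD is informative about
#' founder haplotypes — the situation population-LD phasing relies on.
#'
#' @param truth a `sim_truth` object from [simulate_quartet()].
#' @param window_bp maximum pair separation in bp (must be positive).
#' @param panel_size number of panel haplotypes.
#' @param max_neighbors for each site, at most this many nearest right-hand
#'   neighbors are paired (keeps the record count linear in sites).
#' @param min_r2 pairs below this r-squared are dropped.
#' @return data.frame with `chrom`, `pos_a`, `pos_b`, `r2`, `pair_a`,
#'   `pair_b`; the pair columns give the alleles ("a" ref / "b" alt) that
#'   co-occur on the same haplotype (the sign of D).
#' @export
simulate_ld_panel <- function(truth, window_bp = 250000, panel_size = 200L,
                              max_neighbors = 20L, min_r2 = 0.05) {
  stopifnot(inherits(truth, "sim_truth"))
  if (window_bp <= 0) stop("window_bp must be positive")
  cfg <- truth$config
  set.seed(cfg$seed + 104729L)  # decoupled from the quartet stream
  out <- list()
  for (chrom in truth$chrom_names) {
    f <- truth$alt_freq[[chrom]]
    pos <- truth$true_genotypes$pos[truth$true_genotypes$chrom == chrom]
    extra <- .mosaic_haps(truth$ancestral_pool[[chrom]],
                          max(0L, panel_size - 4L), f,
                          cfg$ld_strength, cfg$copy_mutation)
    panel <- rbind(truth$founders[[chrom]], extra)
    out[[chrom]] <- ld_from_haplotypes(panel, pos, chrom,
                                       window_bp = window_bp,
                                       max_neighbors = max_neighbors,
                                       min_r2 = min_r2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compute pairwise LD records from a haplotype matrix
#'
#' @param haps 0/1 matrix, haplotypes in rows, sites in columns.
#' @param pos 1-based site positions (columns of `haps`).
#' @param chrom chromosome label.
#' @inheritParams simulate_ld_panel
#' @export
ld_from_haplotypes <- function(haps, pos, chrom = "chr1",
                               window_bp = 250000, max_neighbors = 20L,
                               min_r2 = 0) {
  n <- ncol(haps)
  p <- colMeans(haps)
  rec <- list()
  for (off in seq_len(min(max_neighbors, n - 1L))) {
    i <- seq_len(n - off)
    j <- i + off
    ok <- (pos[j] - pos[i]) <= window_bp & p[i] > 0 & p[i] < 1 &
      p[j] > 0 & p[j] < 1
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    p11 <- colMeans(haps[, i, drop = FALSE] * haps[, j, drop = FALSE])
    D <- p11 - p[i] * p[j]
    r2 <- D^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    keep <- r2 >= min_r2
    if (!any(keep)) next
    rec[[length(rec) + 1L]] <- data.frame(
      chrom = chrom, pos_a = pos[i[keep]], pos_b = pos[j[keep]],
      r2 = r2[keep],
      pair_a = ifelse(D[keep] >= 0, "b", "b"),
      pair_b = ifelse(D[keep] >= 0, "b", "a"),
      stringsAsFactors = FALSE)
  }
  if (!length(rec))
    return(data.frame(chrom = character(0), pos_a = integer(0),
                      pos_b = integer(0), r2 = numeric(0),
                      pair_a = character(0), pair_b = character(0)))
  res <- do.call(rbind, rec)
  res[order(res$pos_a, res$pos_b), , drop = FALSE]
}
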