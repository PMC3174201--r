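# Three-tier long-range phasing.
#
# Tier 1 (trio): Mendelian deduction within each father-mother-child trio.
# Tier 2 (state): for triple-heterozygous trios with a homozygous sibling,
#   the inheritance state of the surrounding block determines which parental
#   haplotype the child shares with the sibling.
# Tier 3 (ld): remaining heterozygous sites (typically uniformly
#   heterozygous assortments) are assigned by maximizing the aggregate
#   signed r-squared with already-phased neighbors within a window, using a
#   population LD panel's in-phase allele pairings.
#
# Parents are phased in contigs according to passage of alleles to the
# children; parental contigs break at that parent's crossover windows.

.flip_allele <- function(x) ifelse(x == "a", "b", ifelse(x == "b", "a", x))

#' Phase one child's alleles from the parent-parent-child trio
#'
#' Deduces the child's paternal and maternal alleles whenever the
#' transmission is unique (at least one of the three genotypes homozygous,
#' or the child homozygous). An all-heterozygous trio is ambiguous and is
#' deferred to later tiers; a Mendelian-impossible trio is flagged.
#'
#' @param gF,gM,gC genotype codes.
#' @return list with `paternal`, `maternal` (allele "a"/"b" or NA) and
#'   `status` in phased/ambiguous/mie/missing.
#' @export
phase_trio_site <- function(gF, gM, gC) {
  if (anyNA(c(gF, gM, gC)))
    return(list(paternal = NA, maternal = NA, status = "missing"))
  fa <- unique(.allele_pair(gF)); mo <- unique(.allele_pair(gM))
  cand <- list()
  for (p in fa) for (m in mo)
    if (paste(sort(c(p, m)), collapse = "") == gC)
      cand[[length(cand) + 1L]] <- c(p, m)
  if (length(cand) == 0L)
    return(list(paternal = NA, maternal = NA, status = "mie"))
  cand <- unique(cand)
  if (length(cand) > 1L)
    return(list(paternal = NA, maternal = NA, status = "ambiguous"))
  list(paternal = cand[[1]][1], maternal = cand[[1]][2], status = "phased")
}

.trio_env <- new.env(parent = emptyenv())
.trio_table <- function() {
  if (!is.null(.trio_env$tab)) return(.trio_env$tab)
  grid <- expand.grid(gF = GENOTYPES, gM = GENOTYPES, gC = GENOTYPES,
                      stringsAsFactors = FALSE)
  tab <- lapply(seq_len(nrow(grid)), function(i)
    phase_trio_site(grid$gF[i], grid$gM[i], grid$gC[i]))
  names(tab) <- paste(grid$gF, grid$gM, grid$gC)
  .trio_env$tab <- tab
  tab
}

#' Phase a triple-heterozygous site from the inheritance state
#'
#' Applies when father, mother and the target child are heterozygous and
#' the sibling is homozygous, inside a Mendelian inheritance-state block.
#' The sibling's transmissions are forced (both its alleles are the
#' homozygous allele); the block's sharing pattern then determines which
#' parental haplotype the target child received.
#'
#' @param state one of the four Mendelian states.
#' @param sibling_gt homozygous sibling genotype ("aa" or "bb").
#' @param child_gt target child genotype (must be "ab").
#' @return list with `paternal`, `maternal`, `status`
#'   (phased/inconsistent/not_applicable).
#' @export
phase_by_state <- function(state, sibling_gt, child_gt = "ab") {
  if (!state %in% MENDELIAN_STATES || !sibling_gt %in% c("aa", "bb") ||
      child_gt != "ab")
    return(list(paternal = NA, maternal = NA, status = "not_applicable"))
  s <- substr(sibling_gt, 1, 1)
  bits <- STATE_SHARING[state, ]
  child_p <- if (bits["paternal_same"]) s else .flip_allele(s)
  child_m <- if (bits["maternal_same"]) s else .flip_allele(s)
  if (paste(sort(c(child_p, child_m)), collapse = "") != child_gt)
    return(list(paternal = NA, maternal = NA, status = "inconsistent"))
  list(paternal = child_p, maternal = child_m, status = "phased")
}

#' Phase a site by aggregate signed r-squared over phased LD neighbors
#'
#' For each orientation of the target's non-reference allele (paternal vs
#' maternal) the score sums, over phased heterozygous neighbors within the
#' window, r-squared signed by whether the orientation places the target
#' allele on the same parental haplotype as the panel's in-phase partner
#' allele. The higher-scoring orientation wins; a zero margin leaves the
#' site unphased.
#'
#' @param target_pos target site position.
#' @param neighbors data.frame with `pos` and `pat` (the neighbor's
#'   phased paternal allele, "a"/"b") for phased heterozygous neighbors.
#' @param ld LD records (`pos_a`, `pos_b`, `r2`, `pair_a`, `pair_b`) as
#'   produced by [simulate_ld_panel()] / [ld_from_haplotypes()].
#' @param window_bp neighbor window (default 250 kbp).
#' @return list with `paternal`, `maternal`, `score`, `margin`, `status`.
#' @export
phase_by_ld <- function(target_pos, neighbors, ld, window_bp = 250000) {
  if (nrow(neighbors) == 0L)
    return(list(paternal = NA, maternal = NA, score = 0, margin = 0,
                status = "no_neighbor"))
  rec_a <- ld[ld$pos_a == target_pos, , drop = FALSE]
  rec_b <- ld[ld$pos_b == target_pos, , drop = FALSE]
  # partner: neighbor allele co-occurring with the target's "b"
  rec <- rbind(
    if (nrow(rec_a)) data.frame(nb_pos = rec_a$pos_b, r2 = rec_a$r2,
      partner = ifelse(rec_a$pair_a == "b", rec_a$pair_b,
                       .flip_allele(rec_a$pair_b))),
    if (nrow(rec_b)) data.frame(nb_pos = rec_b$pos_a, r2 = rec_b$r2,
      partner = ifelse(rec_b$pair_b == "b", rec_b$pair_a,
                       .flip_allele(rec_b$pair_a))))
  if (is.null(rec) || nrow(rec) == 0L)
    return(list(paternal = NA, maternal = NA, score = 0, margin = 0,
                status = "no_neighbor"))
  rec <- rec[abs(rec$nb_pos - target_pos) <= window_bp, , drop = FALSE]
  m <- match(rec$nb_pos, neighbors$pos)
  ok <- !is.na(m)
  if (!any(ok))
    return(list(paternal = NA, maternal = NA, score = 0, margin = 0,
                status = "no_neighbor"))
  rec <- rec[ok, , drop = FALSE]
  nb_pat <- neighbors$pat[m[ok]]
  score <- sum(rec$r2 * ifelse(nb_pat == rec$partner, 1, -1))
  if (score == 0)
    return(list(paternal = NA, maternal = NA, score = 0, margin = 0,
                status = "tie"))
  if (score > 0) list(paternal = "b", maternal = "a", score = score,
                      margin = abs(score), status = "phased")
  else list(paternal = "a", maternal = "b", score = score,
            margin = abs(score), status = "phased")
}

#' Phase a quartet: trio logic, inheritance state, then population LD
#'
#' Runs the three phasing tiers over a quartet site table and assembles
#' parental phase contigs. Sites inside error-prone (compression/MIE-rich)
#' blocks are never phased. Tier precedence is strict: a site phased at an
#' earlier tier is never overwritten. Tier 3 iterates (newly phased sites
#' become neighbors) until fixpoint or `max_passes`.
#'
#' @param sites a [quartet_sites] table.
#' @param blocks inheritance-state blocks from [decode_states()]; decoded
#'   on the fly when `NULL`.
#' @param ld optional LD records for tier 3.
#' @param params HMM parameters used when `blocks` is `NULL`.
#' @param window_bp LD neighbor window in bp.
#' @param ld_min_r2 LD records below this r-squared are ignored by tier 3
#'   (weak pairs carry noisy in-phase sign estimates).
#' @param max_passes maximum tier-3 sweeps.
#' @return a `phased_quartet` data.frame: per-child paternal/maternal
#'   alleles with phasing tier, parental transmitted alleles, and phase
#'   contig ids; the contig table is attached as attribute `contigs`.
#' @export
phase_quartet <- function(sites, blocks = NULL, ld = NULL,
                          params = hmm_params(), window_bp = 250000,
                          ld_min_r2 = 0.5, max_passes = 5L) {
  if (is.null(blocks)) blocks <- decode_states(sites, params)
  path <- attr(blocks, "path")
  n <- nrow(sites)
  p <- data.frame(chrom = sites$chrom, pos = sites$pos,
                  ref = sites$ref, alt = sites$alt,
                  gF = sites$gF, gM = sites$gM,
                  gC1 = sites$gC1, gC2 = sites$gC2,
                  stringsAsFactors = FALSE)
  for (ch in c("C1", "C2")) {
    p[[paste0(ch, "_pat")]] <- NA_character_
    p[[paste0(ch, "_mat")]] <- NA_character_
    p[[paste0(ch, "_tier")]] <- "unphased"
  }
  err_mask <- flag_error_prone_sites(blocks, sites)$mask

  # tier 1: per-trio Mendelian deduction
  tab <- .trio_table()
  for (ch in c("C1", "C2")) {
    key <- paste(p$gF, p$gM, p[[paste0("g", ch)]])
    res <- tab[key]
    status <- vapply(res, function(r)
      if (is.null(r)) "missing" else r$status, character(1))
    can <- !err_mask & status == "phased"
    p[[paste0(ch, "_pat")]][can] <-
      vapply(res[can], `[[`, character(1), "paternal")
    p[[paste0(ch, "_mat")]][can] <-
      vapply(res[can], `[[`, character(1), "maternal")
    p[[paste0(ch, "_tier")]][can] <- "trio"
  }

  # tier 2: inheritance state + homozygous sibling
  for (ch in c("C1", "C2")) {
    sib <- if (ch == "C1") "C2" else "C1"
    gch <- p[[paste0("g", ch)]]; gsib <- p[[paste0("g", sib)]]
    idx <- which(!err_mask & p[[paste0(ch, "_tier")]] == "unphased" &
                   p$gF == "ab" & p$gM == "ab" & gch == "ab" &
                   gsib %in% c("aa", "bb") & path %in% MENDELIAN_STATES)
    for (i in idx) {
      r <- phase_by_state(path[i], gsib[i], "ab")
      if (r$status == "phased") {
        p[[paste0(ch, "_pat")]][i] <- r$paternal
        p[[paste0(ch, "_mat")]][i] <- r$maternal
        p[[paste0(ch, "_tier")]][i] <- "state"
      }
    }
  }

  # tier 3: aggregate-r2 LD phasing, iterated to fixpoint.
  # The LD table is turned into a per-target neighbor index once per
  # chromosome; phase_by_ld() documents the per-site scoring rule.
  # Haplotype co-occurrence evidence is only valid between sites on the
  # same physical parental haplotype, so neighbors must lie in the same
  # paternal crossover segment as the target (the paternal allele carries
  # the vote; a crossover between the sites would change which founder
  # haplotype it refers to).
  if (!is.null(ld) && nrow(ld) > 0) {
    ld <- ld[ld$r2 >= ld_min_r2, , drop = FALSE]
    xw <- extract_crossovers(blocks, sites)
    for (chrom in unique(p$chrom)) {
      ld_chr <- ld[ld$chrom == chrom, , drop = FALSE]
      if (nrow(ld_chr) == 0L) next
      bidir <- data.frame(
        target = c(ld_chr$pos_a, ld_chr$pos_b),
        nb = c(ld_chr$pos_b, ld_chr$pos_a),
        r2 = c(ld_chr$r2, ld_chr$r2),
        partner = c(ifelse(ld_chr$pair_a == "b", ld_chr$pair_b,
                           .flip_allele(ld_chr$pair_b)),
                    ifelse(ld_chr$pair_b == "b", ld_chr$pair_a,
                           .flip_allele(ld_chr$pair_a))))
      bidir <- bidir[abs(bidir$target - bidir$nb) <= window_bp, ,
                     drop = FALSE]
      nb_index <- split(bidir[c("nb", "r2", "partner")],
                        factor(bidir$target))
      on_chr <- p$chrom == chrom
      pat_breaks <- sort(unique(
        xw$right_bound[xw$chrom == chrom & xw$parent == "paternal"]))
      pat_seg <- setNames(findInterval(p$pos[on_chr], pat_breaks),
                          p$pos[on_chr])
      for (pass in seq_len(max_passes)) {
        changed <- FALSE
        for (ch in c("C1", "C2")) {
          patcol <- paste0(ch, "_pat"); matcol <- paste0(ch, "_mat")
          tiercol <- paste0(ch, "_tier")
          todo <- which(on_chr & !err_mask & p[[tiercol]] == "unphased" &
                          p[[paste0("g", ch)]] == "ab")
          if (!length(todo)) next
          phased_het <- on_chr & !is.na(p[[patcol]]) &
            p[[paste0("g", ch)]] == "ab"
          pat_by_pos <- setNames(p[[patcol]][phased_het],
                                 p$pos[phased_het])
          for (i in todo) {
            recs <- nb_index[[as.character(p$pos[i])]]
            if (is.null(recs)) next
            nb_pat <- pat_by_pos[as.character(recs$nb)]
            same_seg <- pat_seg[as.character(recs$nb)] ==
              pat_seg[[as.character(p$pos[i])]]
            ok <- !is.na(nb_pat) & !is.na(same_seg) & same_seg
            if (!any(ok)) next
            score <- sum(recs$r2[ok] * ifelse(nb_pat[ok] == recs$partner[ok],
                                              1, -1))
            if (score == 0) next
            p[[patcol]][i] <- if (score > 0) "b" else "a"
            p[[matcol]][i] <- if (score > 0) "a" else "b"
            p[[tiercol]][i] <- "ld"
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
  }

  # parental transmitted alleles: from the children's assignments, or
  # trivially when the parent is homozygous
  hom_allele <- function(g) ifelse(g == "aa", "a", ifelse(g == "bb", "b", NA))
  p$F_t1 <- ifelse(!is.na(p$C1_pat), p$C1_pat, hom_allele(p$gF))
  p$F_t2 <- ifelse(!is.na(p$C2_pat), p$C2_pat, hom_allele(p$gF))
  p$M_t1 <- ifelse(!is.na(p$C1_mat), p$C1_mat, hom_allele(p$gM))
  p$M_t2 <- ifelse(!is.na(p$C2_mat), p$C2_mat, hom_allele(p$gM))
  p$F_t1[err_mask] <- NA; p$F_t2[err_mask] <- NA
  p$M_t1[err_mask] <- NA; p$M_t2[err_mask] <- NA

  p <- build_contigs(p, blocks, sites)
  class(p) <- c("phased_quartet", "data.frame")
  p
}

#' Assemble phase contigs and assign contig ids
#'
#' Parental contigs extend while the transmission pattern to the children is
#' constant and break at that parent's crossover windows; each child's
#' paternal/maternal assignment is chromosome-wide, so children get one
#' contig per chromosome. Sites strictly inside a crossover window are
#' assigned to the left contig (they are uninformative for that parent).
#'
#' @param phased phasing data frame under construction (internal layout).
#' @param blocks inheritance-state blocks.
#' @param sites the underlying [quartet_sites].
#' @return `phased` with `F_contig`, `M_contig`, `C1_contig`, `C2_contig`
#'   columns and a `contigs` attribute
#'   (`contig_id`, `member`, `chrom`, `start`, `end`).
#' @export
build_contigs <- function(phased, blocks, sites) {
  windows <- extract_crossovers(blocks, sites)
  contigs <- list()
  next_id <- 1L
  phased$F_contig <- NA_integer_; phased$M_contig <- NA_integer_
  phased$C1_contig <- NA_integer_; phased$C2_contig <- NA_integer_
  for (chrom in unique(phased$chrom)) {
    on_chr <- phased$chrom == chrom
    for (member in c("C1", "C2")) {
      phased[[paste0(member, "_contig")]][on_chr] <- next_id
      contigs[[length(contigs) + 1L]] <- data.frame(
        contig_id = next_id, member = member, chrom = chrom,
        start = min(phased$pos[on_chr]), end = max(phased$pos[on_chr]))
      next_id <- next_id + 1L
    }
    for (parent in c("paternal", "maternal")) {
      col <- if (parent == "paternal") "F_contig" else "M_contig"
      w <- windows[windows$chrom == chrom & windows$parent == parent, ,
                   drop = FALSE]
      breaks <- sort(unique(w$right_bound))
      seg <- findInterval(phased$pos[on_chr], breaks)  # 0..k segments
      ids <- next_id + seg
      phased[[col]][on_chr] <- ids
      for (s in sort(unique(seg))) {
        sel <- phased$pos[on_chr][seg == s]
        contigs[[length(contigs) + 1L]] <- data.frame(
          contig_id = next_id + s,
          member = if (parent == "paternal") "F" else "M",
          chrom = chrom, start = min(sel), end = max(sel))
      }
      next_id <- next_id + length(breaks) + 1L
    }
  }
  attr(phased, "contigs") <- {
    ct <- do.call(rbind, contigs); rownames(ct) <- NULL; ct
  }
  phased
}
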