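---
title: "Models and methods for family-quartet genome interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for family-quartet genome interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `quartetphase`, their
assumptions, the parameters that matter, and the design choices made
where the design was genuinely open. It states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` themselves
compute.

## Allele assortments and inheritance states

A quartet site carries four genotypes coded against the reference allele
*a* (alternate *b*): `aa`, `ab`, `bb`, or missing. The four Mendelian
inheritance states describe which parental haplotypes the two siblings
share: *identical* (both parents transmitted the same haplotype to both
children), *paternal-identical*, *maternal-identical*, and
*nonidentical*. A state is consistent with an observed assortment if some
assignment of transmitted haplotype indices matching the state's sharing
pattern reproduces both children's genotypes; `classify_assortment()`
enumerates all 2^4 assignments and caches the result for the 81 genotype
vectors. An assortment consistent with no state is a Mendelian
inheritance error (MIE).

**The uniform-heterozygote convention.** Strict enumeration makes the
all-`ab` assortment consistent only with {identical, nonidentical}: under
a parent-identical state, two doubly heterozygous parents cannot produce
two heterozygous children. The package nevertheless scores uniform-het
sites as consistent with all four states, for three reasons: genotypes
cannot distinguish the two parental heterozygote orientations, so the
pattern carries no usable phase information; genotyping artifacts
(notably collapsed structural variation) concentrate at exactly these
sites; and the quartet-analysis literature treats them as
informationless. The convention is encoded once, in `classify_assortment()`,
and the test suite's brute-force oracle encodes the same convention.

## The six-state HMM

`decode_states()` adds two error states. *Compression* regions (collapsed
structural variation in the reference or the samples) manifest as runs of
uniformly heterozygous assortments; *MIE-rich* regions (systematic
sequencing or mapping failure) as runs enriched for MIEs.

**Transitions.** A parent's sharing relation flips when an odd number of
crossovers occurs in that parent's two meioses between adjacent markers;
for a gap of $d$ bp at crossover intensity $r$ per bp per meiosis the
flip probability is $(1 - e^{-4dr})/2$. The two parents flip
independently, so a both-relations change costs two flips. Error states
are entered with per-site probability `error_state_entry` (default 1e-4)
and left with `error_state_exit` (default 1e-2, i.e. an expected error
block of ~100 sites). Default $r$ = 1.2e-8 (~1.2 cM/Mbp).

**Emissions.** Within a Mendelian state a consistent assortment has mass
$1-\varepsilon-u$, an inconsistent one $\varepsilon/2$
(`emission_epsilon`, default 0.005), and a uniform-het assortment $u$
(`het_background`, default 0.15) — uniform hets are consistent with every
state and genuinely common, and without a baseline the compression state
could never be preferred. Compression emits uniform hets at 0.5
(`het_emission_boost`); MIE-rich emits MIEs at 0.3
(`mie_emission_boost`) and uniform hets at only 0.05 (errors rarely
mimic them — this keeps the consistent-site penalty inside MIE-rich low
enough that blocks extend across locally quiet stretches of an error
cluster). Missing genotypes emit with probability 1 in every state,
preserving coordinates. These parameter values are the package's own,
tuned on the simulator and exposed through `hmm_params()`.

**Decoding.** Viterbi, so blocks are contiguous by construction; ties are
broken toward remaining in the current state. Within a stretch of
uninformative markers the maximum-likelihood switch point is the largest
physical gap (larger gaps have higher flip probability); the crossover
machinery below therefore never trusts raw block edges.

**Error-region flagging.** `flag_error_prone_sites()` masks sites inside
compression/MIE-rich blocks, padded by `pad_bp` (default 5,000 bp) on
each side: an error region's boundary is only localized to the nearest
decodable signal, and errors that happen to produce Mendelian-consistent
assortments cluster just beyond it.

**Quality calibration.** `calibrate_quality_threshold()` returns the
smallest genotype-quality cutoff whose discordance against an orthogonal
truth set, among retained calls, is below a target. The bare operation
defaults to 1e-3; the pipeline and the acceptance analyses use 1e-5,
because family-based error control aims at final genotype error rates of
order 1e-6 to 1e-5 and a 1e-3 target cannot bind when the raw
per-genotype error rate is itself ~1e-3. Calibration follows error-region
exclusion (flagged regions are removed from the truth subset first).

## Crossover windows

`extract_crossovers()` removes error blocks, merges Mendelian runs left
adjacent by the removal, and emits one window per changed parental
sharing relation; an identical-to-nonidentical boundary changes both
relations and yields one paternal and one maternal window (a double
crossover between informative markers — the data cannot say more).
Window bounds snap to the last/first flanking markers whose assortment
*pins the changed parent's relation to the flanking block's own value*.
Pinning to the block's own value matters: the decoder may have absorbed a
single contradicting marker inside a block (cheaper than two extra
transitions), and an unqualified "informative" marker could then pull a
bound to the wrong side of the true breakpoint.

With informative markers scattered at mean spacing $s$, a window is the
gap between the last pre- and first post-crossover informative marker —
the sum of two exponentials, an Erlang-2 draw with median
$\approx 1.68\,s$. At the 500 bp informative spacing used in the
resolution study the predicted median is ~839 bp.

**Hotspot enrichment.** Windows are re-placed uniformly over callable
territory (widths and per-chromosome counts preserved); the p-value uses
the add-one estimator and never returns 0 — a saturated test reports
p = 1 together with a `saturated` flag. Overlap is any ≥1 bp
intersection. The expected-by-chance count is reported both as the
permutation mean and as the callable-genome fraction in hotspots.

## Three-tier phasing

Tier 1 deduces a child's parental alleles whenever the trio's genotypes
force a unique transmission. Tier 2 handles triple-heterozygous trios
with a homozygous sibling: the sibling's transmissions are forced, and
the surrounding block's sharing pattern determines which parental
haplotype the target child shares; combinations contradicting the child's
genotype are flagged, not phased. These tiers are deductive — on
error-free data they cannot produce switch errors.

Tier 3 phases remaining heterozygous sites (in practice uniform-het
assortments) by the signed aggregate-r² score: for each orientation of
the non-reference allele, sum over phased heterozygous neighbors within
`window_bp` (default 250,000) of $r^2 \cdot (\pm 1)$ according to whether
the orientation places the target allele on the same parental haplotype
as the panel's in-phase partner allele; a zero margin leaves the site
unphased. Three method choices harden this tier:

* records below `ld_min_r2` = 0.5 are ignored — weak pairs carry noisy
  in-phase sign estimates and, being numerous, can outvote a single
  reliable proxy;
* neighbors must lie in the same paternal crossover segment as the
  target — the paternal allele carries the vote, and a crossover between
  the two sites changes which physical haplotype it refers to;
* homozygous neighbors never vote: they carry the same allele on both
  haplotypes, so both orientations fit them equally.

The tier iterates (newly phased sites become neighbors) to a fixpoint,
at most 5 passes. Tier precedence is strict. Accuracy is bounded by LD
itself: at $r^2 = 0.8$ a founder haplotype carries the minority allele
combination a few percent of the time, and members of one LD block are
not independent witnesses — which is why the package's accuracy property
conditions on a *deductively phased* heterozygous proxy at $r^2 \ge 0.8$.

Parental phase contigs extend while the transmission pattern to the
children is constant and break at that parent's crossover windows; sites
strictly inside a window join the left contig (they are uninformative for
that parent). Children's paternal/maternal assignment is chromosome-wide,
so each child has one phase set per chromosome.

## The synthetic quartet generator

`simulate_quartet()` emulates, with known truth: polymorphic sites as a
Poisson process (default 1/500 bp); founder haplotypes as first-order
mosaic copies of a small ancestral pool (default 6 ancestors, template
persistence `ld_strength` = 0.98 per site, copy mutation 0.02); pool
allele columns persisting between adjacent sites with probability
`ld_block_strength` = 0.98, which creates haplotype blocks in
near-perfect internal LD with both D signs and exact marginal
frequencies; four meioses with Poisson crossovers (default 2 per meiosis
per chromosome), half falling in hotspots covering ~4% of the chromosome;
genotype errors at 1e-3 per genotype, 60% concentrated in 10–50 kbp
clusters dense enough (~0.6 errors per cluster site) that the cluster is
decodable — the clusters exist precisely to create the MIE-rich signal
the HMM is designed to detect; genotype qualities drawn from N(45, 8) for
correct and N(12, 6) for erroneous genotypes (clipped to [1, 60]);
compression regions forcing uniform heterozygosity. Crossover
interference is not modeled; positions are conditionally independent
given counts. Sex chromosomes, read-level error structure, and indel
realism are out of scope.

Two generator regimes matter for interpretation. Under the default
block-LD regime, whole LD blocks share one quartet configuration, so
informative markers arrive in clusters, and blocks in which both parents
are heterozygous throughout are *genuinely* uniformly heterozygous runs —
observationally identical to compression regions and correctly flagged
as such (the default error-prone fraction lands at a few percent of
sites). Scattered-marker analyses (the resolution study, and properties
that require informative markers everywhere) instead use
`ld_block_strength = 0` with a large pool, making sites independent. For
balanced markers ($f = 1/2$) the fraction of sites pinning a given
parent's sharing relation is exactly 5/16 by enumeration
(`expected_informative_fraction()`), which converts the 500 bp
informative-spacing condition into a site density without pilot noise.
Passing tests on this generator shows the machinery is correct under its
assumptions; it does not certify performance on real data, where LD,
error processes and coverage are richer.

`simulate_ld_panel()` extends the founders to a population panel by the
same copying process — the founders seed the panel's ancestry, so panel
r² and in-phase pairings are informative about the founders in the way
population-LD phasing assumes.

## Risk, prioritization, pharmacogenomics

Genotype likelihood ratios derive from a published odds ratio, risk-allele
frequency and prevalence under a multiplicative odds model
(`odds(D|g) = odds0 · OR^g`), with `odds0` solved by root-finding to match
the prevalence; LR(g) = P(g|case)/P(g|control). Composite LRs multiply
over LD-pruned loci (r² > 0.3 pruned to the best-powered representative);
missing genotypes contribute 1; percentiles against a cohort count ties
half. Inclusion requires replication in more than 2 studies and total n
above 2,000.

Fitch parsimony prunes gapped species with their branches, counts minimum
substitutions bottom-up, and divides by the pruned tree's total branch
length. The default mRNA energy proxy is a Nussinov-style base-pair
maximization (GC = 3, AU = 2, GU = 1, minimum loop 3; energy = −score),
pluggable via `energy_fn` for thermodynamic folders; the Z-score
background shuffles a 5 nt interval around the SNV, preserving
composition. Codon-usage shift clusters (position, usage) embeddings by
k-means fitted on the reference transcript, with alternate centroids
reusing the reference memberships so the displacement is well-defined
without cluster matching; with positions excluded the embedding is sorted
first, making the score order-invariant. Splice models are generic
log-odds matrices over fixed windows (donor 9-mer, acceptor 23-mer); the
built-in consensus PWMs are for testing and as a format template.

Star-allele calling matches each haplotype against allele definitions
(all defining variants present), defaults to \*1, resolves nested
definitions by most-specific-wins, and enumerates unphased heterozygote
assignments, calling only a unique consistent diplotype. Mixed
increased/loss-of-function diplotypes are labelled undetermined
(provisional) — their in-vivo phenotype is not settled. Warfarin dosing
evaluates a coefficient table supplied as configuration; the shipped
file carries the published IWPC pharmacogenetic algorithm (Klein et al.
2009) on the square-root-weekly-dose scale.

## Problem sizes and numerical choices

The test suite and acceptance analyses run at desk scale: 1–5 Mbp
chromosomes (up to 7 replicate chromosomes, ~70k sites, for the
resolution study), 100–10,000 Monte Carlo permutations, 500-replicate
estimator checks. Viterbi decoding is exact, in log space; the only
tolerance-bearing numeric step is the LR root-finder (`uniroot` at
1e-12). Degenerate inputs are defined explicitly: empty site lists give
empty block tables, zero-variant call sets give NA rates, saturated
permutation tests give p = 1 with a flag, zero-margin LD scores leave
sites unphased, and a truth subset without discordant calls yields cutoff
0 with a warning.

## Known limitations

* Tier-3 phasing accuracy is LD-bounded; blocks anchored only through
  weak proxies can be assigned wholesale to the wrong parent, and no
  score threshold can detect this from the data alone.
* The compression state and genuine uniformly heterozygous LD runs are
  observationally identical; under strong block LD the flagged fraction
  includes such runs by design.
* Short double-crossover segments containing few informative markers are
  invisible to any genotype-based decoder and are merged into their
  flanking blocks.
* The consequence annotator handles biallelic SNVs and simple indels
  against exon/CDS models; it does not model overlapping reading frames,
  selenoproteins, or splice-region effects beyond the 2 bp dinucleotides.
* X/Y chromosomes are excluded throughout; the assortment logic is
  autosomal.
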