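---
title: "Methods: competitive-mapping introgression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive-mapping introgression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`introgressr` detects segments of the *Saccharomyces paradoxus* genome that
have introgressed into *S. cerevisiae* strains, at gene resolution, from
**competitive mapping**: reads are aligned to a concatenated two-species
reference so that each read settles on the subgenome it matches best. A
strain carrying an introgressed segment produces coverage on the
*S. paradoxus* copy of the affected genes and loses the corresponding
coverage on the *S. cerevisiae* orthologs; the per-gene depth profile on
the two subgenomes is therefore the primary signal. Around this core the
package provides block assembly, phylogenetic validation, donor-lineage
assignment by identity-by-state (IBS), clade-level retention analysis, and
the population-genetic statistics used to characterize the host
populations (windowed π and Tajima's D, heterozygosity, pairwise IBS,
weighted Weir–Cockerham F~st~, classical MDS, and a Spearman Mantel test
of isolation by distance).

Because suitable public call sets cannot ship with a package, all logic is
exercised against a first-class synthetic-data generator
(`simulate_dataset()`) that emits the complete input bundle — subgenome
references, annotation with ortholog pairing and divergence, focal and
donor-panel VCFs, depth summaries, clade labels and geography — together
with the exact ground truth of every planted introgression.

## The gene-level calling model

For each strain, each *S. paradoxus* gene is called **introgressed** iff
all three criteria hold:

1. *Coverage*: strictly more than half of the gene's positions have depth
   exceeding 25% of the strain's median reference depth
   (`min_covered_frac = 0.5`, `depth_factor = 0.25`; both strict `>`,
   reading "over half" and "exceeding" literally).
2. *Ortholog comparison*: the gene is the deeper member of its ortholog
   pair, or its mean depth is at least 25% of the *S. cerevisiae*
   ortholog's depth (inclusive `>=`).
3. *Divergence*: the ortholog pair differs at ≥ 5% of nucleotide
   positions (inclusive). Below this, competitive mapping cannot separate
   the orthologs reliably, so such genes are never callable; genes with no
   1:1 ortholog are skipped rather than guessed.

A called gene is **heterozygous** when the depth ratio
paradoxus/cerevisiae lies in the closed interval `[0.25, 4]` — both
orthologs retain one haplotype's worth of coverage — and **homozygous**
when the ratio exceeds 4 or the cerevisiae copy has no coverage (ratio
∞). Ratios below 0.25 cannot occur for called genes (criterion 2
guarantees it), and the code asserts this rather than silently mapping it.

**Median scope.** The covered-depth threshold is defined relative to "the
median depth of the entire reference". With a two-species concatenated
reference, a strain without introgressions has essentially zero coverage
on half of that reference, which makes a literal whole-reference median
degenerate (≈ 0, or unstable at the 50% boundary) and the 25% threshold
vacuous. `summarize_gene_depths()` therefore defaults to
`median_scope = "resident"` — the median over the resident
(*S. cerevisiae*) subgenome, a robust proxy for the strain's
characteristic coverage — with `"concatenated"` available for references
where most positions are covered.

## Blocks and phylogenetic validation

Maximal runs of consecutive called genes (annotation order, one
chromosome, no gap tolerance) form **blocks**. Each block is validated by
asking whether its haplotype *groups with S. paradoxus*: the block's
variant columns are aligned against a small species panel (by default two
*S. cerevisiae* and five *S. paradoxus* representatives, mirroring common
practice for such checks), p-distances with pairwise deletion are
computed, a neighbor-joining tree is built (`ape::nj`), and the verdict is
the species of the focal haplotype's nearest panel member by patristic
distance. This operationalizes "groups with" as nearest-subtree
attachment; for star-like panels it coincides with a monophyly check while
remaining fully internal and deterministic, in place of an external
maximum-likelihood tree program. Ties within `1e-9` are *indeterminate*,
as are blocks with zero variant columns — they are retained but flagged,
never silently kept or dropped. Only non-rejected blocks proceed to donor
assignment.

## Donor-lineage assignment

Within each block, restricted to paradoxus-subgenome variants, IBS between
the focal genotype and every donor-panel strain is the per-site
shared-allele fraction `1 - |dosage_a - dosage_b|/2` averaged over
co-called sites (pairwise deletion). The block is assigned to the
**lineage of the maximum-IBS strain**; when the best values of two or more
lineages agree within `tie_tol = 1e-6` (our formalization of "equally
high"), the block stays unassigned. Assignment is computed per block — not
per gene — and propagated verbatim to every gene of the block, because a
contiguous introgressed run descends from one donor haplotype. A second,
independent route (`assign_origin_by_tree_distance()`, minimum p-distance
to the donor panel over the block alignment) is provided purely as a
concordance check on the IBS route.

## Retention patterns across clades

`build_presence_matrices()` reduces calls to a strain × gene binary matrix
and a clade × gene carrier-fraction matrix. Clade-level presence defaults
to ≥ 1 carrier strain; the threshold is exposed because both this
convention and a stricter "present in ≥ 75% of strains" convention are in
legitimate use, and they answer different questions (any retention vs
fixed retention). Overlap between clade gene sets is tested with the
one-sided hypergeometric upper tail (exact); multi-way intersections get
either an add-one permutation p-value under independent uniform draws of
same-size sets, or an exact tail computed by chaining hypergeometric
distributions (the running intersection of independent uniform sets is
Markov-hypergeometric). The test universe defaults to all ortholog-paired
genes passing the divergence rule — the set of genes that *could* have
been called — since no universe is canonically defined for such tests.
Retention profiles are clustered with average-linkage agglomeration on
Euclidean distances between clade fraction vectors; rows are pre-sorted by
clade name so tied merges resolve deterministically.

## Population-genetic statistics

All statistics are computed from allele dosages with per-site exclusion of
missing genotypes, treating each diploid as two haplotypes:

* **π** per fixed 10-kb window (0-based, half-open, anchored at position 0
  per chromosome): `sum over sites of 2j(k−j)/(k(k−1))` divided by the
  nominal window width, where `k` is called haplotypes and `j` the
  alternate count. This equals the average pairwise difference, and the
  test suite checks it against a brute-force pairwise-counting oracle.
* **Tajima's D** per window from the standard constants
  (`tajima_constants()`); `D` is undefined (`NA`, never 0) when `S = 0`.
  With missing data, the per-window haplotype count is the rounded mean of
  called haplotypes over segregating sites.
* **Heterozygosity** per strain: heterozygous calls / called variants.
* **Weighted F~st~**: the Weir–Cockerham ratio-of-sums estimator,
  `sum(a) / sum(a+b+c)` over sites with defined components. Slightly
  negative estimates are reported as-is; flooring at 0 would bias
  downstream averages.
* **Mantel test**: Spearman correlation of lower-triangle entries, null
  from simultaneous row/column permutation, one-sided
  `p = (hits + 1)/(n_perm + 1)` with floor `1/(n_perm+1)` (for the default
  9999 permutations, 1e-4). Genetic distance defaults to `1 − IBS` since
  no particular metric is canonical; any symmetric matrix is accepted.
  Geographic distance is haversine on the mean Earth radius (6371 km).
* **MDS**: classical scaling (double-centering + eigendecomposition);
  component signs are fixed by making the largest-magnitude loading
  positive so embeddings are reproducible.

Site filters follow the standard regime — depth masking (cells with
DP < 5 become missing), QUAL ≥ 30, biallelic SNPs only, ≥ 90% call rate —
in that fixed order, because depth masking changes call rates; the filters
are idempotent. The structure analyses additionally drop sites with > 1%
missingness and then strains with > 10% missingness (sites first, then
strains), and prune linkage with the greedy 50-variant/5-step/r² > 0.5
window rule. The pruning window is interpreted in variant counts (the
convention of the standard pruning tool); a base-pair unit is available
via `unit = "bp"`. Within a violating pair the later site in positional
order is dropped — deterministic and order-stable.

## The synthetic-data generator

The generator is the package's study system, and its defaults are the
reference scenario: 6 clades × 10 diploid strains, 8 chromosomes × 50
one-kb genes (≈ 0.48 Mb per subgenome), subgenome divergence 0.12 (within
the range typical of this species pair), 2 donor lineages of 3 panel
strains (2% lineage-private variation, 1% shared, 0.2% within-lineage),
2 introgression pulses with clades distributed round-robin, per-strain
private blocks at rate 2 with shifted-geometric lengths (mean 5 genes),
30% of blocks heterozygous, and mean competitive-mapping depth 150×,
comparable to deep short-read yeast datasets. Scenario presets expose 1-,
2- and 3-pulse histories without asserting any as correct, since the true
pulse history of real populations is unknown.

Design choices worth knowing:

* Donor lineages carry independent private mutations rather than an
  explicit coalescent — sufficient to make maximum-IBS assignment
  identifiable and much easier to reason about.
* Depth is summarized per gene (covered fraction + mean), because the
  caller consumes only gene-level summaries; a per-position simulator and
  BED writer exist to integration-test `summarize_gene_depths()`. Under
  the `poisson` model the gene mean is Poisson over gene positions and the
  covered fraction is binomial with the implied per-position exceedance
  probability.
* Heterozygous blocks write the donor allele as a heterozygous genotype
  into the focal VCF and split depth 50/50 between the subgenomes, so
  zygosity is recoverable from the depth ratio alone and heterozygous
  introgressions raise the strain's heterozygosity ratio.
* Strains without an introgressed segment have *missing* genotypes at
  paradoxus-subgenome sites (depth 0), exactly as competitive mapping
  would produce; donor assignment therefore runs on the unfiltered
  paradoxus matrix while population statistics use the filtered resident
  subgenome.
* Background variation on the resident subgenome is clade-structured
  (logit-normal clade frequencies around a per-site ancestral frequency)
  with a geographic-gradient term scaled by `ibd_strength`, and clade
  centroids sit on a geographic transect with within-clade jitter — so
  genetic and geographic distances correlate positively whenever
  `ibd_strength > 0`.
* All randomness flows from one config seed through fixed per-stage
  offsets; identical configs produce byte-identical files, which the
  tests verify by checksum.

What the generator does **not** emulate: read-level errors and mapping
ambiguity, recombination within blocks, indels and structural variation,
gene content differences between the species, coalescent demography, and
mitochondria. Consequently, perfect recovery on noiseless synthetic data
shows the decision rules are implemented exactly as specified, and the
Poisson-noise battery shows robustness to counting noise at realistic
depth — neither shows robustness to alignment artifacts in real data,
which is where the phylogenetic validation step earns its keep.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the default scenario
(24,000 strain × gene decisions, typically ~900 planted genes in ~170
blocks), a 5-seed Poisson battery (≥ 2,000 planted genes in total), and a
4-lineage donor-assignment scenario at 1% private divergence; these sizes
keep a full run in a few minutes on one core while leaving every rate
estimate with a denominator in the hundreds or thousands. Tolerances:
π against its oracle at 1e-12; Tajima's D fixture at 1e-3; exact
hypergeometric against full enumeration at 1e-12; NJ/patristic and IBS
tie tolerances as given above. The Mantel permutation count is 9999
wherever a p-value is reported, and 99–999 in smoke tests where only
plumbing is exercised.

## Known limitations

Breakpoints are gene-resolution only; blocks never tolerate gaps, so a
single miscalled gene splits a block. The validation panel is synthetic
(generated alongside the data) rather than a curated set of real genomes.
The multi-way overlap null assumes independent uniform sets, which
ignores within-clade correlation of retention. The Mantel genetic
distance (`1 − IBS`) and the overlap-test universe are reasonable
defaults, not claims about the uniquely correct choice; both are
parameters.
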