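---
title: "Methods: virome ecology of depth-stratified metagenomes"
author: "viroecol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome ecology of depth-stratified metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroecol)
```

## Scope and model of the data

`viroecol` analyses the viral side of an assembled, depth-stratified
aquatic metagenome.  Its inputs are products of an upstream assembly and
annotation workflow that the package deliberately does not re-run: contig
sequences with viral/provirus flags, per-contig per-sample read counts,
lysogeny-gene and AMG annotations, CRISPR arrays with detection scores,
tRNA sequences, host taxonomy lineages, defence-system calls, a
protein-similarity graph, and per-sample water chemistry (DOC, Fe, NH3,
NO3, PO4, SO4, salinity, DO).  Everything downstream of those tables —
vOTU cataloguing, normalisation, community statistics, host linkage and
AMG ecology — is computed here.

## vOTU catalogue

Viral contigs (all longer than 5 kb, the floor below which viral calls
are unreliable) are clustered greedily at 95% nucleotide identity with a
candidate/representative length ratio of at least 0.85, the CD-HIT
convention: contigs are sorted by length (ties broken lexicographically
by id, for cross-platform determinism), and each contig joins the first
cluster whose representative it matches, otherwise founds its own.  The
pairwise identity is pluggable — a precomputed table for production-scale
data, a global-alignment identity (`align_identity`) for small inputs —
because re-implementing CD-HIT's word-filter heuristics is out of scope;
the greedy rule itself is what defines the catalogue.

A vOTU is called **temperate** if any member is a provirus or carries a
lysogeny gene (integrase, recombinase, excisionase, CI/Cro repressor,
parA, parB), otherwise **lytic**.  Novelty against a reference virus set
uses per-hit coverage: a hit qualifies if its alignment covers at least
70% of either the query or the subject; the best qualifying identity sets
the tier — known (> 90%), similar (50–90%, both bounds inclusive on the
similar side), novel otherwise.  Multi-HSP coverage aggregation is
deliberately per-hit: summing disjoint HSPs can manufacture coverage that
no single alignment supports.

## Abundance and community structure

Counts are normalised to transcripts-per-million: within each sample,
count/length rates are rescaled to sum to 10^6, making columns comparable
across libraries.  The per-sample **viral fraction** is the viral TPM sum
divided by 10^6, in percent.  Diversity is the Shannon index in natural
logs (vegan's default).  Community stratification is tested by one-way
PERMANOVA on Bray–Curtis distances of vOTU TPM profiles.  The
dissimilarity is a package choice (exposed as an option): Bray–Curtis is
the standard abundance-based ecology distance and the natural partner of
a distance-based pseudo-F.  The permutation p-value uses the
(1 + b)/(1 + m) estimator so p is never zero; when the distinct label
arrangements number at most the requested permutations the null is
enumerated exhaustively and p is the exact tail proportion.  Pairwise
cluster contrasts are corrected with Benjamini–Hochberg across all
pairs — the conservative reading when only a single adjusted value is
reported upstream.  Depth-cluster overlap is summarised as Venn-region
counts with presence defined as TPM strictly above zero (no abundance
floor is imposed, since none is stated for the analysis this mirrors).

## Host linkage

Three evidence channels link vOTUs to prokaryotic hosts:

1. **CRISPR spacers** (arrays with detection score strictly above 0.4)
   are scanned against vOTU sequences, both strands, keeping matches
   whose span on the vOTU is 20–75 bp with at most one edit — one
   substitution *or* one 1-bp indel, never both, mirroring blastn
   mismatch/gap accounting at word size 7.  Coordinates are 0-based,
   half-open, plus-strand, with strand reported separately.  The matcher
   is a sliding-window Hamming scan plus single-indel variant scan in
   C++; an independent banded dynamic-programming engine
   (`engine = "dp"`) computes the same candidate set from the edit-
   distance recurrence and is compared against the scan engine on
   hundreds of random instances in the test suite.  Overlapping ±1-bp
   shadow variants of one locus are deduplicated keeping the fewest-edit
   span.
2. **tRNAs**: a viral tRNA identical over its full length (either
   strand) to a tRNA on a different contig links the two; self-hits are
   excluded.
3. **Prophage context**: a provirus inherits the lineage of its host
   flank, when classified.

The consensus assigns, per vOTU, the strict-majority phylum over all
links (ties and empty evidence leave the vOTU unassigned); this
resolution rule is the package's own, as no convention exists for
conflicting evidence.  Host *orders* are collected as sets but never
"assigned" — they feed only the AMG eligibility filter.  Per-phylum phage
and defence-system Shannon diversities are computed and related by the
same OLS machinery as the depth regression.

## AMG ecology

AMG proteins are clustered into orthologous groups (OGs) by the Markov
Cluster Algorithm at inflation 1.5 on an input similarity graph (the
all-vs-all homology search that produces the graph is upstream).  The
numeric knobs that the algorithm needs but that are rarely stated —
pruning threshold 1e-5, convergence tolerance 1e-8, 100-iteration cap,
self-loops at each node's maximum incident weight — are fixed defaults
exposed in the call.  Attractor overlaps resolve to the smallest
attractor id.

An OG's abundance in a sample is the TPM sum over its *distinct* member
vOTUs — gene copy number is ignored because abundance is measured at the
contig level.  Before interpretation, OGs pass an eligibility filter
designed to exclude correlations driven by co-encoded functions or host
effects: member genes on provirus vOTUs are dropped (member-gene rather
than whole-OG exclusion — the narrower reading of an ambiguous rule, kept
explicit here), then the OG must retain at least two vOTUs whose hosts
span at least two orders.  The chemistry screen computes Pearson r for
each OG × variable pair across all samples (replicated chemistry per
depth; correlating 12 samples rather than 6 depth means is the package's
choice and is configurable by aggregating beforehand) and retains pairs
with p < 0.05 and |r| > 0.8, both strict.  The pipeline reports the
screen for *all* OGs with eligibility as a column, because on sparse
host-annotation data the filter can silence true planted signal; the
eligible subset is what the stringent reading keeps.

Pairwise **co-occurrence** of AMG functions across vOTUs uses the exact
probabilistic model: given marginals N1 and N2 among N vOTUs, the
co-occurrence count follows the hypergeometric law
P(j) = C(N1, j) C(N−N1, N2−j) / C(N, N2); `p_gt` is the upper tail at
the observed count and a pair is significant when `p_gt` < 0.05.  The
expected-count pre-filter some implementations apply (skip pairs with
expected < 1) is off by default and reported as a column-ready quantity
(`expected`), so the caller can reproduce either convention.

## The synthetic community generator

`generate_community()` emulates the sampling design the pipeline
assumes: six depths (2, 8, 17, 18, 22, 28 m), two biological replicates
each, and three depth clusters (2 m / 8 m / 17–28 m).  Key structure:

- **Counts.**  Each vOTU is either unique to one depth cluster (exactly
  zero counts elsewhere) or shared; within its clusters its expected
  abundance is a lognormal base level times an independent lognormal
  depth factor (`abundance_dispersion`, default sd 1.0 on the log scale
  — roughly an order of magnitude of within-cluster variation, typical
  of viral relative abundances).  Counts are Poisson draws rescaled to a
  free `library_size` (sequencing depth is not modelled; no value is
  stated for the data this emulates, so it is a parameter).  Host
  contigs form an abundant background so viral fractions land in the
  single-digit-percent range seen in cellular-fraction metagenomes.
- **Sequences** are uniform-random nucleotides: downstream stages need
  exact/near-exact substring structure, not codon realism.  Multi-member
  vOTUs are built by trimming (≤ 2%) and substituting (0.5%) copies of
  the representative, keeping true identity ≥ 0.975 — safely above the
  0.95 clustering threshold — and the generator emits the exact pairwise
  identities as the precomputed table a production run would get from an
  upstream clusterer.
- **Chemistry.**  Non-planted variables follow smooth depth profiles
  (salinity and sulphate rising, oxygen falling, nutrients peaking at
  mid-depth) with relative Gaussian noise `noise_sd`.  A planted
  correlation (family f, variable v, target r) replaces v with a linear
  transform of the family's TPM trajectory plus Gaussian noise that is
  orthogonalised in-sample and scaled so the realised correlation equals
  the target exactly before the `noise_sd` term — the simplest mechanism
  that makes recovery deterministic at low noise.
- **Host links.**  Spacers (25–40 nt) are copied from single-member
  vOTUs into host CRISPR arrays with 0, 1 or 2 substitutions
  (`spacer_mutation_rate`); at ≤ 1 the matcher must recover the pair, at
  2 it must not.  tRNAs are shared verbatim; proviruses are embedded
  into host contigs whose lineage becomes the truth.  Links target
  single-member vOTUs so each planted spacer has exactly one viral
  source.  Decoy arrays (including one below the 0.4 score floor) and
  unlinked tRNAs exercise the filters.
- **AMG families** get within-family similarity edges (weights 50–100)
  and no between-family edges, so family recovery by MCL is exact;
  family 2 optionally reuses family 1's vOTUs, planting one co-occurring
  function pair (`plant_cooccurrence`).
- **Determinism.**  One RNG stream seeded from `config$seed` is consumed
  in a documented fixed order (chemistry, sequences, counts, AMG
  families, homology, planted correlations); host-link planting runs on
  a derived substream (seed + 7919) so `plant_host_links()` is
  deterministic whether called inside the generator or standalone.

What the generator does *not* emulate: sequencing error, assembly
artifacts, compositional coupling between chemistry and the microbial
background, codon structure, genome architecture, or realistic taxon
abundance distributions.  Passing tests therefore demonstrate that the
*algorithms* implement their definitions and recover planted structure —
not that the pipeline's biological conclusions transfer to real data.

## Numerical choices and degenerate inputs

- TPM columns of all-zero samples stay all-zero instead of dividing by
  zero; zero contig lengths are an error.
- Shannon of an all-zero vector and Bray–Curtis between two all-zero
  samples are errors (undefined), not silent zeros.
- PERMANOVA with every group of size one is a degenerate design error;
  an all-identical configuration (0/0 pseudo-F) reports p = 1.
- Constant vectors in the correlation screen yield `r = NA`, a warning,
  and are never retained.
- OLS with constant response returns slope 0, r² = 0, p = 1 rather than
  NaN.
- Greedy clustering ties (equal lengths) break lexicographically by id;
  MCL attractor overlaps break to the smallest id — both for
  platform-independent determinism.

## Problem sizes used by the test-suite and acceptance runs

The default synthetic community uses 40 vOTUs (56 viral contigs), 20
host contigs, 12 samples and 6 AMG families; the acceptance checks run
200 random spacer instances (sequences ≤ 5 kb × 50 spacers), all
co-occurrence margins with N ≤ 12, 600 null PERMANOVA replicates at 199
permutations, 100 seeded bundles for planted-correlation recovery and
100 random clique graphs for MCL.  These sizes keep the whole suite in
the low minutes while leaving each statistical check adequately powered
(e.g. the null-calibration standard error is below 0.01 at 600
replicates).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, planted_correlations = list(
  list(family = 1, variable = "PO4", r = -0.95)))
bundle <- generate_community(cfg)
res <- run_pipeline(bundle, out_dir = "results", seed = 1)
res$summary$votu_count
res$summary$retained_correlations
```

## Known limitations

- The spacer matcher is exact for the stated one-edit model; it does not
  reproduce blastn bit-score ranking or e-values, only the retention
  filter that consumes them.
- MCL is the textbook dense formulation; it is adequate for AMG-protein
  graphs (hundreds of nodes) but not for million-node orthology graphs.
- The consensus host rule is phylum-rank majority; finer ranks are
  parsed and stored but not voted on.
- PERMANOVA is one-way; nested or stratified designs (e.g. replicate
  within depth) are not modelled.
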