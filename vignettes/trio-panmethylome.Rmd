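---
title: "Allele-specific pan-methylome analysis on a haplotype sequence graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific pan-methylome analysis on a haplotype sequence graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmeth)
```

## The problem

Vegetatively propagated crops keep the genotype of a founder individual
essentially frozen for centuries, which makes them a natural system for
asking how stable DNA methylation is across clonal generations and how
much of a hybrid's methylome is inherited from each parent.  Answering
that question requires *allele-specific* methylation quantification in a
parent–progeny trio: two diploid parents and a hybrid whose two
haplotypes each descend from one parent.  Comparing methylation across
six haplotypes with divergent sequences is awkward on any single linear
reference — divergent regions are invisible, and C→T substitutions are
indistinguishable from unmethylated cytosines after bisulfite
conversion.  `panmeth` instead anchors every comparison on a haplotype
sequence graph: each haplotype is a named *path* through shared and
allele-specific sequence *nodes*, and the graph supplies the coordinate
system in which windows, nodes, genes and variants are compared.

The package implements the full pipeline — graph I/O and coordinate
projection, cytosine-report processing, node-level methylation
classification, windowed differential methylation with inheritance
logic, single-reference bias quantification and correction, and
gene-level classification — together with a synthetic trio generator
that produces all inputs with complete ground truth.  Every statistical
and combinatorial component is validated against that truth.

## The graph model and coordinate projection

A `sequence_graph` holds nodes (DNA segments), edges and one path per
haplotype; paths spell their haplotype byte-for-byte.  Before any
node-level comparison the graph is chopped so no node exceeds 200 bp
(`chop_nodes`), which turns nodes into approximately window-sized units
shared across haplotypes.  Chopping preserves all path sequences
exactly; this is property-tested on randomly oriented graphs.

Positions are projected between haplotypes through shared nodes
(`project_positions`): a source position is located inside a node, and
if that node occurs *exactly once* on the target path the within-node
offset is carried over (mirrored under opposite orientation).  A node
occurring more than once on the target is ambiguous, and the projection
deliberately returns nothing rather than guessing an occurrence; the
same applies to nodes absent from the target (private sequence).  On
synthetic trios, every defined projection agrees exactly with the
generator's base-level homology maps.

Pairwise variants between two paths are extracted by walking both paths
between anchor nodes (nodes single-copy on both paths):
the concatenated non-shared sequence on each side forms the two
alleles, classified as SNP, MNP, INDEL or OTHER (complex or nested
structures, e.g. a multi-copy node inside the bubble).  Variants where
both alleles agree are discarded.  INDELs of at least 50 bp are flagged
as structural variants.  Nested bubbles are not recursively decomposed.

## Cytosine reports, filtering and uniting

Methylation arrives as bismark-style per-cytosine reports covering all
three plant contexts (CG, CHG, CHH) on both strands.  On reading, the
context is recomputed from the trinucleotide and validated.  Sites with
coverage below 10 are discarded per clone; the clones of a cultivar are
then united on the intersection of their (chromosome, position, strand)
keys with strands kept separate (no destranding).  Per-clone counts are
deliberately *not* averaged at this stage because the differential test
treats clones as biological replicates.  A site counts as methylated
when its level reaches 20% (inclusive).  Median-ratio coverage
normalisation across clones is available (`normalize_coverage`) but off
by default; the simulated clones share one Poisson depth, so it only
adds rounding noise there.

## Node-level methylation classification

United profiles are projected onto the chopped graph
(`assign_sites_to_nodes`): each site falls in exactly one node of its
own path.  A node is *methylated in a haplotype* when it carries at
least one cytosine whose across-clone mean level reaches 20%.  The
node-level rule is our own definition (the window-level thresholds do
not dictate one); it is configurable, and "same methylation pattern"
between haplotypes is implemented as the same binary methylated status
per node rather than per-site pattern matching, because the quantity of
interest is the count of nodes containing methylated cytosines.

Cytosine-carrying nodes are classified from their sharing set —
haplotype presence, or the methylated haplotypes in methylation-aware
mode.  `core` means all six haplotypes; `private` means the set touches
a single cultivar; `dispensable` covers everything between.  In
parallel, `cultivar_class` distinguishes `all` / `intra` (one cultivar)
/ `inter` (several cultivars, not all haplotypes).  Both the
haplotype-level combinations (for upset-style summaries) and the
cultivar-level reduction are emitted, since either reduction can be the
quantity of interest.  The expected inheritance signal — the progeny
haplotype shares more methylated nodes with its source parental
haplotype than the parent's two haplotypes share with each other — is
exercised on seeded replicates in the test suite.

## Windowed differential methylation

Windows of 200 bp tile both progeny haplotypes (CSCF and CSSB); each
window's endpoints are projected onto the other haplotypes, and a
window is retained only when every projection is defined, every
projected length lies in [150, 250] bp, and every haplotype offers at
least 3 cytosines of the analysed context inside its interval.  Windows
are anchored on the progeny so that each test reads one progeny allele.

For a comparison of cultivar A against reference cultivar B, each
clone's methylated/total counts are summed over all cytosines inside
the cultivar's projected interval(s) — both haplotypes for a parent, a
single haplotype in intra-cultivar mode.  For comparisons involving the
progeny the default is *allele mode*: the progeny group uses only the
window's own reference haplotype, so windows anchored on CSCF measure
the CF-derived allele.  This is the central modelling decision of the
package: pooling both progeny haplotypes (available as
`cs_mode = "pooled"`) averages the two alleles and halves every
inherited differential, while allele mode keeps the windows anchored on
CSCF and CSSB as two separate, complementary views.  In pooled mode the
two tilings can produce duplicate homologous windows;
`dedup_windows` collapses them by exact projected-interval identity.
In allele mode both anchors are kept by design.

The test itself (`test_window`) is a two-group binomial logistic
likelihood-ratio test.  With pooled group proportions
$\hat p_g = \sum_i m_i / \sum_i n_i$ (these are the fitted values of the
binomial GLM with a binary group covariate) the deviance is

$$D = 2\left[\ell(\hat p_A) + \ell(\hat p_B) - \ell(\hat p_0)\right],
\qquad
\ell(p) = \sum_i m_i \log p + (n_i - m_i)\log(1-p),$$

with the $0\log 0 \equiv 0$ convention.  Clone replicates make the
counts overdispersed relative to the binomial; the Pearson dispersion

$$\hat\varphi = \frac{1}{N-2}\sum_i
\frac{(m_i - n_i\hat p_{g(i)})^2}{n_i \hat p_{g(i)}(1-\hat p_{g(i)})}$$

scales the statistic down ($D/\hat\varphi$) whenever $\hat\varphi > 1$,
the standard McCullagh–Nelder correction; $p$ comes from the upper
$\chi^2_1$ tail.  Degenerate Pearson terms (zero coverage, pooled
proportion 0 or 1) contribute zero.  The implementation is checked to
$10^{-10}$ against an independently coded brute-force evaluation of the
same likelihood expressions, and the deviance/dispersion agree with
`glm(..., family = binomial)` on random inputs.  We do not attempt to
reproduce any external implementation bit-for-bit; the stated formulas
are the contract.

Significance uses Benjamini–Hochberg q-values computed within each
comparison × context stratum (a standard, fully specified choice) at
q < 0.01, plus context-specific minimum differentials: 20 percentage
points for CG and CHG, 10 for CHH, reflecting the much lower dynamic
range of CHH methylation.  A window is `hyper` when the first group
exceeds the reference by at least the threshold, `hypo` symmetrically.
`sweep_parameters` reruns tiling and calling across a grid of window
size, step, minimum cytosines and differential threshold — the
screening used to settle on the defaults.

Inherited DMR sets follow the trio logic: `iCF` collects windows
significant with the same sign in CS-vs-SB *and* CF-vs-SB (the progeny
behaves like CF where CF differs from SB), `iSB` symmetrically from
CS-vs-CF and SB-vs-CF.  For intra-cultivar DMRs (parent haplotype 1 vs
haplotype 2), `intra_cultivar_concordance` asks whether the progeny
level matches at least one parental haplotype: the minimum absolute
delta must stay below the context's differential threshold.  With no
epimutation the progeny copies one haplotype exactly, and the
concordant fraction reaches 1 up to counting noise.

## Single-reference bias and homology-based correction

Mapping a sample onto a haplotype that is not its own hides
genome-specific cytosines and — worse — converts sample-side C→T
substitutions into confident unmethylated calls, because a bisulfite
read from a true T is indistinguishable from a converted unmethylated
C.  The generator emulates this (`emit_single_reference_calls`):
homologous sites keep their counts, C>T (and reverse-strand G>A) SNP
sites emit fully unmethylated coverage, and sample-absent positions are
dropped.

The correction strategy pairs 200 bp chunks of the reference haplotype
with their homologues on the alternative haplotype.  Here the pairing
comes from graph projection with the same unambiguity and [150, 250] bp
length rules as the DMA windows — the graph already encodes the
alignment that an external whole-genome aligner would have to
rediscover — and the alternative-side sample's own calls are ported
into each reference chunk (`port_methylation`).  Region means are
computed per context and overall, both emitted.  Regions are then
classified by the pre/post contrast: `corrected` (at least 75%
methylated only after porting, delta ≥ 20 points), `original` (high
only before), `low_delta` / `high_delta` for the remainder — an
exclusive, exhaustive partition with both thresholds configurable.
Finally `substitution_enrichment` localises the pairwise SNPs to the
regions and tests the corrected group for enrichment of the
bisulfite-confusable substitutions (C>T and G>A) with Fisher's exact
test, reporting the sample odds ratio.

## Gene-level methylation

Genes are classified from mean exonic levels: `gbM` (gene-body
methylation) requires CG ≥ 20% with CHG and CHH below 20%; `teM`
(TE-like methylation) requires at least 5% in all three contexts and
not gbM; everything else — including genes lacking exonic sites in a
required context, which are flagged — is `other`.  Metagene profiles
average levels in 100 bins over the 1 kb upstream flank, the gene body
and the 1 kb downstream flank, strand-aware; empty bins stay missing
rather than zero, and genes shorter than the bin count are binned with
fractional widths rather than dropped.  Promoters are 3 kb upstream of
the TSS, clipped at the sequence start.

DMRs are annotated against the gene space with the fixed priority
exon > intron > promoter > repeat > intergenic.  Any exclusive
single-label scheme needs *some* precedence; we put genic features
first and keep the raw overlap flags (including the separate TE flag)
in the output so any other precedence can be recomputed.  SV proximity
restricts variants to INDELs ≥ 50 bp and reports, within 1 kb,
`within` (overlap) versus `proximal` pairs, plus a Fisher test of TE
content against large-deletion impact.  Allelic gene pairs across the
two progeny haplotypes are built by projecting each gene span through
the graph, requiring ≥ 50% overlap of the projected span with a native
gene, and keeping only reciprocal matches; unpaired genes are
categorised as unidirectional, no-overlap or unprojectable.

## The synthetic trio generator

The generator emulates the study design end to end: an ancestral
sequence is mutated into four parental haplotypes (SNPs, short indels,
large indels ≥ 50 bp); the progeny haplotypes are exact copies of one
CF and one SB haplotype (the choice is recorded); the graph is built
directly from the variant table, one bubble per variant, so topology
and coordinates are known rather than inferred.  Whole haplotypes are
inherited without recombination; clones share their cultivar's genotype
exactly.  Methylation is a two-level mixture: each cytosine is either
methylated (80% level) or unmethylated (2%), drawn per context with
probabilities CG 0.5, CHG 0.4, CHH 0.1 by default.  These per-context
state frequencies are free parameters of the generator — documented
defaults in the plant-like range, not estimates of any real genome.
Progeny sites inherit the copied parent's state and flip with the
epimutation probability (default 0.02, reflecting high but imperfect
clonal conservation of methylation).  Per clone, levels receive
truncated Gaussian noise (sd 5 points), coverage is Poisson (mean 30)
and methylated counts are binomial.  The two-level mixture makes truth
differentials unambiguous, which is exactly what the validation needs;
it is not a model of intermediate methylation states.

Three planted-signal modes create known structure: `shared_states`
draws one state per ancestral site for all haplotypes (a global null
for calibration); `planted_dmr_*` forces one parent methylated and the
other unmethylated in a fraction of tiles of one context (known
inherited DMRs); `bias_region_*` forces regions methylated on all
haplotypes and converts a fraction (default 30%) of their cytosines
into C>T/G>A SNPs carried by the SB haplotypes, at an even stride so
the planted fraction is uniform at sub-region scale (known
reference-bias showcases).  Annotations place non-overlapping multi-exon
genes with intronic and intergenic repeats; designated genes are forced
into gbM or teM by overriding their exonic states, giving
classification ground truth.

What the generator does *not* emulate bounds what passing tests can
claim: there are no reads (no mapping errors, no M-bias, no PCR
duplicates), bisulfite conversion is perfect, coverage is homogeneous
Poisson, and overdispersion arises only through the configured clone
noise.  Results on real libraries additionally depend on those
processes.  Identical configuration and seed reproduce every output
byte-for-byte.

## Numerical choices and problem sizes

Coordinates are 0-based half-open internally and converted at the I/O
boundaries (CX reports and GFF are 1-based).  Windows whose terminal
tile is shorter than 150 bp are dropped; windows where any sample has
zero total coverage are skipped and counted.  Combination summaries
break ties lexicographically.  The deviance is clamped at zero against
floating-point cancellation.

The validation suite runs trios of 20–100 kb for unit-level checks,
50 kb × 2 chromosomes for graph integrity (50 seeds), 260 kb for null
calibration (≈ 2,500 windows), 200 kb for inheritance recovery and
400 kb with 100 genes for classification — sizes chosen so the whole
suite exercises every code path at meaningful sample sizes while
remaining comfortable to run on a laptop.

## Known limitations

Ambiguous projections are dropped, not resolved; dense repeats would
therefore lose more windows than the synthetic genomes suggest.
Adjacent variants closer than two bases merge into MNP/OTHER records.
The DMA assumes unpaired clones; a paired design would need a different
test.  Spatial merging of adjacent significant windows into larger
regions is out of scope (the analysis is per window), as are read-level
bisulfite simulation, external-aligner homology discovery and
expression integration beyond the generic signed-intersection logic.
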