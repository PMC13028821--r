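---
title: "Methods: lineage, cellulose-locus and mobilome comparison across complete Komagataeibacter genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage, cellulose-locus and mobilome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(komagenomics)
```

# Overview

`komagenomics` compares complete genomes of cellulose-producing acetic
acid bacteria along three axes: dataset structure (a curated manifest of
assemblies), cellulose-synthesis locus architecture with its local
c-di-GMP regulatory context, and the mobilome (plasmids, insertion
sequences, prophage remnants). A cross-module correlation analysis then
asks whether these axes covary. Every stage can be exercised on synthetic
genome sets with planted, machine-readable ground truth, which is how the
test suite validates parameter recovery end to end.

This vignette documents the models and conventions behind each module,
the tunable parameters and their defaults, the numerical choices, and the
limitations a user should know about.

# Manifest curation

The manifest is a frozen TSV (one row per assembly: accession, species,
strain, `size_bp`, source, `excluded_clonal`). Curation follows two
rules:

* clonal or derivative assemblies are excluded by accession
  (`apply_exclusions`), so near-identical genomes do not inflate
  mobilome-sharing signals;
* species identity is the species label verbatim — no taxonomy
  resolution is attempted, because comparative statements are made at the
  level of the labels the dataset carries.

Summary conventions are fixed so that reported numbers are reproducible:
the genome-size median for an even number of genomes is the arithmetic
mean of the two central values, and Mb values are `size_bp / 1e6` rounded
half-up to two decimals. The bundled 22-genome manifest, after removing
its four flagged accessions, yields an 18-genome nonredundant set whose
summary (sizes 3.44–4.24 Mb, median 3.76 Mb; 10 species, 3 singleton
species) is asserted exactly in the test suite.

# MinHash sketching and Mash distances

A sketch retains the `s` smallest hash values over the distinct canonical
k-mers of a sequence (canonical = lexicographic minimum of the k-mer and
its reverse complement; any k-mer containing `N` is skipped entirely, so
ambiguous positions never create phantom sharing). Between two sketches
the Jaccard index is estimated as

\[ \hat\jmath = \frac{|X \cap A \cap B|}{|X|},\qquad
   X = \mathrm{bottom}_s(A \cup B), \]

and transformed into the Mash distance
\(d = -\tfrac{1}{k}\ln\!\big(2\hat\jmath/(1+\hat\jmath)\big)\), which
approximates per-base divergence under a Poisson substitution model.
Conventions: \(\hat\jmath = 0\) maps to the cap \(d = 1\);
\(\hat\jmath = 1\) gives \(d = 0\); values are clamped to \([0, 1]\).

**Hashing.** The hash is a splitmix64 finalizer applied to the
2-bit-packed canonical k-mer XORed with a mixed seed. The 64-bit result
is truncated to its top 53 bits so every hash is exactly representable as
an R double; at sketch scales the collision probability (~n²/2⁵⁴) is
negligible. This makes sketches bit-identical across platforms with no
external dependency. Setting `s = Inf` keeps every hash, making the
Jaccard exact — this is the sampling-error-free reference
(`mash_distance_exact`) used by the tests.

**Parameters.** `k = 16` balances specificity against sketch starvation
on plasmid-sized replicons; `s = 1000` is the default for plasmids and
`s = 2000` is recommended for chromosomes. The tests verify that at these
settings the sketch estimate stays within ±0.01 of the exact-Jaccard
distance on 5-kb sequence pairs diverged at 0.5–2% per base, and that the
mean deviation at 50 kb is within ±0.005.

**Trees.** `nj_tree` runs standard neighbor joining (via `ape::nj`) on
any labelled distance matrix and returns Newick with branch lengths;
negative branch lengths, which NJ can produce on non-additive input, are
clamped to zero. On additive matrices the tree reproduces all pairwise
path lengths (tested to 1e-9).

# Plasmid homology clustering and conservation classes

Plasmids are clustered by **single linkage**: connected components of the
graph whose edges join plasmids at Mash distance ≤ threshold (default
0.10). Single linkage is the deliberate choice here because plasmid
families can be held together by shared modules rather than end-to-end
similarity — a mosaic family forms a connected component through its
module even when some member pairs are individually distant. Components
of size 1 are retained as flagged singletons but excluded from
"clustered plasmid" counts and from the presence matrix. Cluster ids are
dense from 1, ordered by descending size with ties broken by the
lexicographically smallest member, so "Cluster 1" is always the largest
group regardless of input order.

Within-cluster dispersion (median/min/max over all member pairs)
classifies each cluster:

| median Mash distance | class |
|---|---|
| < 0.02 | `highly_conserved` (backbone-like) |
| 0.02–0.05 (closed) | `moderately_conserved` |
| > 0.05 | `mosaic_like` (module-driven) |

The boundary values 0.02 and 0.05 fall in the moderate class because the
outer classes are defined by strict inequalities. These labels are
within-dataset descriptors of distance dispersion, not externally
benchmarked plasmid-family definitions.

Two orthogonal validations accompany the clusters: pairwise Jaccard
overlap of normalized CDS product sets per cluster (case-folded,
whitespace-collapsed, trailing punctuation stripped; the Jaccard of two
empty sets is defined as 1 so annotation-free pairs are not penalized),
and ingestion of plasmid mobility tables (conjugative / mobilizable /
non-mobilizable / unknown, with unrecognized labels bucketed as unknown
under a warning — the unknown class is preserved as real information).

# bcs locus anchoring and the richness feature matrix

Cellulose synthesis genes occur in multiple copies and multiple operon
configurations, so cross-genome comparison needs a standardized locus.
The **anchor contig** is the contig on which *bcsA* and *bcsZ*
co-localize; genomes without such a contig are flagged non-qualifying
(never an error) and are excluded from anchor-based window summaries
while remaining in the feature matrix with presence-based features and
zero-imputed window signals. When several contigs qualify, the tie-break
is: more distinct bcs targets, then longer contig, then lexicographic
contig ID — a deterministic rule, tested by enumeration.

The **anchor locus** for the 50-kb rule is the full span of bcs hits on
the anchor contig, extended 50 kb in both directions and clipped to the
contig. A GGDEF or EAL gene counts if its CDS interval intersects this
window under closed-interval semantics (a gene overlapping the window
edge by a single base counts; the count is monotone non-decreasing in the
window size). Dual-domain proteins (GGDEF and EAL) count once under each
target.

Protein-level similarity is summarized **relative to a medoid**: for each
target carried by at least two genomes, pairwise distance is 1 minus the
Jaccard of amino-acid 5-mer sets, the medoid minimizes summed distance
(ties to the lexicographically smallest genome), and the per-genome
feature is 1 minus the distance to the medoid; genomes lacking the target
get 0. The alignment-free 5-mer metric keeps the module deterministic and
dependency-free; it is a design reconstruction, since any number of
protein-similarity metrics could fill this slot.

The feature matrix assembles bcsA copy count, a 0/1 dispersal flag,
on-anchor presence flags for bcsB/C/D/Z/Q, window presence flags and
counts for GGDEF/EAL, and the medoid similarities. Columns are z-scored
with the means/sds stored; constant columns are dropped before PCA and
recorded. PCA is the eigendecomposition of the covariance of the scaled
matrix (via `prcomp`), components ordered by eigenvalue, with each
component's sign fixed so its largest-magnitude loading is positive —
this makes scores reproducible across row orders and BLAS builds. The
exact feature list is a reconstruction of the named ingredients
(multicopy bcsA, presence flags, window signals, medoid similarity)
rather than a published vector, so absolute PC coordinates are not
comparable across implementations; the tests therefore validate the
projection against an independent eigensolver rather than against fixed
coordinates.

# Mobilome burden

IS and prophage burdens are deterministic aggregations over annotation
rows: per genome, element count and cumulative length computed from
1-based inclusive coordinates (`end − start + 1`), never from sequence,
so fragmented inputs remain summarizable. Genomes present in the manifest
but absent from the annotation table get explicit zero summaries. Length
distributions use type-7 (linear interpolation) quantiles and
closed-on-the-left bins, with "medium" operationalized as 20–50 kb;
edges are configurable. Cross-tool agreement between two burden tables is
summarized as the Spearman rank correlation of per-genome totals.

# Pangenome composition and cross-module linkage

From a binary gene-cluster × genome membership table: **core** clusters
are present in every genome (strict 100% intersection — copy-number-based
core sub-bins are deliberately collapsed, since a membership table
carries no copy number), **singletons** in exactly one genome,
**accessory** the rest. Per-genome counts restrict to clusters the genome
carries; fractions divide by the genome's total.

`spearman_cor` computes rho as the Pearson correlation of mid-ranks
(average ranks under ties). The two-sided p value is exact by full
permutation enumeration for n ≤ 9 and uses the
t approximation \(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) otherwise; the
crossover is where full enumeration (9! permutations) stays cheap.
Zero-variance inputs are an error, and `linkage_analysis` drops such
pairs with a warning rather than failing the family. Benjamini–Hochberg
adjustment is applied across the full set of variable pairs in one call;
subset analyses (e.g. plasmid-bearing genomes only) should be run as
separate calls so each family is corrected on its own. Missing values are
handled by pairwise deletion with the per-pair n reported.

The operating characteristics are measured, not assumed: on independent
columns (n = 18 genomes, 200 replicates) the mean fraction of q < 0.05
pairs stays below 0.05, and a single planted monotone pair with true
rho = 0.9 among six null columns is detected (q < 0.05) in at least 80%
of replicates. Both simulations run in the acceptance script.

# The synthetic-genome generator

The generator exists so that every pipeline stage has a recoverable
ground truth. Its defaults mirror the shape of the curated dataset:

* 18 genomes, chromosome length 3.76 Mb (the curated median), across 10
  species labels with 3 singleton species;
* a mosaic plasmid family of 7 members (shared module occupying 30% of
  each member) and a conserved backbone family of 6 (each member mutated
  from a common ancestor at 0.005 per base), echoing the two dominant
  homology clusters, plus four small backbone families (3, 3, 2, 2) and
  five unrelated singleton plasmids over 13 plasmid-bearing genomes;
* per-genome IS counts uniform in [50, 181] with element lengths in
  [700, 2500] bp; 1–4 prophage regions per genome with lengths in
  [10080, 70900] bp (the observed dataset ranges, used as generator
  bounds);
* a bcs architecture table with 17 qualifying anchors (14 of them with
  GGDEF and EAL inside the 50-kb window), one non-qualifying genome, and
  3 genomes with dispersed bcsA copies — matching the architecture counts
  of the curated set.

Backbone mutation is i.i.d. substitution to a uniformly chosen different
base, with no indels, so exact k-mer Jaccard oracles stay simple; the
realized substitution count is recorded in the truth. Two members mutated
independently at rate r diverge at ≈ 2r, which is how the backbone
default 0.005 lands safely inside the highly-conserved class (expected
distance ≈ 0.01 < 0.02) and the mosaic module fraction 0.3 lands in the
mosaic class (exact distance ≈ 0.075 > 0.05). Elements are placed
non-overlapping with at least 1 bp gaps; the bcs neighborhood reserves a
fixed region so IS/prophage placements can never contaminate the 50-kb
window. Infeasible configurations (elements exceeding the chromosome,
spec needing more contigs than available) error before any file is
written.

Randomness comes from R's Mersenne–Twister with `sample.kind =
"Rejection"` pinned explicitly, so identical configuration and seed give
byte-identical output files across platforms — asserted by hashing every
artifact in the tests.

**What the generator does not emulate:** realistic base composition or
codon structure (sequences are uniform ACGT), rearrangements and indels,
operon regulation, IS target-site preferences, prophage decay gradients,
and read-level artifacts. Passing parameter-recovery tests therefore
demonstrates the correctness of the pipeline's logic and statistics on
data with the declared structure, not robustness to every property of
real assemblies. Annotation-driven modules consume real GFF3/TSV tables,
so results on real data inherit the upstream annotators' error modes.

# Numerical choices and degenerate inputs

* Hashes are 53-bit truncations of a 64-bit mix (exact doubles in R).
* Mash: \(\hat\jmath = 0 \Rightarrow d = 1\); distances clamped to
  [0, 1]; two empty sketches compare as identical (distance 0).
* Rounding of Mb summaries is half-up (R's `round` is banker's).
* Quantiles are type 7 everywhere.
* BH q values delegate to `p.adjust(method = "BH")`; inputs outside
  [0, 1] are an error.
* PCA sign convention: largest-magnitude loading positive per component.
* Jaccard of two empty sets is 1 (product concordance, protein 5-mers).
* Proteins shorter than the 5-mer word contribute themselves as a single
  token.
* Cluster ordering and anchor tie-breaks are fully deterministic; NJ
  tie-breaking is delegated to `ape::nj`, which is deterministic for a
  given input.

# Problem sizes used in the checks

The test suite and acceptance script size their simulations to run in a
few minutes on one core: 5-kb sequence pairs (20 replicates × 3 rates)
for sketch-versus-exact agreement, 40-kb plasmids in 4-member families
across 20 seeds for conservation-class recovery, 200 random ≤ 10-taxon
instances for the clustering oracle, one full default 18-genome synthetic
set (3.76-Mb chromosomes) for anchor/window/burden recovery, and 200 +
100 replicates of the n = 18 linkage simulations. These sizes are the
package's own choice of a fast, convincing demonstration; all of them can
be scaled up through the exported configuration objects.

# Known limitations

* Single-linkage clustering is threshold-sensitive by design; the 0.10
  default is a judgment call exposed as an argument, and raising it can
  only merge clusters (monotonicity is tested).
* The conservation classes describe within-dataset dispersion only.
* The richness feature list and the protein-similarity metric are
  reconstructions; PC coordinates are reproducible within this package
  but not across differently specified feature sets.
* With ~18 genomes the linkage analysis has power only for strong
  monotone effects (the measured 80%+ power is at true rho = 0.9);
  phylogenetic non-independence of closely related strains is not
  modeled.
* Exact Spearman p values are enumerated only to n = 9; beyond that the
  t approximation is used, which is standard but approximate under heavy
  ties.
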