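# komagenomics

Comparative genomics of complete *Komagataeibacter* genomes: a tested,
reusable R implementation of a lineage-and-mobilome analysis pipeline for
bacterial-cellulose-producing acetic acid bacteria.

*Komagataeibacter* strains are the main industrial producers of bacterial
cellulose, yet closely related isolates differ in cellulose yield and in
genetic stability during propagation. Those differences track two things a
genome can tell us: the architecture of the cellulose-synthesis (*bcs*)
locus together with its local c-di-GMP regulatory context, and the mobilome
— plasmids, insertion sequences (IS) and prophage remnants — which is
strongly strain-dependent. This package implements the full comparative
workflow over complete assemblies, plus a seeded synthetic-genome generator
with machine-readable ground truth so every stage is testable without
downloading anything.

## What it computes

- **Manifest curation** (`load_manifest`, `apply_exclusions`,
  `summarize_manifest`): a frozen genome table with species/strain labels
  and sizes; clonal or derivative assemblies are excluded to form the
  nonredundant comparison set.
- **MinHash sketching and Mash distances** (`sketch_sequence`,
  `mash_distance`, `distance_matrix`, `nj_tree`): the sketch keeps the *s*
  smallest 64-bit hashes over distinct canonical k-mers; the Jaccard index
  *j* is estimated from the merged bottom-*s* set and transformed into the
  Mash distance *d* = −(1/k)·ln(2j/(1+j)), an estimate of per-base
  divergence. Neighbor-joining Newick trees summarize distance matrices.
- **Plasmid homology clustering** (`cluster_plasmids`, `dispersion_stats`,
  `classify_conservation`, `presence_matrix`, `product_concordance`,
  `ingest_mobility_table`): single-linkage components at a Mash distance
  threshold (default 0.10); within-cluster median/min/max distances
  classify each cluster as highly conserved (median < 0.02), moderately
  conserved (0.02–0.05) or mosaic-like (> 0.05), separating conserved
  backbones from module-driven assemblages; clusters are validated
  orthogonally by CDS-product Jaccard concordance.
- **bcs locus anchoring and richness PCA** (`find_targets`,
  `select_anchor`, `window_signals`, `medoid_similarity`,
  `build_feature_matrix`, `pca_project`): the anchor contig is the contig
  where *bcsA* and *bcsZ* co-localize; GGDEF/EAL domain signals are
  counted within 50 kb of the anchor span; per-genome features (bcsA copy
  number and dispersal, on-anchor gene presence, window signals, medoid
  protein similarity) are z-scored and projected by PCA.
- **Mobilome burden** (`is_burden`, `prophage_burden`,
  `length_distribution`, `cross_tool_concordance`): per-genome IS count
  and cumulative IS length; prophage region count and total length, with
  short/medium/long length bins.
- **Pangenome composition and linkage** (`composition_metrics`,
  `spearman_cor`, `bh_adjust`, `linkage_analysis`): core / accessory /
  singleton partitioning of a gene-cluster membership table, and
  tie-corrected Spearman correlations across modules with
  Benjamini–Hochberg false-discovery control.
- **Synthetic data** (`synth_config`, `generate_genome_set`,
  `mutate_backbone`, `plant_mosaic_family`, `plant_bcs_locus`,
  `synth_feature_table`): deterministic genome sets with planted plasmid
  families, bcs architectures, IS elements and prophage regions, and an
  exhaustive truth record for parameter-recovery tests.

## Worked example

```r
library(komagenomics)

# Curated manifest: 22 complete assemblies, 4 excluded as clonal/derivative
manifest <- load_manifest(system.file("extdata",
    "komagataeibacter_manifest.tsv", package = "komagenomics"))
nonredundant <- apply_exclusions(manifest, clonal_exclusions())
str(summarize_manifest(nonredundant))
#> List of 6
#>  $ n_genomes          : int 18
#>  $ n_species          : int 10
#>  $ n_singleton_species: int 3
#>  $ size_median_mb     : num 3.76
#>  $ size_min_mb        : num 3.44
#>  $ size_max_mb        : num 4.24

# Synthetic 18-genome set with two dominant planted plasmid families
out <- file.path(tempdir(), "demo")
res <- generate_genome_set(synth_config(seed = 1), out)
p <- sketch_params(k = 16, s = 1000)
dm <- distance_matrix(sketch_fasta(file.path(out, "plasmids.fna"), p))
cs <- cluster_plasmids(dm, threshold = 0.10)
disp <- dispersion_stats(cs, dm)
head(disp[disp$size > 1, ], 3)
#>   cluster_id size n_pairs median_d   min_d  max_d         category
#> 1          1    7      21  0.07787 0.07479 0.0808      mosaic_like
#> 2          2    6      15  0.00987 0.00926 0.0110 highly_conserved
#> 3          3    3       3  0.01080 0.01075 0.0121 highly_conserved
```

The 18-genome summary reproduces the curated dataset (sizes 3.44–4.24 Mb,
median 3.76 Mb; 10 species, 3 of them represented by a single genome). On
the synthetic set, the planted mosaic family of 7 is recovered as the
largest, mosaic-like cluster (members share a 30% sequence module but
diverge overall), while the 6-member backbone family mutated at 0.5% per
base clusters with a median Mash distance near 0.01, well inside the
highly conserved class.

## Scope notes

External tools whose outputs the field would normally feed into this kind
of analysis (anvi'o pangenome clustering, ISEScan, VIBRANT/Cenote-Taker,
MOB-suite, Prokka, IQ-TREE, pyANI) are consumed as annotation tables or
emulated by the synthetic generator; they are deliberately not
reimplemented or wrapped. The methods vignette
(`vignettes/komagataeibacter-pipeline.Rmd`) documents the model choices,
defaults and limitations.
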