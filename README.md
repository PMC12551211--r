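# pangraphsv

Structural-variant discovery and association analysis from
reference-backbone pangenome graphs, aimed at livestock genomics of the
kind practised on multi-breed cattle panels: a set of de novo assemblies is
aligned into a graph anchored on the linear reference, and the graph is
then mined for structural variants (SVs), novel sequence, population
structure and trait associations.

The package covers the full downstream pipeline once a graph and
per-assembly paths exist (it does not build graphs from raw assemblies):

- **Graph and path I/O** — rGFA/GFA1 graphs with `SN`/`SO`/`SR` origin
  tags, per-assembly node-path BED files, FASTA, an SV VCF (4.2) and
  genotype/phenotype/metadata tables.
- **Graph partition** — node occupancy from sample paths; the *core*
  (carried by every assembly and the reference), *flexible* (a proper
  subset) and *nested* (carried by no path; realignment artefacts)
  classes; per-sample novel-sequence contributions; non-reference
  sequences (NRS: carried, off-backbone, > 50 bp) and breed-specific
  features.
- **SV catalogue** — bubbles enumerated between backbone anchor nodes,
  alleles deduplicated by sequence; classification into insertions
  (empty reference path, alternate ≥ 50 bp), deletions (empty alternate
  path, reference ≥ 50 bp) and substitutions; biallelic vs multiallelic;
  haploid genotyping of every assembly; non-reference unique insertions
  (NRUIs) from pure-insertion bubbles; length spectra.
- **Virtual SNPs** — deletions converted to array-genotypable markers by
  the breakpoint base-change test (first deleted base vs first base after
  the 3' breakpoint, with the opposite-strand confirmation), and marker
  informativeness: MAF, He = 2pq, PIC = He − 2p²q².
- **Population structure** — presence/absence (PAV) matrices, Jaccard /
  complete-linkage hierarchical clustering, dosage PCA, adjusted Rand
  agreement with breed labels.
- **Association** — the weighted mixed linear model
  `y = 1μ + xβ + u + e`, `u ~ N(0, G σu²)`, `e ~ N(0, D σe²)` with `G`
  the VanRaden genomic relationship matrix and `D` the diagonal of
  inverse per-animal accuracy weights; REML variance components from the
  null model via a one-dimensional eigendecomposition profile; a
  per-marker generalised-least-squares Wald scan with the components held
  fixed; Bonferroni thresholds; the SCS = 3 + log₂(SCC/100,000) trait
  transform; and iterative LD-window QTL grouping (10 Mb windows,
  r² > 0.7 with the peak).
- **Synthetic data** — a deterministic simulator of multi-breed
  populations with planted SVs (Balding–Nichols breed divergence,
  breed-private sites, transposable-element-like length modes at
  150/250/5,500 bp), the matching graph + paths, diploid genotype cohorts
  and mixed-model phenotypes, with full ground truth.

## Worked example

```r
library(pangraphsv)

cfg   <- sim_config(seed = 1)        # 14 breeds x 4 assemblies, 2 Mb, 120 SVs
pl    <- run_pipeline(cfg)           # simulate -> graph -> call -> GWAS -> QTL

pl$partition
#> graph partition:
#>   core          121 nodes        1,961,423 bases
#>   flexible      157 nodes           98,280 bases
#>   nested          5 nodes            2,416 bases
#>   total         283 nodes        2,062,119 bases

pl$catalog
#> sv_catalog: 120 SVs (DEL=42, INS=50, SUB=28) over 56 samples

pl$null_fit
#> null mixed model: mu=0.2877  sigma_u2=0.4871  sigma_e2=43.35  h2=0.466

pl$qtl[, .(region, chrom, peak_marker, peak_neg_log10_p, n_markers)]
#>    region chrom peak_marker peak_neg_log10_p n_markers
#> 1:      1  chr1       sv052         9.273773         1
pl$causal$sv_id                      # "sv052" — the planted causal deletion
```

The partition rows are the bases shared by every assembly plus the
reference (core), carried by only a subset (flexible), and traversed by no
path (nested, excluded from analysis). The null-model line shows the REML
variance components of the weighted mixed model — `h2` is the polygenic
fraction of phenotypic variance — and the QTL table shows that the scan's
single genome-wide-significant region peaks at the deletion the simulator
planted as causal.

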