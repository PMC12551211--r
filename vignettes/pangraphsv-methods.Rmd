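---
title: "Methods: pangenome-graph SV discovery, virtual SNPs and weighted mixed-model association"
author: "pangraphsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome-graph SV discovery, virtual SNPs and weighted mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangraphsv)
```

# The data model

A reference-backbone pangenome graph represents a species' sequence
diversity as segments (nodes) joined by links (edges). The linear
reference genome is the rank-0 *backbone*: its segments carry origin tags
(contig `SN`, offset `SO`, rank `SR` in rGFA) and, ordered by offset,
tile each chromosome without overlap. Sequence contributed by other
assemblies hangs off the backbone as rank ≥ 1 nodes. Each assembly,
realigned to the graph, traces a *path* — an ordered, oriented node
traversal — stored here as a BED-like file of comma-separated node steps.

All internal coordinates are 0-based half-open; VCF emission converts to
1-based anchored positions (the anchor base before the event is shared by
REF and every ALT), and the virtual-SNP breakpoint test uses 1-based
inclusive intervals to match how deletion breakpoints are tabulated. Each
conversion is explicit and unit-tested rather than implicit in the
arithmetic.

# Graph partition

Node occupancy is computed from the paths alone: a node's carrier set is
the set of samples whose steps include it, in either orientation
(orientation is deliberately ignored for carriage — an inverted traversal
still carries the sequence). The reference counts as one more carrier of
every backbone node. Three classes follow:

* **core** — carried by every sample *and* the reference;
* **nested** — carried by no sample and off the backbone. Realignment of
  assemblies to a graph can fail to re-traverse nodes inside complex
  bubbles, leaving sequence that no path supports; these nodes are
  excluded from all downstream analysis;
* **flexible** — everything else.

The partition is exhaustive and disjoint, so class base totals conserve:
core + flexible equals the path-covered bases and adding nested gives the
total graph bases. These identities are asserted in the tests rather than
assumed.

Non-reference sequence (NRS) applies three filters in order: drop nested
nodes, drop backbone nodes, keep nodes strictly longer than 50 bp. The
strict `>` is used for NRS and NRUI; the SV length rule below uses `≥ 50`.
Both cutoffs are arguments, because the two conventions coexist in
published catalogues and a user should be able to state which one a
number was produced under.

Per-sample novel-sequence contributions credit each off-backbone carried
node to its earliest carrier in a stated integration order; the total is
order-invariant (it is just the off-backbone carried base count), which
the tests check by permutation.

# Bubbles and SV classification

Projecting a path onto the backbone yields anchor pairs: consecutive
backbone nodes the path visits, with the off-backbone nodes between them
as the traversal. A skipped backbone node between two anchors is deletion
evidence; a non-empty traversal is insertion/substitution evidence.
Backbone visits that break collinearity are dropped and the path flagged
— such segments are not genotyped rather than mis-genotyped.

A *bubble* is the union of deviating anchor intervals across samples
(overlapping intervals are merged and logged). Within a bubble, each
sample's allele is the concatenated sequence of its traversal; alleles
are deduplicated by exact sequence — no fuzzy merging, so two alternates
differing by one base stay distinct alleles. Allele 0 is always the
reference path between the anchors. Samples that do not cover both
anchors are genotyped missing, not reference.

Classification follows the bubble's allele lengths:

* **insertion** — reference allele (essentially) empty, longest alternate
  ≥ 50 bp;
* **deletion** — some alternate (essentially) empty, reference ≥ 50 bp;
* **substitution** — sequence on both sides (this bucket also absorbs
  inversions and duplications, which are not sub-typed);
* bubbles with all alleles under 50 bp are not SVs and are dropped.

"Essentially empty" is governed by `small_allele_tol`, default 0 (the
strict definition); setting it to 5 reproduces catalogues that tolerate a
few residual bases on the empty path. A bubble with exactly two alleles
is biallelic, otherwise multiallelic.

NRUIs (non-reference unique insertions) restrict NRS to insertion-type
bubbles containing no reference-derived node, i.e. sequence genuinely
absent from the reference rather than rearranged; NRUI ⊆ NRS is a tested
invariant.

# Virtual SNPs and marker informativeness

A deletion `[s, e]` (1-based inclusive) is genotypable on a SNP array if
deleting it changes the base read at the breakpoint: if `base(s)` (first
deleted base) differs from `base(e+1)` (first base after the 3'
breakpoint), the marker's reference allele is `base(s)` and its alternate
is `base(e+1)`. The complementary test on the opposite strand compares
`base(e)` with `base(s-1)`. Both flags are reported and the caller
decides whether to require confirmation, since retention policy for
markers passing only one strand is a panel-design choice, not a property
of the sequence. The forward test of the reverse-complemented sequence
with mirrored coordinates equals the reverse test of the original — a
property the tests exercise on hundreds of random draws. Intervals
touching a sequence end, or with ambiguity bases at tested positions,
are reported non-convertible with a reason.

Marker informativeness uses observed allele counts over non-missing
diploid dosages: `He = 2pq`, `PIC = He − 2p²q²`, `MAF = min(p, q)`.
A marker is *polymorphic* when both alleles are observed at least once in
the full genotyped set; panel means are computed over polymorphic markers
only, with the monomorphic count reported separately. Frequencies are
plain observed counts, not breed-weighted.

# Population structure

PAV matrices are binary sample-by-feature carriage indicators. Distances
default to Jaccard — shared absences carry no signal for presence data —
with complete linkage; both are arguments since the clustering function
alone does not pin them down. Rows are sorted lexicographically before
clustering so ties break deterministically. PCA of dosages centres and
scales each marker (so the total explained variance equals the retained
marker count), mean-imputes missing dosages per marker, and drops
zero-variance markers with a message. Cluster agreement with breed labels
is summarised by the adjusted Rand index.

# The weighted mixed linear model

The association model is `y = 1μ + xβ + u + e` with
`u ~ N(0, G σu²)` and `e ~ N(0, D σe²)`, where `y` are daughter yield
deviations (or any phenotype with heterogeneous accuracy), `x` the tested
marker's dosages, `G` the genomic relationship matrix and `D` the
diagonal of inverse per-animal accuracy weights `1/wᵢ`, so animal *i*'s
residual variance is `σe²/wᵢ`. `G` is VanRaden's first method,
`Z Z' / (2 Σ pⱼ(1−pⱼ))` at observed frequencies, with per-marker mean
imputation of missing dosages.

Variance components come from the null model (`β = 0`) by REML profiled
over the single ratio `λ = σu²/σe²`: whitening by `D^{−1/2}` and an
eigendecomposition of `D^{−1/2} G D^{−1/2}` diagonalise the covariance,
so each candidate `λ` costs O(n) and the optimisation is a 1-D search
over `log λ ∈ [−12, 12]`. Estimates at the search boundary, and the
`G ∝ I` collapse where only `σu² + σe²` is identified, are flagged. The
reported `h²` is `σu² / (σu² + σe² · mean(1/w))` — the polygenic share of
*phenotype-scale* variance, which matters whenever weights are
heterogeneous.

The scan holds the components fixed and solves, per marker, the 2×2
generalised-least-squares system for intercept and marker effect in the
whitened coordinates — no per-marker matrix inversion — with a Wald
χ²(1 df) p-value. Monomorphic (or numerically degenerate) markers are
reported with p = 1 and flagged. The tests pin the scan to an
explicit-inverse GLS oracle at 10⁻⁸ relative tolerance and check type-I
calibration and p-value uniformity under the null.

Significance uses the Bonferroni threshold `α/m`; QTL grouping is
iterative LD clumping: the most significant unassigned marker seeds a
region, markers within a 10 Mb window centred on the peak whose squared
dosage correlation with the peak exceeds 0.7 join it, and the procedure
repeats. The window is read as peak-centred (±5 Mb); both the window and
the r² cutoff are arguments because tiled-window variants of the
procedure exist. Peak ties break by smaller p, then smaller position.

# The synthetic population

The simulator defines the study conditions under which every claim in the
test suite is made.

* **Desk preset** — one 2 Mb chromosome, 14 breeds × 4 haploid
  assemblies, 120 planted SVs, 2,000 SNPs; the full pipeline runs in
  well under a minute. Problem sizes for the statistical checks are 400
  to 840 animals with 300-1,800 markers.
* **SV types and lengths** — insertions (empty reference footprint),
  deletions (empty alternate), substitutions (sequence both sides), with
  a 10% multiallelic fraction among insertions/substitutions. Lengths
  mix point masses at 150, 250 and 5,500 bp — the repeat-family peaks of
  real cattle SV spectra — over a log-normal body (median 300 bp),
  truncated to [50 bp, 10 kb]. Sites are non-overlapping with a 200 bp
  minimum gap and 500 bp chromosome-end margins, so each SV has distinct
  backbone anchors.
* **Breed structure** — alternate-allele frequencies per breed follow a
  Balding–Nichols draw around an ancestral frequency, with the Fst-like
  `divergence` parameter (default 0.15, a plausible across-breed value
  for differentiated livestock breeds) controlling the spread; a
  configurable fraction of sites (default 20%) is breed-private. Breed
  recovery claims (ARI = 1) are made at high divergence (0.6, private
  fraction 0.5), emulating strongly differentiated breeds; at the
  default divergence clustering is only partially concordant, as it
  should be.
* **Realized alleles** — every planted SV is redrawn until it has at
  least one alternate carrier (an undiscoverable site has no counterpart
  in a graph built from assemblies), and alternate alleles that no
  assembly carries are pruned: a real graph contains only sequence some
  assembly contributed. A multiallelic site whose second alternate fails
  to segregate is therefore realized biallelic, and the ground truth
  records the realized state.
* **Graph emission** — backbone segments split the reference at every SV
  breakpoint; each carried alternate allele becomes one off-backbone
  node whose rank is the position of its earliest carrier in the sample
  order; deletion carriers get skip edges. Concatenating any path's node
  sequences spells that sample's haplotype exactly — the sequence-level
  oracle for the calling stage. A configurable number of decoy "nested"
  nodes (default 5) is wired into the graph but traversed by no path, to
  exercise the nested-node filter.
* **Phenotypes** — `y = μ + xβ + u + e` with `σu² = h²`, `σe²` scaled so
  the expected phenotype-scale residual variance is `1 − h²` under the
  drawn weights (`w ~ Uniform(20, 200)`, an effective-daughter-count
  range), and `β` chosen so the causal marker explains a stated variance
  fraction (default 5%). The end-to-end GWAS cohort is 60 diploid
  animals per breed (n = 840), the scale at which a 5% effect is
  reliably genome-wide significant; variance-component recovery is
  checked in a half-sib design (12 sire families), because h² is only
  weakly identified from near-unrelated individuals at these sample
  sizes.

## What the generator does and does not emulate

It reproduces the structural features the methods depend on: a reference
backbone with bubbles, breed-structured carriage, haploid assembly paths
with full coverage, heterogeneous-accuracy phenotypes under the exact
association model. It does **not** emulate alignment error, partial path
coverage, near-duplicate alleles, repeat-induced mis-anchoring,
linkage disequilibrium between markers (cohort genotypes are drawn
independently given breed), or recombination/coalescent history. Perfect
recall/precision on synthetic data therefore demonstrates correctness of
the graph algebra and the solvers, not robustness to the failure modes of
real alignments; the flagged-path, merged-bubble and missing-genotype
behaviours are the designed degradation paths for such data.

# Numerical choices and degenerate inputs

Eigenvalues of the whitened relationship matrix are clipped at zero; the
phenotype simulator adds `10⁻⁸ I` before the Cholesky factorisation.
REML uses `optimize()` at tolerance 10⁻⁸ on the log-ratio scale.
Markers whose 2×2 GLS system is numerically singular are flagged rather
than reported with unstable estimates. Empty inputs (no deviating
samples, no significant markers, deletion-free catalogues, empty path
files) return empty, well-typed results rather than errors; genuinely
invalid inputs (unknown nodes, step pairs without edges, REF
disagreements with the FASTA, all-missing markers) raise errors naming
the offending record.

# Known limitations

Inversions and duplications land in the substitution bucket by design.
Overlapping bubbles are merged to union anchors, which can fuse adjacent
SVs into one multiallelic site on real data. The bubble enumerator
assumes paths are collinear with the backbone at the anchors it uses;
heavily rearranged samples are flagged and partially genotyped. The
simulator's lack of marker-marker LD means QTL regions on synthetic data
are typically single-marker; the grouping procedure itself is exercised
separately on constructed LD patterns.
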