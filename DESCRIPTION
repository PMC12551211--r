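Package: pangraphsv
Title: Structural Variant Discovery and Association from Reference-Backed Pangenome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reference-backbone pangenome graphs of the
    kind built from multiple de novo assemblies of a species: reading and
    writing rGFA/GFA1 graphs and per-assembly path files, partitioning graph
    nodes into core, flexible and nested sequence, extracting non-reference
    sequences and non-reference unique insertions, enumerating bubbles along
    the reference backbone and classifying structural variants (insertions,
    deletions, substitutions), converting deletions into array-genotypable
    virtual SNPs with marker informativeness statistics (MAF, expected
    heterozygosity, polymorphic information content), presence/absence-based
    population-structure analysis (hierarchical clustering, PCA), and a
    weighted mixed-linear-model association scan with REML variance
    components, Bonferroni thresholds and LD-window QTL grouping. Includes a
    deterministic simulator of multi-breed cattle-like populations with
    planted structural variants that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
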