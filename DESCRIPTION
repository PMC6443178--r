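Package: hervscan
Title: Somatic Mutation Hotspot Detection in Human Endogenous Retrovirus
    Elements
Version: 0.1.0
Authors@R:
    person("hervscan", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Genome-wide scan for human endogenous retrovirus (HERV)
    elements carrying significantly more (or fewer) somatic single
    nucleotide variants than expected under a uniform-genome null.  Each
    element is tested with an exact binomial tail against a per-region
    background density, with Bonferroni family-wise error control,
    separate protein-coding and non-coding backgrounds, HERV taxonomy
    (canonical flag, supergroup, group) aggregation, cancer-type
    cross-tabulation, DNA functional-element overlap, and a protein
    functional-site annotation join.  Includes a synthetic
    mutation-landscape generator so the full pipeline runs and is tested
    without any external download, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
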