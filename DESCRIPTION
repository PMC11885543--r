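Package: mitocrypt
Title: Cryptic Mitochondrial DNA Mutations, Site Frequency Spectra and
    Mitochondrial Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the accumulation of cryptic mitochondrial DNA
    (mtDNA) mutations -- heteroplasmies unique to a single cell of a donor --
    from single-cell sequencing base counts. Calls per-cell heteroplasmies from
    base-count tables, classifies variants as cryptic, shared or common, builds
    cryptic site frequency spectra (cSFS) with a homoplasmic class, and computes
    summary statistics (mutation load, rank-biserial effect sizes, Mann-Whitney
    spectrum shifts, dN/dS Fisher tests, pseudobulk heteroplasmy, homoplasmy
    rates). Includes an exact event-driven Moran-model simulator of the mtDNA
    population of a post-mitotic cell under infinite-sites neutral mutation, a
    synthetic-cohort generator with known ground truth, and a coalescent-based
    Bayesian fit of a donor's mitochondrial age W and scaled per-base mutation
    rate Theta = N*nu from the cSFS, with prediction of homoplasmy accumulation
    and heteroplasmy threshold-crossing curves over a lifetime.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
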