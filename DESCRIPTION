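Package: supertreeprep
Title: Curation and Matrix Construction for Supertree Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling, curating and processing collections of
    published phylogenies ahead of a supertree analysis. Provides a
    single-file XML dataset format coupling source trees with their
    bibliographic and character metadata, tree surgery (taxon substitution
    and deletion with node collapsing, polyphyly permutation, genus-level
    polytomy expansion), dataset-level checks (summary, cleaning, data
    independence, taxonomic overlap connectivity, metadata subsetting),
    Baum-Ragan matrix representation with parsimony (MRP) coding with
    NEXUS and TNT writers, and Safe Taxonomic Reduction of binary 0/1/?
    matrices with reduced-matrix, category-report and reinsertion outputs.
    A synthetic-data generator and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'supertreeprep-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'newick.R'
    'bibtex.R'
    'phyml.R'
    'tree-ops.R'
    'mrp.R'
    'str.R'
    'checks.R'
    'synth.R'
    'show-methods.R'
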