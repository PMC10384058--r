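Package: ampliTIC
Title: Taxonomy-Informed Clustering and Ecological Profiling of 16S rRNA
    Amplicon Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous 16S rRNA gene amplicon fragments into a
    sequence-based diversity estimate for a taxonomic order. Provides
    dereplication of aligned records, selection of the most-represented
    alignment region from per-column base coverage, length filtering against a
    reference base-count expectation, calibration of species/genus/family
    similarity cutoffs from described reference species, taxonomy-informed
    hierarchical incremental clustering into molecular families, genera and
    species (fOTUs, gOTUs, sOTUs), assignment of described species names to
    clusters, and ecological prevalence/abundance summaries across environment
    categories. A synthetic community generator with planted hierarchical
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
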