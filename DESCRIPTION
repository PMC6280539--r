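Package: mgdtnet
Title: miRNA-Gene-Drug Triplet Networks for Expression-Based Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tripartite miRNA-gene-drug networks from interaction
    catalogs, scores every miRNA-gene-drug triplet for disease-specific
    dysregulation from paired mRNA/miRNA expression profiles (gene risk
    score, product of differential-expression P values, and
    differential miRNA-mRNA correlation, combined by equally weighted
    rank aggregation with a label-permutation null), derives
    disease-specific and common triplet networks and drug participation
    rankings, and maps miRNA target sets to enriched pathways by a
    hypergeometric test to nominate drug repurposing candidates. A
    synthetic-data module generates interaction catalogs and two-group
    expression studies with planted dysregulated triplets so the whole
    pipeline can be benchmarked without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
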