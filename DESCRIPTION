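Package: litgenet
Title: Literature Mining of Gene Trends, Co-Occurrence Networks and Country Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline framework for mining annotated biomedical abstract
    corpora for genetic research trends. Reads MEDLINE/PubMed XML or a
    line-delimited JSON corpus format, recognizes gene mentions with a
    dictionary matcher over a synonym lexicon, resolves author affiliation
    strings to countries by rightmost sub-address escalation against an
    offline gazetteer, and derives gene-by-country count matrices, research
    effort fractions, international collaboration counts, maximal closed
    frequent gene itemsets over country and year transactions, gene
    co-occurrence networks with component, pruning, centrality and
    modularity-community analysis, and hierarchical plus fuzzy c-means
    clustering with partition-validity indices. Includes a deterministic
    synthetic-corpus generator with planted communities, country
    preferences and itemsets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    ape,
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
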