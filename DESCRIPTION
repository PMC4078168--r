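Package: phylobrowse
Title: Phylogenetic Community Structure Under Ungulate Browsing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing selective ungulate herbivory as a biotic
    filter during plant community assembly. Converts line-intercept transect
    records from paired exclosure/control plots into percent cover, computes
    species richness, Shannon-Wiener diversity and mean pairwise phylogenetic
    distance, tests community phylogenetic structure with the net relatedness
    index under tip-shuffle permutation nulls, quantifies phylogenetic signal
    in browse-relevant traits (Fritz and Purvis' D for binary traits, a
    parsimony-score permutation test for multistate traits), and scores
    species with a deer-browsing susceptibility index. A synthetic-data module
    simulates pure-birth trees, threshold-model and Markov traits, and
    filtered communities with transect-level records so the full analysis
    chain can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
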