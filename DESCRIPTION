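Package: quintetroot
Title: Species Tree Rooting from Unrooted Gene Trees Under the
    Multi-Species Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Roots an unrooted species tree using only the topologies of
    unrooted gene trees, exploiting the Allman-Degnan-Rhodes (ADR)
    identifiability theory for five-taxon (quintet) trees under the
    multi-species coalescent (MSC).  Every candidate rooting is scored by
    how strongly the empirical distribution of unrooted quintet gene-tree
    topologies violates the ADR equivalence-class invariants and
    inequality partial order associated with that rooted quintet; the
    rooting with the smallest total violation is returned.  Includes the
    scoring machinery for trees with five or more taxa (exhaustive and
    linear quintet encodings), rooted-tree evaluation metrics (clade
    distance, root distance, normalized Robinson-Foulds, average
    discordance), and a coalescent-unit MSC gene-tree simulator for
    fixtures and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
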