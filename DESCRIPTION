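Package: lianascape
Title: Liana Community Structure, Composition and Host Specificity in
    Tropical Forest Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow linking liana (woody vine) community
    structure, floristic and functional composition, and tree-host
    specificity to local forest structure and microtopography.
    Provides a stem-level synthetic census generator with known ground
    truth; quadrat-scale forest and terrain metrics including a
    relative slope position index derived from D8 flow routing on a
    digital elevation model; stepwise AIC linear models with a REML
    random-intercept pseudo-replication check; non-symmetric
    correspondence analysis with instrumental variables (NSCA/NSCAIV)
    and partial CCA with permutation tests; Hill-N2 weighted
    community-weighted-mean and species-niche-centroid (fourth-corner)
    max-tests; and bipartite liana-host randomization tests classifying
    attraction and repulsion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
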