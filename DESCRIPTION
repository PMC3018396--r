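Package: hubclass
Title: Classifying Party and Date Hubs in Protein Interaction Networks from
    Biological Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the network role of a protein (non-hub, intermediately
    connected, party hub, or date hub) from its biological features alone,
    without access to the interaction network itself. Implements seventeen
    sequence- and annotation-based feature encodings (amino-acid, dipeptide
    and gapped-pair compositions, co-occurrence texture statistics,
    physicochemical property fractions, domain and repeated-domain content,
    Gene Ontology level memberships, disorder-region summaries, and PSSM-20 /
    PSSM-400 profile encodings), supervised principal-component reduction of
    each encoding to three combined features, Bayes classifiers with Gaussian
    or mixture-density class-conditional models plus a minimum-risk decision
    rule under a hub-prioritising cost matrix, greedy forward fusion of
    feature sets, a multiclass evaluation suite, and a synthetic
    protein-interaction-network data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
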