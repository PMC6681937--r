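Package: trophamix
Title: Provenance Tracking and Entropy Analysis of Trophallactic Food Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how food collected by individual foragers
    blends as it is disseminated through an ant colony by mouth-to-mouth
    (trophallactic) exchange. Reads time-ordered interaction schedules, tracks
    the provenance of food "types" (labelled by the collecting forager) through
    every transfer, and summarises blending with a family of Shannon entropies
    (types entropy, per-crop entropy, load-weighted mixing entropy, overall
    mixing entropy). Fits the truncated-exponential food-transfer rule by
    maximum likelihood, computes interaction-direction statistics and static
    contact-graph community structure, and provides hybrid simulations that
    replay an empirical schedule under substituted transfer rules, a
    random-interaction trade-off model for the dissemination-versus-mixing
    compromise, and a seeded synthetic-colony generator with ground-truth
    provenance for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
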