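Package: matequeue
Title: Mating-Order and Paternity-Share Analysis for Freely Mating Insect Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse post-copulatory sexual selection in freely
    mating groups with a phenotypically marked focal male. From behavioural
    mating logs and marker-split offspring counts the package scores each
    focal male's paternity share under sperm-competition conditions, his
    mating-order index (how often he held the last-male position) and his
    repetitive matings; partitions the explained variance in paternity share
    into mating-order, repetitive-mating and remaining components by
    all-possible-subsets commonality analysis; fits quasi-binomial and
    quasi-Poisson models of the scores on group composition; and simulates
    replicate mating groups with last-male sperm precedence so every stage
    of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
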