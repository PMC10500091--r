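Package: phenovar
Title: Phenotype- and Genotype-Driven Ranking of Candidate Genetic Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate rare genetic disorders for a single patient by
    fusing two independent evidence streams: a per-gene pathogenicity score
    obtained by assigning ACMG-AMP evidence codes to annotated variants and
    combining them through a Bayesian odds framework, and a phenotype score
    obtained by comparing the patient's Human Phenotype Ontology (HPO) term
    set against disease annotation profiles with a blend of topological and
    information-content semantic similarity. Includes an allele-frequency and
    inheritance-mode variant screen, a TOP-k benchmark harness with a paired
    Wilcoxon signed-rank comparison, and a deterministic synthetic fixture
    generator (toy ontologies, annotation corpora, patient cases with spiked
    causal variants) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
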