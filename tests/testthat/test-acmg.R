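test_that("the rule table assigns the expected evidence codes", {
  gm <- data.frame(gene = "GENE1", lof_mechanism = TRUE,
                   missense_constrained = FALSE, truncating_mechanism = FALSE,
                   bs1_max_af = 0.01, stringsAsFactors = FALSE)
  # stop-gain, AF absent, LOF-mechanism gene
  v <- variant_row(consequence = "stop_gained")
  expect_true(all(c("PVS1", "PM2") %in% assign_evidence(v, gm)))
  # synonymous, AF 0.2: BA1; BP7 once splice impact is known absent
  v2 <- variant_row(consequence = "synonymous", pop_af = 0.2)
  expect_true("BA1" %in% assign_evidence(v2, gm))
  v2$splice_impact <- FALSE
  expect_true(all(c("BA1", "BP7") %in% assign_evidence(v2, gm)))
  # every optional annotation field missing, AF present and unremarkable
  v3 <- variant_row(consequence = "missense", pop_af = 0.01)
  expect_identical(assign_evidence(v3, gene_meta = NULL), character(0))
})

test_that("rules lacking inputs stay silent and can be disabled", {
  gm <- data.frame(gene = "GENE1", lof_mechanism = TRUE,
                   bs1_max_af = NA_real_, stringsAsFactors = FALSE)
  v <- variant_row(consequence = "stop_gained", pop_af = 0.02)
  expect_identical(assign_evidence(v, gm), "PVS1")
  rules <- default_acmg_rules()
  rules$enabled[["PVS1"]] <- FALSE
  expect_identical(assign_evidence(v, gm, rules), character(0))
})

test_that("precomputed evidence codes are ingested and validated", {
  v <- variant_row(acmg_codes = "PVS1,PM2")
  expect_identical(assign_evidence(v), c("PM2", "PVS1"))
  expect_error(evidence_vector(c("PVS1", "PX9")), "unknown ACMG evidence code")
  rules <- default_acmg_rules()
  rules$use_precomputed <- FALSE
  # falls through to rule evaluation (AF absent -> PM2 only)
  expect_identical(assign_evidence(v, rules = rules), "PM2")
})

test_that("the Bayesian combiner matches its closed form on key points", {
  # neutral exponent: posterior equals the prior
  expect_equal(posterior_probability(character(0))$posterior, 0.1)
  # one strong pathogenic + one strong benign cancel exactly
  expect_equal(posterior_probability(c("PS1", "BS1"))$posterior, 0.1,
               tolerance = 1e-12)
  # PVS1 + one moderate: exponent 1.25
  got <- posterior_probability(c("PVS1", "PM2"))
  expect_equal(got$posterior, oracle_posterior(1, 0, 1, 0, 0, 0),
               tolerance = 1e-12)
  expect_identical(got$classification, "pathogenic")
  # BA1 stand-alone override beats any pathogenic evidence
  ba <- posterior_probability(c("BA1", "PVS1", "PM2"))
  expect_identical(ba$posterior, 0)
  expect_identical(ba$classification, "benign")
  # posterior strictly inside (0,1) away from the override
  lo <- posterior_probability(c("BS1", "BS2", "BP1", "BP3", "BP4", "BP6", "BP7"))
  expect_gt(lo$posterior, 0)
  expect_identical(lo$classification, "benign") # < 0.001 band
})

test_that("gene scores take the maximum variant posterior, order-independently", {
  gm <- data.frame(gene = c("G1", "G2"), lof_mechanism = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  v <- variant_table(
    variant_row(gene = "G1", pos = 1L, consequence = "stop_gained"),
    variant_row(gene = "G1", pos = 2L, consequence = "missense", pop_af = 0.01),
    variant_row(gene = "G2", pos = 3L, consequence = "missense", pop_af = 0.01))
  gs <- gene_scores(v, gm)
  expect_identical(gs$gene, c("G1", "G2"))
  expect_equal(gs$score[gs$gene == "G1"], oracle_posterior(1, 0, 1, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(gs$score[gs$gene == "G2"], 0.1)
  # permutation invariance
  gs2 <- gene_scores(v[c(3, 1, 2), ], gm)
  expect_equal(gs, gs2, ignore_attr = TRUE)
  expect_identical(nrow(gene_scores(v[0, ], gm)), 0L)
})

test_that("YAML config overrides rules and field map, rejecting unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  pm2_af_max: 0.001",
               "  enabled:",
               "    BP7: false",
               "field_map:",
               "  gene: SYMBOL"), path)
  cfg <- load_config(path)
  expect_identical(cfg$rules$pm2_af_max, 0.001)
  expect_false(cfg$rules$enabled[["BP7"]])
  expect_identical(unname(cfg$field_map[["gene"]]), "SYMBOL")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:", "  not_a_rule: 1"), bad)
  expect_error(load_config(bad), "unknown rules_config key")
})
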