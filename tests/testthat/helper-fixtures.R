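# In-code fixtures shared across test files.

# root <- A <- B <- C chain.
chain_obo <- function() {
  c("[Term]", "id: HP:0000001", "name: root",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002",
    "[Term]", "id: HP:0000004", "name: C", "is_a: HP:0000003")
}

# Diamond: C has parents A and B, both children of root.
diamond_obo <- function() {
  c("[Term]", "id: HP:0000001", "name: root",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000001",
    "[Term]", "id: HP:0000004", "name: C", "is_a: HP:0000002",
    "is_a: HP:0000003")
}

# Multi-parent term X with unequal-length paths to the root:
# root <- A <- B <- X (length 3) and root <- D <- X (length 2).
uneven_obo <- function() {
  c("[Term]", "id: HP:0000001", "name: root",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002",
    "[Term]", "id: HP:0000005", "name: D", "is_a: HP:0000001",
    "[Term]", "id: HP:0000006", "name: X", "is_a: HP:0000003",
    "is_a: HP:0000005")
}

# Ontology and 4-disease corpus giving ic(p) = ln 2, ic(t1) = ic(t2) = ln 4:
# p under root with children t1, t2; u a separate child of the root.
ic_toy <- function() {
  obo <- c("[Term]", "id: HP:0000001", "name: root",
           "[Term]", "id: HP:0000002", "name: p", "is_a: HP:0000001",
           "[Term]", "id: HP:0000003", "name: t1", "is_a: HP:0000002",
           "[Term]", "id: HP:0000004", "name: t2", "is_a: HP:0000002",
           "[Term]", "id: HP:0000005", "name: u", "is_a: HP:0000001")
  ont <- parse_obo(obo)
  corpus <- annotation_corpus(list(
    D1 = "HP:0000003", D2 = "HP:0000004",
    D3 = "HP:0000005", D4 = "HP:0000005"))
  list(ontology = ont, corpus = corpus, ic = compute_ic(ont, corpus))
}

hp_snippet_path <- function() {
  system.file("extdata", "hp_snippet.obo", package = "phenovar")
}

# One fully annotated variant row; override fields as needed.
variant_row <- function(...) {
  v <- data.frame(chrom = "1", pos = 1000L, ref = "G", alt = "A",
                  gene = "GENE1", genotype = "het", pop_af = NA_real_,
                  consequence = NA_character_, insilico = NA_real_,
                  assertion = NA_character_, hotspot = NA, control_hom = NA,
                  case_control = NA, known_change = NA_character_,
                  repeat_region = NA, splice_impact = NA,
                  acmg_codes = NA_character_, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) v[[nm]] <- args[[nm]]
  v
}

# Stack several variant_row() results.
variant_table <- function(...) {
  do.call(rbind, c(list(...), list(make.row.names = FALSE)))
}

# Independent high-precision oracle for the Bayesian combiner: evaluates the
# tiered-odds exponent in closed form, without the per-item product the
# implementation uses.
oracle_posterior <- function(pvs, ps, pm, pp, bs, bp,
                             prior = 0.1, opvs = 350) {
  expo <- pvs + ps / 2 + pm / 4 + pp / 8 - bs / 2 - bp / 8
  odds <- exp(expo * log(opvs))
  odds * prior / ((odds - 1) * prior + 1)
}

# First k code names of each tier, used to realize a count lattice point.
codes_for_counts <- function(pvs = 0, ps = 0, pm = 0, pp = 0, bs = 0, bp = 0) {
  c(head(c("PVS1"), pvs),
    head(c("PS1", "PS4"), ps),
    head(c("PM1", "PM2", "PM4", "PM5"), pm),
    head(c("PP2", "PP3", "PP5"), pp),
    head(c("BS1", "BS2"), bs),
    head(c("BP1", "BP3", "BP4", "BP6", "BP7"), bp))
}

small_fixtures <- function(seed = 1, n_cases = 5, ...) {
  make_corpus_and_cases(synth_config(
    seed = seed, n_terms = 60, n_diseases = 12, n_genes = 16,
    terms_per_disease = 6, n_cases = n_cases,
    n_background_variants = 10, ...))
}
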