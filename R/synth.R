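# Deterministic synthetic fixture generator: toy ontologies, disease
# annotation corpora, gene-disease maps and patient cases (noisy HPO terms
# plus a spiked causal variant among benign-profile background variants).
# Stands in for access-restricted patient cohorts so the whole pipeline is
# testable offline; see the methods vignette for what the noise model does
# and does not emulate.

resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

#' Configuration of the synthetic fixture generator
#'
#' All randomness flows from `seed` (with per-case derived substreams), so
#' identical configurations yield byte-identical fixtures. Defaults describe
#' a moderately noisy clinical scenario; see the methods vignette for the
#' rationale behind each value.
#'
#' @param seed Integer master seed.
#' @param n_terms Number of ontology terms including the root (>= 2).
#' @param n_diseases,n_genes Corpus sizes; `n_genes >= n_diseases` so every
#'   disease gets a distinct causal gene.
#' @param branching Target out-degree of ontology terms; smaller values give
#'   deeper graphs.
#' @param terms_per_disease Annotation terms per disease.
#' @param p_drop Probability a true patient term is omitted.
#' @param p_add Per-true-term probability of adding one random term.
#' @param p_generalize Probability a kept term is replaced by a parent.
#' @param n_cases Number of patient cases.
#' @param n_background_variants Benign-profile background variants per case.
#' @param p_common_background Fraction of background variants drawn from the
#'   common-frequency stratum (caught by the alpha filter or BA1); the rest
#'   are rare with benign in-silico profiles.
#' @param causal_template Fields of the spiked causal variant; the default
#'   (`stop_gained`, absent population AF) triggers PVS1 + PM2 in a
#'   loss-of-function gene.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_terms = 150L, n_diseases = 60L,
                         n_genes = 80L, branching = 3L,
                         terms_per_disease = 8L,
                         p_drop = 0.2, p_add = 0.2, p_generalize = 0.1,
                         n_cases = 100L, n_background_variants = 30L,
                         p_common_background = 0.5,
                         causal_template = list(consequence = "stop_gained",
                                                pop_af = NA_real_)) {
  stopifnot(n_terms >= 2L, n_diseases >= 1L, n_genes >= 1L, branching >= 1L,
            terms_per_disease >= 1L, n_cases >= 1L,
            n_background_variants >= 0L,
            p_drop >= 0, p_drop <= 1, p_add >= 0, p_add <= 1,
            p_generalize >= 0, p_generalize <= 1,
            p_common_background >= 0, p_common_background <= 1)
  if (terms_per_disease > n_terms - 1L) {
    stop("terms_per_disease exceeds the number of non-root terms")
  }
  if (n_genes < n_diseases) {
    stop("n_genes must be at least n_diseases (one distinct causal gene per disease)")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a toy rooted DAG ontology as OBO text
#'
#' Every non-root term gets a primary parent by breadth-first fill (the
#' earliest term with fewer than `branching` children), plus a random
#' second parent with probability 0.25, so the graph is a genuine
#' multi-parent DAG of depth about `log_branching(n_terms)`. Output is
#' valid OBO parseable by [parse_obo()].
#'
#' @param config A `synth_config`.
#' @return Character vector of OBO lines.
#' @export
make_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_terms
  ids <- sprintf("HP:%07d", seq_len(n))
  nms <- c("All", sprintf("Synthetic phenotype %03d", seq_len(n - 1L) + 1L))
  parents <- vector("list", n)
  parents[[1L]] <- integer(0)
  n_children <- integer(n)
  for (i in seq_len(n)[-1L]) {
    pool <- which(n_children[seq_len(i - 1L)] < config$branching)
    if (!length(pool)) pool <- seq_len(i - 1L)
    ps <- pool[1L] # breadth-first fill bounds the out-degree by `branching`
    if (i > 2L && stats::runif(1) < 0.25) {
      extra <- setdiff(seq_len(i - 1L), ps)
      if (length(extra)) ps <- c(ps, resample(extra))
    }
    parents[[i]] <- ps
    n_children[ps] <- n_children[ps] + 1L
  }
  out <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    out <- c(out, "[Term]", paste0("id: ", ids[i]), paste0("name: ", nms[i]))
    for (p in parents[[i]]) {
      out <- c(out, paste0("is_a: ", ids[p], " ! ", nms[p]))
    }
    out <- c(out, "")
  }
  out
}

perturb_terms <- function(terms, ontology, p_drop, p_add, p_generalize, pool) {
  keep <- terms[stats::runif(length(terms)) >= p_drop]
  if (length(keep) && p_generalize > 0) {
    gen <- stats::runif(length(keep)) < p_generalize
    for (i in which(gen)) {
      pars <- setdiff(ontology$parents[[keep[i]]], ontology$root)
      if (length(pars)) keep[i] <- resample(pars)
    }
  }
  n_add <- stats::rbinom(1L, length(terms), p_add)
  if (n_add > 0L) keep <- c(keep, resample(pool, n_add))
  unique(keep)
}

#' Generate an annotation corpus, gene-disease map and patient cases
#'
#' Each disease receives a distinct random term set, one distinct causal
#' gene and one inheritance mode. Each case picks a causal disease, perturbs
#' its term set with the configured noise, and spikes one causal variant
#' (genotype consistent with the inheritance mode) into the causal gene
#' among `n_background_variants` benign-profile background variants in
#' random genes, so the frequency screen and the benign ACMG rules are
#' genuinely exercised. Cases whose phenotype becomes empty after noise are
#' flagged invalid and skipped downstream with a warning.
#'
#' @param config A `synth_config`.
#' @param obo Optional pre-generated OBO text (defaults to
#'   [make_ontology()] on the same config).
#' @return A fixture list with elements `obo`, `ontology`, `corpus`,
#'   `gene_disease`, `gene_meta`, `cases` (each with `id`, `hpo`,
#'   `variants`, `vcf`, `causal_disease`, `causal_gene`, `valid`), `truth`
#'   and `config`.
#' @export
make_corpus_and_cases <- function(config, obo = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(obo)) obo <- make_ontology(config)
  ont <- parse_obo(obo)
  nonroot <- setdiff(ont$ids, ont$root)

  set.seed(derived_seed(config$seed, 0L))
  nd <- config$n_diseases
  dids <- sprintf("SD:%06d", seq_len(nd))
  dnames <- sprintf("Synthetic disorder %d", seq_len(nd))
  sets <- list()
  seen <- character(0)
  for (k in seq_len(nd)) {
    for (try in 1:100) {
      s <- sort(resample(nonroot, config$terms_per_disease))
      sig <- paste(s, collapse = "|")
      if (!(sig %in% seen)) break
    }
    seen <- c(seen, sig)
    sets[[dids[k]]] <- s
  }
  corpus <- annotation_corpus(sets, stats::setNames(dnames, dids))

  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  causal_genes <- resample(genes, nd)
  modes <- sample(c("AD", "AR", "XLD", "XLR"), nd, replace = TRUE,
                  prob = c(0.5, 0.3, 0.05, 0.15))
  gene_disease <- data.frame(gene = causal_genes, disease_id = dids,
                             inheritance = modes, stringsAsFactors = FALSE)
  chrom <- stats::setNames(as.character(sample(1:22, config$n_genes,
                                               replace = TRUE)), genes)
  chrom[causal_genes[modes %in% c("XLD", "XLR")]] <- "X"
  background_only <- setdiff(genes, causal_genes)
  gene_meta <- data.frame(
    gene = genes,
    chrom = unname(chrom[genes]),
    lof_mechanism = genes %in% causal_genes,
    missense_constrained = stats::runif(config$n_genes) < 0.2 &
      genes %in% causal_genes,
    truncating_mechanism = stats::runif(config$n_genes) < 0.1 &
      genes %in% background_only,
    bs1_max_af = 0.01,
    stringsAsFactors = FALSE
  )

  bases <- c("A", "C", "G", "T")
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    set.seed(derived_seed(config$seed, i))
    d <- resample(dids)
    g <- gene_disease$gene[gene_disease$disease_id == d]
    mode <- gene_disease$inheritance[gene_disease$disease_id == d]
    hpo <- perturb_terms(sets[[d]], ont, config$p_drop, config$p_add,
                         config$p_generalize, pool = nonroot)
    valid <- length(hpo) > 0L
    if (!valid) {
      warning(sprintf("case %d has no phenotype terms after noise; flagged invalid", i))
    }
    geno <- switch(mode, AR = "hom_alt", XLR = "hemi", "het")
    ref <- resample(bases)
    causal <- data.frame(
      chrom = unname(chrom[g]), pos = sample.int(1e8L, 1L), ref = ref,
      alt = resample(setdiff(bases, ref)), gene = g, genotype = geno,
      pop_af = as.numeric(config$causal_template$pop_af),
      consequence = as.character(config$causal_template$consequence),
      insilico = NA_real_, assertion = NA_character_, hotspot = NA,
      control_hom = NA, case_control = NA, known_change = NA_character_,
      repeat_region = NA, splice_impact = NA, acmg_codes = NA_character_,
      stringsAsFactors = FALSE)
    nb <- config$n_background_variants
    bg <- NULL
    if (nb > 0L) {
      bgene <- resample(genes, nb, replace = TRUE)
      common <- stats::runif(nb) < config$p_common_background
      csq <- sample(c("missense", "synonymous"), nb, replace = TRUE,
                    prob = c(0.6, 0.4))
      bref <- resample(bases, nb, replace = TRUE)
      balt <- vapply(bref, function(r) resample(setdiff(bases, r)), "")
      bg <- data.frame(
        chrom = unname(chrom[bgene]), pos = sample.int(1e8L, nb), ref = bref,
        alt = balt, gene = bgene, genotype = "het",
        pop_af = ifelse(common, stats::runif(nb, 0.12, 0.6),
                        stats::runif(nb, 0.001, 0.09)),
        consequence = csq,
        insilico = stats::runif(nb, 0, 0.18),
        assertion = ifelse(stats::runif(nb) < 0.3, "benign", NA_character_),
        hotspot = NA, control_hom = NA, case_control = NA,
        known_change = NA_character_, repeat_region = NA,
        splice_impact = ifelse(csq == "synonymous", FALSE, NA),
        acmg_codes = NA_character_,
        stringsAsFactors = FALSE)
    }
    variants <- if (is.null(bg)) causal else
      do.call(rbind, list(causal, bg, make.row.names = FALSE))
    cases[[i]] <- list(id = sprintf("case_%03d", i), hpo = hpo,
                       variants = variants, vcf = variants_to_vcf(variants),
                       causal_disease = d, causal_gene = g, valid = valid)
  }

  truth <- data.frame(
    case_id = vapply(cases, `[[`, "", "id"),
    disease_id = vapply(cases, `[[`, "", "causal_disease"),
    gene = vapply(cases, `[[`, "", "causal_gene"),
    valid = vapply(cases, function(cs) cs$valid, logical(1)),
    stringsAsFactors = FALSE)

  list(obo = obo, ontology = ont, corpus = corpus,
       gene_disease = gene_disease, gene_meta = gene_meta,
       cases = cases, truth = truth, config = config)
}

# Per-case substream seed, kept strictly below 2^31.
derived_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 1) %% 2147483647)
}

#' Serialize a variant table to VCF text
#'
#' Writes one VCF 4.2 record per variant with the annotation INFO keys of
#' [default_field_map()] and a single-sample GT column (`0/1`, `1/1` or
#' hemizygous `1`). Records are sorted by chromosome then position; missing
#' annotation values are simply omitted from INFO, so a read-back through
#' [read_variants()] restores them as `NA`.
#'
#' @param variants Variant `data.frame`.
#' @return Character vector of VCF lines.
#' @export
variants_to_vcf <- function(variants) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=INSILICO,Number=1,Type=Float,Description=\"In-silico pathogenicity score\">",
    "##INFO=<ID=ASSERT,Number=1,Type=String,Description=\"Clinical assertion\">",
    "##INFO=<ID=HOTSPOT,Number=1,Type=Integer,Description=\"In mutational hotspot\">",
    "##INFO=<ID=CTRLHOM,Number=1,Type=Integer,Description=\"Homozygous in controls\">",
    "##INFO=<ID=CASECTRL,Number=1,Type=Integer,Description=\"Case-control enrichment\">",
    "##INFO=<ID=KNOWN,Number=1,Type=String,Description=\"Relation to known pathogenic change\">",
    "##INFO=<ID=REPEATRGN,Number=1,Type=Integer,Description=\"In repeat region\">",
    "##INFO=<ID=SPLICE,Number=1,Type=Integer,Description=\"Predicted splice impact\">",
    "##INFO=<ID=ACMG,Number=1,Type=String,Description=\"Precomputed ACMG evidence codes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  if (!nrow(variants)) return(hdr)
  o <- order(variants$chrom, variants$pos, variants$alt)
  v <- variants[o, , drop = FALSE]
  fmt_num <- function(x) sprintf("%.6g", x)
  fmt_lgl <- function(x) ifelse(x, "1", "0")
  recs <- vapply(seq_len(nrow(v)), function(i) {
    kv <- c(
      paste0("GENE=", v$gene[i]),
      if (!is.na(v$pop_af[i])) paste0("AF=", fmt_num(v$pop_af[i])),
      if (!is.na(v$consequence[i])) paste0("CSQ=", v$consequence[i]),
      if (!is.na(v$insilico[i])) paste0("INSILICO=", fmt_num(v$insilico[i])),
      if (!is.na(v$assertion[i])) paste0("ASSERT=", v$assertion[i]),
      if (!is.na(v$hotspot[i])) paste0("HOTSPOT=", fmt_lgl(v$hotspot[i])),
      if (!is.na(v$control_hom[i])) paste0("CTRLHOM=", fmt_lgl(v$control_hom[i])),
      if (!is.na(v$case_control[i])) paste0("CASECTRL=", fmt_lgl(v$case_control[i])),
      if (!is.na(v$known_change[i])) paste0("KNOWN=", v$known_change[i]),
      if (!is.na(v$repeat_region[i])) paste0("REPEATRGN=", fmt_lgl(v$repeat_region[i])),
      if (!is.na(v$splice_impact[i])) paste0("SPLICE=", fmt_lgl(v$splice_impact[i])),
      if (!is.na(v$acmg_codes[i])) paste0("ACMG=", v$acmg_codes[i])
    )
    gt <- switch(v$genotype[i], het = "0/1", hom_alt = "1/1", hemi = "1",
                 stop("unknown genotype: ", v$genotype[i]))
    paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
          paste(kv, collapse = ";"), "GT", gt, sep = "\t")
  }, character(1))
  c(hdr, recs)
}

#' Write a fixture set to disk
#'
#' Emits `hp_toy.obo`, `annotations.tsv` (HPOA-style), `gene_disease.tsv`,
#' `gene_meta.tsv`, `truth.tsv` and, for each valid case,
#' `cases/<id>.vcf` and `cases/<id>.hpo`.
#'
#' @param fx Fixture set from [make_corpus_and_cases()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(file.path(dir, "cases"), recursive = TRUE, showWarnings = FALSE)
  writeLines(fx$obo, file.path(dir, "hp_toy.obo"))
  rows <- unlist(lapply(names(fx$corpus$disease_terms), function(d) {
    paste(d, fx$corpus$disease_names[[d]], "", fx$corpus$disease_terms[[d]],
          sep = "\t")
  }))
  writeLines(c("#synthetic disease-phenotype annotations",
               "database_id\tdisease_name\tqualifier\thpo_id", rows),
             file.path(dir, "annotations.tsv"))
  utils::write.table(fx$gene_disease, file.path(dir, "gene_disease.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$gene_meta, file.path(dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cs in fx$cases) {
    if (!isTRUE(cs$valid)) next
    writeLines(cs$vcf, file.path(dir, "cases", paste0(cs$id, ".vcf")))
    writeLines(cs$hpo, file.path(dir, "cases", paste0(cs$id, ".hpo")))
  }
  invisible(dir)
}

#' Read a fixture set back from disk
#'
#' Inverse of [write_fixtures()]: parses the ontology, corpus, gene tables,
#' truth table and every case's VCF and HPO files through the package's own
#' readers.
#'
#' @param dir Fixture directory.
#' @return Fixture list in the same shape as [make_corpus_and_cases()].
#' @export
read_fixtures <- function(dir) {
  ont <- parse_obo(file.path(dir, "hp_toy.obo"))
  corpus <- read_hpoa(file.path(dir, "annotations.tsv"), ont)
  gd <- read_gene_disease(file.path(dir, "gene_disease.tsv"))
  gm <- read_gene_meta(file.path(dir, "gene_meta.tsv"))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  cases <- lapply(which(truth$valid), function(i) {
    id <- truth$case_id[i]
    list(id = id,
         hpo = read_patient_terms(file.path(dir, "cases", paste0(id, ".hpo"))),
         variants = read_variants(file.path(dir, "cases", paste0(id, ".vcf")),
                                  format = "vcf"),
         causal_disease = truth$disease_id[i],
         causal_gene = truth$gene[i],
         valid = TRUE)
  })
  list(obo = readLines(file.path(dir, "hp_toy.obo"), warn = FALSE),
       ontology = ont, corpus = corpus, gene_disease = gd, gene_meta = gm,
       cases = cases, truth = truth)
}
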