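# End-to-end case analysis and the benchmark evaluation loop.

#' Rank candidate genetic disorders for one patient
#'
#' Runs the full pipeline: the alpha allele-frequency screen and the
#' inheritance-mode screen on the variants, ACMG evidence assignment and
#' Bayesian combination to per-gene scores, phenotype scoring of the
#' patient's HPO terms against every corpus disease, and gamma-fusion into
#' the final ranking. The two evidence streams are analyzed independently:
#' either may be omitted, in which case the other alone drives the ranking.
#'
#' @param ontology An `hpo_ontology`.
#' @param corpus An `annotation_corpus` (the candidate-disease universe).
#' @param gene_disease Gene-disease association `data.frame`.
#' @param gene_meta Optional gene metadata for the rule engine.
#' @param patient_terms Character vector of patient HPO term ids, or `NULL`.
#' @param variants Variant `data.frame` from [read_variants()], or `NULL`.
#' @param alpha Allele-frequency screen threshold (default 0.1).
#' @param beta Phenotype blend weight (default 0.9).
#' @param gamma Fusion weight of the gene score (default 0.5).
#' @param sex Optional patient sex for the X-linked screen.
#' @param bayes Parameters from [bayes_params()].
#' @param rules Rule table from [default_acmg_rules()].
#' @param ic Optional precomputed IC table.
#' @param sim_cache Optional precomputed `sim_cache`.
#' @return Ranked disease `data.frame` (see [rank_diseases()]).
#' @export
rank_disorders <- function(ontology, corpus, gene_disease, gene_meta = NULL,
                           patient_terms = NULL, variants = NULL,
                           alpha = 0.1, beta = 0.9, gamma = 0.5, sex = NULL,
                           bayes = bayes_params(),
                           rules = default_acmg_rules(),
                           ic = NULL, sim_cache = NULL) {
  if (is.null(patient_terms) && is.null(variants)) {
    stop("no input evidence: supply HPO terms and/or variants")
  }
  gs <- NULL
  if (!is.null(variants) && nrow(variants)) {
    va <- filter_af(variants, alpha)
    by_gene <- filter_inheritance(va, gene_modes(gene_disease), sex = sex)
    if (length(by_gene)) {
      surv <- do.call(rbind, c(unname(by_gene), list(make.row.names = FALSE)))
      gs <- gene_scores(surv, gene_meta, bayes, rules)
    }
  }
  ps <- NULL
  if (!is.null(patient_terms) && length(patient_terms)) {
    if (is.null(ic)) ic <- compute_ic(ontology, corpus)
    ps <- phenotype_scores(patient_terms, corpus, ontology, ic = ic,
                           beta = beta, sim_cache = sim_cache)
  }
  if ((is.null(gs) || !nrow(gs)) && is.null(ps)) {
    stop("no variants survived screening and no phenotype was provided")
  }
  rank_diseases(gs, ps, gene_disease, gamma = gamma,
                disease_names = corpus$disease_names)
}

#' Evaluate a synthetic case collection end to end
#'
#' Runs [rank_disorders()] on every valid case of a fixture set (see
#' [make_corpus_and_cases()]), recording the rank of the causal disease and
#' of the causal gene (through [gene_ranking()]). IC and the pairwise
#' term-similarity cache are computed once and shared across cases.
#'
#' @param fx Fixture set from [make_corpus_and_cases()] or
#'   [read_fixtures()].
#' @param alpha,beta,gamma Pipeline parameters.
#' @param sex Optional patient sex.
#' @return `data.frame` with columns `case_id`, `causal_disease`,
#'   `causal_gene`, `disease_rank`, `gene_rank`, `n_ranked_genes`.
#' @export
evaluate_cases <- function(fx, alpha = 0.1, beta = 0.9, gamma = 0.5,
                           sex = NULL) {
  ont <- fx$ontology
  ic <- compute_ic(ont, fx$corpus)
  sc <- build_sim_cache(ont, ic)
  cases <- Filter(function(cs) isTRUE(cs$valid), fx$cases)
  if (!length(cases)) stop("no valid cases to evaluate")
  rows <- lapply(cases, function(cs) {
    ranked <- rank_disorders(ont, fx$corpus, fx$gene_disease, fx$gene_meta,
                             patient_terms = cs$hpo, variants = cs$variants,
                             alpha = alpha, beta = beta, gamma = gamma,
                             sex = sex, ic = ic, sim_cache = sc)
    drank <- ranked$rank[match(cs$causal_disease, ranked$disease_id)]
    granks <- gene_ranking(ranked, fx$gene_disease)
    data.frame(case_id = cs$id,
               causal_disease = cs$causal_disease,
               causal_gene = cs$causal_gene,
               disease_rank = if (length(drank)) drank else NA_real_,
               gene_rank = {
                 r <- match(cs$causal_gene, granks)
                 if (is.na(r)) NA_real_ else as.numeric(r)
               },
               n_ranked_genes = length(granks),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Random-permutation baseline gene ranks for a case collection
#'
#' For each valid case, ranks the candidate genes in a fresh random order
#' and records the causal gene's position. Serves as the uninformed
#' baseline a real ranking must beat.
#'
#' @param fx Fixture set.
#' @param seed Integer seed.
#' @return Numeric vector of causal-gene ranks, one per valid case.
#' @export
random_baseline_ranks <- function(fx, seed = 1L) {
  genes <- sort(unique(as.character(fx$gene_disease$gene)))
  cases <- Filter(function(cs) isTRUE(cs$valid), fx$cases)
  set.seed(seed)
  vapply(cases, function(cs) {
    as.numeric(match(cs$causal_gene, sample(genes)))
  }, numeric(1))
}
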