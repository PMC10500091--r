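# Score fusion, disease/gene ranking and the TOP-k benchmark harness.

#' Fuse gene and phenotype scores and rank candidate diseases
#'
#' The combined score of a disease is the convex combination
#' `gamma * gene_score + (1 - gamma) * phenotype_score`, where the gene
#' score is the maximum score over the disease's linked genes (0 when none
#' is supported by a surviving variant) and the phenotype score is the
#' normalized blend from [phenotype_scores()] (0 for diseases absent from
#' the phenotype scoring, e.g. when no HPO terms were given). Diseases are
#' sorted by decreasing combined score; ties are broken by higher phenotype
#' score, then lexicographic disease id, so the ranking is a deterministic
#' total order.
#'
#' @param gene_scores `data.frame` from [gene_scores()], or `NULL` when no
#'   variant data was supplied.
#' @param phen_scores `data.frame` from [phenotype_scores()], or `NULL`.
#' @param gene_disease Gene-disease association `data.frame` (columns
#'   `gene`, `disease_id`, `inheritance`).
#' @param gamma Gene-score weight in `[0, 1]` (default 0.5, the equal-weight
#'   sum).
#' @param disease_names Optional named character vector of display names.
#' @return `data.frame` with columns `rank`, `disease_id`, `disease_name`,
#'   `gene`, `gene_score`, `phenotype_score`, `combined_score`,
#'   `triggered_evidence`.
#' @export
rank_diseases <- function(gene_scores = NULL, phen_scores = NULL,
                          gene_disease, gamma = 0.5, disease_names = NULL) {
  stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1)
  has_g <- !is.null(gene_scores) && nrow(gene_scores) > 0L
  has_p <- !is.null(phen_scores) && nrow(phen_scores) > 0L
  if (!has_g && !has_p) stop("no input evidence: both score sources are empty")

  gs <- if (has_g) stats::setNames(gene_scores$score, gene_scores$gene)
        else stats::setNames(numeric(0), character(0))
  gev <- if (has_g) stats::setNames(gene_scores$evidence, gene_scores$gene)
         else stats::setNames(character(0), character(0))
  ps <- if (has_p) stats::setNames(phen_scores$normalized, phen_scores$disease_id)
        else stats::setNames(numeric(0), character(0))

  gmap <- split(as.character(gene_disease$gene),
                as.character(gene_disease$disease_id))
  cand <- unique(c(names(ps),
                   as.character(gene_disease$disease_id)[
                     gene_disease$gene %in% names(gs)]))
  if (!length(cand)) stop("no candidate diseases")

  nd <- length(cand)
  gsc <- numeric(nd); psc <- numeric(nd)
  best <- rep(NA_character_, nd); evd <- rep(NA_character_, nd)
  for (k in seq_len(nd)) {
    d <- cand[k]
    g <- intersect(gmap[[d]], names(gs))
    if (length(g)) {
      sc <- gs[g]
      gsc[k] <- max(sc)
      best[k] <- sort(g[sc == gsc[k]])[1]
      evd[k] <- unname(gev[best[k]])
    }
    if (d %in% names(ps)) psc[k] <- ps[[d]]
  }
  comb <- gamma * gsc + (1 - gamma) * psc
  o <- order(-comb, -psc, cand)
  nm <- if (is.null(disease_names)) cand else {
    x <- unname(disease_names[cand]); x[is.na(x)] <- cand[is.na(x)]; x
  }
  data.frame(rank = seq_len(nd),
             disease_id = cand[o],
             disease_name = nm[o],
             gene = best[o],
             gene_score = gsc[o],
             phenotype_score = psc[o],
             combined_score = comb[o],
             triggered_evidence = evd[o],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene ranking derived from a disease ranking
#'
#' Orders genes by the best (minimum) rank of any linked disease, so the
#' disease-level ranking can be read as a causal-gene ranking for
#' benchmarking. Each gene appears once; genes none of whose diseases were
#' ranked are excluded. Ties share the disease rank and are broken by gene
#' symbol.
#'
#' @param ranked Output of [rank_diseases()].
#' @param gene_disease Gene-disease association `data.frame`.
#' @return Ordered character vector of gene symbols (position = gene rank).
#' @export
gene_ranking <- function(ranked, gene_disease) {
  rk <- stats::setNames(ranked$rank, ranked$disease_id)
  by_gene <- split(as.character(gene_disease$disease_id),
                   as.character(gene_disease$gene))
  minr <- vapply(by_gene, function(ds) {
    r <- rk[ds[ds %in% names(rk)]]
    if (length(r)) min(r) else NA_real_
  }, numeric(1))
  minr <- minr[!is.na(minr)]
  names(minr)[order(minr, names(minr))]
}

#' TOP-k report over a benchmark case collection
#'
#' Proportion of cases whose causal gene (or disease) falls within rank 1,
#' 5, 10, 20, 50, and beyond 50. Bands are cumulative through TOP-50 and
#' `TOP-50 + (>50) = 1`; a causal entity absent from its ranking counts in
#' the `>50` band.
#'
#' @param cases Either a numeric vector of causal ranks (`NA` = unranked),
#'   or a list of cases, each a list with elements `genes` (ranked symbols)
#'   and `causal` (the causal symbol).
#' @return Object of class `topk_report` with elements `top1`, `top5`,
#'   `top10`, `top20`, `top50`, `gt50`, `n_cases`.
#' @export
topk_report <- function(cases) {
  if (!length(cases)) stop("empty case list")
  ranks <- if (is.numeric(cases)) as.numeric(cases) else {
    vapply(cases, function(cs) {
      r <- match(cs$causal, cs$genes)
      if (is.na(r)) NA_real_ else as.numeric(r)
    }, numeric(1))
  }
  inband <- function(k) mean(!is.na(ranks) & ranks <= k)
  out <- list(top1 = inband(1), top5 = inband(5), top10 = inband(10),
              top20 = inband(20), top50 = inband(50))
  out$gt50 <- 1 - out$top50
  out$n_cases <- length(ranks)
  structure(out, class = "topk_report")
}

#' @export
print.topk_report <- function(x, ...) {
  cat(sprintf(
    "TOP-k over %d cases: TOP-1 %.1f%%, TOP-5 %.1f%%, TOP-10 %.1f%%, TOP-20 %.1f%%, TOP-50 %.1f%%, >50 %.1f%%\n",
    x$n_cases, 100 * x$top1, 100 * x$top5, 100 * x$top10, 100 * x$top20,
    100 * x$top50, 100 * x$gt50))
  invisible(x)
}

#' Paired one-sided Wilcoxon signed-rank comparison of two rank vectors
#'
#' Tests whether the first method's causal ranks are systematically smaller
#' (better) than the second's, via `stats::wilcox.test` with
#' `alternative = "less"` on the paired vectors. Zero differences are
#' dropped by the routine's standard policy and their count is reported;
#' the normal approximation with continuity correction is used so tied
#' ranks are handled without warnings. Fewer than five pairs triggers an
#' underpowered warning but the p-value is still reported. All-zero
#' differences degenerate to p = 1.
#'
#' @param ranks_a,ranks_b Equal-length numeric vectors of causal ranks.
#' @return List with `statistic`, `p_value`, `n`, `n_zero_dropped`,
#'   `method`.
#' @export
compare_ranks <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) {
    stop("rank vectors differ in length")
  }
  if (anyNA(ranks_a) || anyNA(ranks_b)) {
    stop("rank vectors must be complete; substitute a beyond-list rank for unranked cases")
  }
  if (length(ranks_a) < 5L) {
    warning("fewer than 5 paired cases; the signed-rank test is underpowered")
  }
  d <- ranks_a - ranks_b
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n = length(ranks_a),
                n_zero_dropped = length(ranks_a),
                method = "Wilcoxon signed rank (degenerate: all paired differences zero)"))
  }
  wt <- stats::wilcox.test(ranks_a, ranks_b, paired = TRUE,
                           alternative = "less", exact = FALSE,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(ranks_a), n_zero_dropped = sum(d == 0),
       method = paste("Wilcoxon signed rank, one-sided (a < b);",
                      "zero differences dropped, normal approximation",
                      "with continuity correction"))
}
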