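# ACMG-AMP evidence assignment, Bayesian combination and per-gene scoring.
#
# The evidence repertoire matches what automated annotation can support
# without segregation or functional data: PVS1; PS1, PS4; PM1, PM2, PM4,
# PM5; PP2, PP3, PP5; BA1; BS1, BS2; BP1, BP3, BP4, BP6, BP7.

.acmg_code_tier <- c(
  PVS1 = "pvs",
  PS1 = "ps", PS4 = "ps",
  PM1 = "pm", PM2 = "pm", PM4 = "pm", PM5 = "pm",
  PP2 = "pp", PP3 = "pp", PP5 = "pp",
  BA1 = "ba",
  BS1 = "bs", BS2 = "bs",
  BP1 = "bp", BP3 = "bp", BP4 = "bp", BP6 = "bp", BP7 = "bp"
)

# Exponent contribution of one evidence item, in units of the
# very-strong odds: supporting 1/8, moderate 1/4, strong 1/2, very strong 1.
.acmg_tier_weight <- c(pvs = 1, ps = 1 / 2, pm = 1 / 4, pp = 1 / 8,
                       ba = 0, bs = -1 / 2, bp = -1 / 8)

#' Supported ACMG evidence codes
#' @return Character vector of the 18 supported code names.
#' @export
acmg_codes <- function() names(.acmg_code_tier)

#' Build an evidence vector from triggered code names
#'
#' @param codes Character vector of ACMG code names (case-insensitive);
#'   duplicates are collapsed. Unknown codes raise an error.
#' @return Object of class `evidence_vector`: per-tier counts `pvs`, `ps`,
#'   `pm`, `pp`, `ba`, `bs`, `bp` plus the sorted `triggered` set.
#' @export
evidence_vector <- function(codes = character()) {
  codes <- unique(toupper(as.character(codes)))
  codes <- codes[nzchar(codes)]
  unknown <- setdiff(codes, names(.acmg_code_tier))
  if (length(unknown)) {
    stop("unknown ACMG evidence code(s): ", paste(unknown, collapse = ", "))
  }
  tiers <- .acmg_code_tier[codes]
  cnt <- function(tn) sum(tiers == tn)
  structure(
    list(pvs = cnt("pvs"), ps = cnt("ps"), pm = cnt("pm"), pp = cnt("pp"),
         ba = cnt("ba"), bs = cnt("bs"), bp = cnt("bp"),
         triggered = sort(codes)),
    class = "evidence_vector"
  )
}

#' @export
print.evidence_vector <- function(x, ...) {
  cat("evidence_vector:",
      if (length(x$triggered)) paste(x$triggered, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Parameters of the Bayesian evidence combiner
#'
#' Defaults follow the Bayesian reformulation of the ACMG-AMP combining
#' rules: prior probability of pathogenicity 0.1, odds of pathogenicity for
#' one very-strong item 350, and classification bands pathogenic >= 0.99,
#' likely pathogenic >= 0.90, likely benign <= 0.10, benign < 0.001.
#'
#' @param prior Prior probability of pathogenicity, strictly in (0, 1).
#' @param odds_pathogenic Odds assigned to one very-strong pathogenic item
#'   (> 1); weaker tiers contribute exponents 1/2, 1/4, 1/8 and benign
#'   tiers the corresponding negative exponents.
#' @param pathogenic,likely_pathogenic,likely_benign,benign Band cutoffs.
#' @return A list of validated parameters.
#' @export
bayes_params <- function(prior = 0.1, odds_pathogenic = 350,
                         pathogenic = 0.99, likely_pathogenic = 0.90,
                         likely_benign = 0.10, benign = 0.001) {
  stopifnot(prior > 0, prior < 1, odds_pathogenic > 1,
            pathogenic > likely_pathogenic,
            likely_pathogenic > likely_benign,
            likely_benign > benign, benign > 0)
  list(prior = prior, odds_pathogenic = odds_pathogenic,
       pathogenic = pathogenic, likely_pathogenic = likely_pathogenic,
       likely_benign = likely_benign, benign = benign)
}

#' Posterior pathogenicity probability of an evidence vector
#'
#' Combined odds are the product of per-item odds,
#' `odds_pathogenic ^ w(item)` with weights 1 (PVS), 1/2 (PS), 1/4 (PM),
#' 1/8 (PP), -1/2 (BS), -1/8 (BP); the posterior is
#' `odds * prior / ((odds - 1) * prior + 1)`. BA1 is stand-alone benign
#' evidence: when triggered it overrides the odds machinery, forcing the
#' posterior to 0 and the classification to "benign".
#'
#' @param ev An `evidence_vector`, or a character vector of code names.
#' @param params Parameters from [bayes_params()].
#' @return List with `posterior`, `odds`, `classification` and `evidence`.
#' @export
posterior_probability <- function(ev, params = bayes_params()) {
  if (is.character(ev)) ev <- evidence_vector(ev)
  stopifnot(inherits(ev, "evidence_vector"))
  if (ev$ba > 0L) {
    return(list(posterior = 0, odds = 0, classification = "benign",
                evidence = ev))
  }
  w <- .acmg_tier_weight[.acmg_code_tier[ev$triggered]]
  odds <- prod(params$odds_pathogenic ^ w)
  post <- odds * params$prior / ((odds - 1) * params$prior + 1)
  cls <- if (post >= params$pathogenic) "pathogenic"
    else if (post >= params$likely_pathogenic) "likely_pathogenic"
    else if (post < params$benign) "benign"
    else if (post <= params$likely_benign) "likely_benign"
    else "uncertain_significance"
  list(posterior = post, odds = odds, classification = cls, evidence = ev)
}

#' Default ACMG rule table
#'
#' A transparent, configurable re-implementation of automated ACMG evidence
#' assignment that reads fields already present on the annotated input.
#' Every rule can be disabled individually; a rule whose input fields are
#' missing stays silent. Precomputed evidence codes (e.g. from an external
#' ACMG interpreter) can be ingested directly from the variant's
#' `acmg_codes` field and then take precedence over rule evaluation.
#'
#' @return A list with per-rule `enabled` flags, thresholds
#'   (`pm2_af_max`, `ba1_af_min`, `pp3_threshold`, `bp4_threshold`),
#'   consequence vocabularies and `use_precomputed`.
#' @export
default_acmg_rules <- function() {
  list(
    enabled = stats::setNames(rep(TRUE, length(.acmg_code_tier)),
                              names(.acmg_code_tier)),
    use_precomputed = TRUE,
    pm2_af_max = 1e-4,
    ba1_af_min = 0.05,
    pp3_threshold = 0.8,
    bp4_threshold = 0.2,
    null_consequences = c("stop_gained", "frameshift", "splice_acceptor",
                          "splice_donor", "start_lost"),
    inframe_consequences = c("inframe_insertion", "inframe_deletion",
                             "stop_lost")
  )
}

#' Load rules and field map from a YAML config
#'
#' The config may carry a `rules` section (merged over
#' [default_acmg_rules()]) and a `field_map` section (merged over
#' [default_field_map()]). Unknown rule keys or unknown evidence codes in
#' `rules$enabled` are a hard error at load time.
#'
#' @param path Path to a YAML file.
#' @return List with elements `rules` and `field_map`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- default_acmg_rules()
  fm <- default_field_map()
  if (!is.null(cfg$rules)) {
    bad <- setdiff(names(cfg$rules), names(rules))
    if (length(bad)) stop("unknown rules_config key(s): ", paste(bad, collapse = ", "))
    if (!is.null(cfg$rules$enabled)) {
      badc <- setdiff(names(cfg$rules$enabled), names(.acmg_code_tier))
      if (length(badc)) stop("unknown evidence code(s) in rules_config: ",
                             paste(badc, collapse = ", "))
      for (cd in names(cfg$rules$enabled)) {
        rules$enabled[[cd]] <- isTRUE(cfg$rules$enabled[[cd]])
      }
      cfg$rules$enabled <- NULL
    }
    rules <- utils::modifyList(rules, cfg$rules)
  }
  if (!is.null(cfg$field_map)) {
    bad <- setdiff(names(cfg$field_map), names(fm))
    if (length(bad)) stop("unknown field_map key(s): ", paste(bad, collapse = ", "))
    for (k in names(cfg$field_map)) fm[[k]] <- as.character(cfg$field_map[[k]])
  }
  list(rules = rules, field_map = fm)
}

gene_meta_row <- function(gene_meta, gene) {
  if (is.null(gene_meta) || is.null(gene) || is.na(gene)) return(NULL)
  i <- match(gene, gene_meta$gene)
  if (is.na(i)) return(NULL)
  as.list(gene_meta[i, , drop = FALSE])
}

#' Assign ACMG evidence codes to one annotated variant
#'
#' Applies the rule table to the variant's annotation fields and the gene's
#' metadata. Rules lacking their inputs stay silent; a variant carrying
#' precomputed codes in `acmg_codes` (comma-separated) short-circuits rule
#' evaluation when `rules$use_precomputed` is `TRUE`.
#'
#' @param variant A one-row variant `data.frame` (see [read_variants()]) or
#'   an equivalent named list.
#' @param gene_meta Optional gene-level metadata `data.frame` with columns
#'   `gene`, `lof_mechanism`, `missense_constrained`,
#'   `truncating_mechanism`, `bs1_max_af`.
#' @param rules Rule table from [default_acmg_rules()].
#' @return Character vector of triggered code names.
#' @export
assign_evidence <- function(variant, gene_meta = NULL,
                            rules = default_acmg_rules()) {
  v <- as.list(variant)
  fld <- function(nm) {
    x <- v[[nm]]
    if (is.null(x) || length(x) != 1L || is.na(x)) NA else x
  }
  num <- function(nm) suppressWarnings(as.numeric(fld(nm)))
  flag <- function(nm) isTRUE(as.logical(fld(nm)))

  if (isTRUE(rules$use_precomputed)) {
    pre <- fld("acmg_codes")
    if (!is.na(pre) && nzchar(pre)) {
      codes <- trimws(strsplit(as.character(pre), ",", fixed = TRUE)[[1]])
      return(evidence_vector(codes)$triggered)
    }
  }

  gm <- gene_meta_row(gene_meta, v$gene)
  gflag <- function(nm) !is.null(gm) && isTRUE(as.logical(gm[[nm]]))

  csq <- fld("consequence")
  af <- num("pop_af")
  ins <- num("insilico")
  asr <- fld("assertion")
  known <- fld("known_change")
  spl <- fld("splice_impact")
  on <- function(code) isTRUE(rules$enabled[[code]])
  codes <- character(0)

  if (on("PVS1") && !is.na(csq) && csq %in% rules$null_consequences &&
      gflag("lof_mechanism")) codes <- c(codes, "PVS1")
  if (on("PS1") && identical(known, "same_aa")) codes <- c(codes, "PS1")
  if (on("PS4") && flag("case_control")) codes <- c(codes, "PS4")
  if (on("PM1") && flag("hotspot")) codes <- c(codes, "PM1")
  if (on("PM2") && (is.na(af) || af < rules$pm2_af_max)) codes <- c(codes, "PM2")
  if (on("PM4") && !is.na(csq) && csq %in% rules$inframe_consequences &&
      !flag("repeat_region")) codes <- c(codes, "PM4")
  if (on("PM5") && identical(known, "same_residue") &&
      identical(csq, "missense")) codes <- c(codes, "PM5")
  if (on("PP2") && identical(csq, "missense") &&
      gflag("missense_constrained")) codes <- c(codes, "PP2")
  if (on("PP3") && !is.na(ins) && ins >= rules$pp3_threshold) codes <- c(codes, "PP3")
  if (on("PP5") && !is.na(asr) && tolower(asr) == "pathogenic") codes <- c(codes, "PP5")
  if (on("BA1") && !is.na(af) && af > rules$ba1_af_min) codes <- c(codes, "BA1")
  if (on("BS1") && !is.na(af) && !is.null(gm)) {
    mx <- suppressWarnings(as.numeric(gm[["bs1_max_af"]]))
    if (length(mx) == 1L && !is.na(mx) && af > mx) codes <- c(codes, "BS1")
  }
  if (on("BS2") && flag("control_hom")) codes <- c(codes, "BS2")
  if (on("BP1") && identical(csq, "missense") &&
      gflag("truncating_mechanism")) codes <- c(codes, "BP1")
  if (on("BP3") && !is.na(csq) && csq %in% rules$inframe_consequences &&
      flag("repeat_region")) codes <- c(codes, "BP3")
  if (on("BP4") && !is.na(ins) && ins <= rules$bp4_threshold) codes <- c(codes, "BP4")
  if (on("BP6") && !is.na(asr) && tolower(asr) == "benign") codes <- c(codes, "BP6")
  if (on("BP7") && identical(csq, "synonymous") && !is.na(spl) &&
      !as.logical(spl)) codes <- c(codes, "BP7")

  sort(codes)
}

#' Per-gene pathogenicity scores from filtered variants
#'
#' Groups variants by gene, computes each variant's posterior pathogenicity
#' probability, and aggregates to a gene score as the maximum posterior
#' (single dominant variant, the conservative monogenic reading). The
#' result is permutation-invariant in the input order; within-gene ties are
#' broken by the lexicographically smallest variant key.
#'
#' @param variants Variant `data.frame` (already screened; see
#'   [filter_af()] and [filter_inheritance()]).
#' @param gene_meta Optional gene metadata (see [assign_evidence()]).
#' @param params Parameters from [bayes_params()].
#' @param rules Rule table from [default_acmg_rules()].
#' @return `data.frame` with columns `gene`, `score`, `n_variants`,
#'   `best_variant`, `evidence`, plus a `supporting` attribute listing every
#'   variant's key, posterior and evidence per gene.
#' @export
gene_scores <- function(variants, gene_meta = NULL, params = bayes_params(),
                        rules = default_acmg_rules()) {
  if (is.null(variants) || !nrow(variants)) {
    out <- data.frame(gene = character(0), score = numeric(0),
                      n_variants = integer(0), best_variant = character(0),
                      evidence = character(0), stringsAsFactors = FALSE)
    attr(out, "supporting") <- list()
    return(out)
  }
  key <- variant_key(variants)
  n <- nrow(variants)
  posts <- numeric(n)
  codes <- character(n)
  for (i in seq_len(n)) {
    cds <- assign_evidence(variants[i, , drop = FALSE], gene_meta, rules)
    posts[i] <- posterior_probability(cds, params)$posterior
    codes[i] <- paste(cds, collapse = ",")
  }
  genes <- sort(unique(as.character(variants$gene)))
  supporting <- stats::setNames(vector("list", length(genes)), genes)
  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    sel <- which(variants$gene == genes[k])
    sel <- sel[order(key[sel])]
    b <- sel[which.max(posts[sel])]
    rows[[k]] <- data.frame(gene = genes[k], score = posts[b],
                            n_variants = length(sel),
                            best_variant = key[b], evidence = codes[b],
                            stringsAsFactors = FALSE)
    supporting[[k]] <- data.frame(variant = key[sel], posterior = posts[sel],
                                  evidence = codes[sel],
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "supporting") <- supporting
  out
}

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}
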