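# HPO ontology: OBO parsing, DAG structure, information content, MICA.

#' Parse an OBO-format ontology into an HPO DAG
#'
#' Reads the stanza-based OBO 1.2/1.4 format used to distribute the Human
#' Phenotype Ontology (`hp.obo`). Only `[Term]` stanzas and `is_a`
#' relationships are used: the phenotypic-abnormality subontology of HPO is
#' structured by `is_a`, and other relationship types (`part_of`, ...) are
#' ignored. The result is a rooted directed acyclic graph, not a tree: a term
#' may have several parents, and depth is defined as the shortest `is_a` path
#' to the root.
#'
#' Obsolete terms are excluded from the graph but recorded together with their
#' `replaced_by` target (when present) so that stale identifiers can still be
#' resolved with [resolve_terms()]. `alt_id`s of live terms are recorded the
#' same way.
#'
#' @param x Path to an `.obo` file, or a character vector (or single string)
#'   of OBO text.
#' @return An object of class `hpo_ontology`: a list with elements `ids`,
#'   `name` (named character), `parents` and `children` (named lists of
#'   character vectors), `depth` (named integer, shortest path to root),
#'   `ancestors` (named list; reflexive transitive closure over `is_a`),
#'   `root`, `obsolete` (named character, old id -> replacement or `NA`) and
#'   `alt` (named character, alternative id -> canonical id).
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001 ! All")
#' ont <- parse_obo(obo)
#' ont$depth[["HP:0000002"]]
#' @export
parse_obo <- function(x) {
  lines <- obo_lines(x)

  recs <- list()
  cur <- NULL
  in_term <- FALSE
  push <- function() {
    if (!is.null(cur) && !is.null(cur$id)) recs[[length(recs) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (identical(ln, "[Term]")) {
      push()
      cur <- list(parents = character(), alt = character(), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # [Typedef] etc. terminate any open [Term]
      push()
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) < 3L) next
    key <- m[2]
    val <- m[3]
    id_token <- sub("\\s.*$", "", sub("\\s*!.*$", "", val))
    if (key == "id") {
      cur$id <- id_token
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, id_token)
    } else if (key == "is_obsolete") {
      cur$obsolete <- grepl("true", val, ignore.case = TRUE)
    } else if (key == "replaced_by") {
      cur$replaced_by <- id_token
    } else if (key == "alt_id") {
      cur$alt <- c(cur$alt, id_token)
    }
  }
  push()

  if (!length(recs)) stop("no [Term] stanzas found in OBO input")
  ids_all <- vapply(recs, function(r) r$id, character(1))
  if (anyDuplicated(ids_all)) {
    stop("duplicate term id in OBO input: ", ids_all[duplicated(ids_all)][1])
  }

  is_obs <- vapply(recs, function(r) isTRUE(r$obsolete), logical(1))
  live <- recs[!is_obs]
  if (!length(live)) stop("OBO input contains only obsolete terms")
  ids <- vapply(live, function(r) r$id, character(1))

  obsolete <- stats::setNames(
    vapply(recs[is_obs], function(r) {
      if (is.null(r$replaced_by)) NA_character_ else r$replaced_by
    }, character(1)),
    ids_all[is_obs]
  )
  alt_pairs <- lapply(live, function(r) stats::setNames(rep(r$id, length(r$alt)), r$alt))
  alt <- unlist(alt_pairs)
  if (is.null(alt)) alt <- stats::setNames(character(0), character(0))

  nm <- stats::setNames(
    vapply(live, function(r) if (is.null(r$name)) NA_character_ else r$name, character(1)),
    ids
  )

  # Remap is_a targets through alt ids and obsolete replacements.
  parents <- stats::setNames(lapply(live, function(r) {
    p <- unique(r$parents)
    unname(vapply(p, function(pp) {
      if (pp %in% ids) return(pp)
      if (pp %in% names(alt)) return(alt[[pp]])
      if (pp %in% names(obsolete) && !is.na(obsolete[[pp]])) return(obsolete[[pp]])
      stop("is_a parent not present in ontology: ", pp, " (child ", r$id, ")")
    }, character(1)))
  }), ids)

  roots <- ids[lengths(parents) == 0L]
  if (length(roots) == 0L) {
    stop("ontology has no root: every term has an is_a parent")
  }
  if (length(roots) > 1L) {
    stop("ontology has multiple roots: ", paste(roots, collapse = ", "))
  }
  root <- roots

  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  # Kahn topological order; leftovers indicate a cycle.
  n <- length(ids)
  unplaced <- lengths(parents)
  names(unplaced) <- ids
  order_ <- character(n)
  queue <- character(n)
  queue[1L] <- root
  head <- 1L; tail <- 1L; k <- 0L
  while (head <= tail) {
    t <- queue[head]; head <- head + 1L
    k <- k + 1L
    order_[k] <- t
    for (ch in children[[t]]) {
      unplaced[[ch]] <- unplaced[[ch]] - 1L
      if (unplaced[[ch]] == 0L) { tail <- tail + 1L; queue[tail] <- ch }
    }
  }
  if (k < n) {
    left <- setdiff(ids, order_[seq_len(k)])
    bad <- left[1L]
    badp <- intersect(parents[[bad]], left)[1L]
    stop(sprintf("cyclic is_a graph: edge %s -> %s lies on a cycle", bad, badp))
  }

  # Shortest-path depth by BFS over parent -> child edges.
  depth <- stats::setNames(rep(NA_integer_, n), ids)
  depth[[root]] <- 0L
  queue[1L] <- root; head <- 1L; tail <- 1L
  while (head <= tail) {
    t <- queue[head]; head <- head + 1L
    for (ch in children[[t]]) {
      if (is.na(depth[[ch]])) {
        depth[[ch]] <- depth[[t]] + 1L
        tail <- tail + 1L; queue[tail] <- ch
      }
    }
  }

  # Reflexive transitive ancestor closure, built in topological order.
  anc <- stats::setNames(vector("list", n), ids)
  for (t in order_) {
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  }

  structure(
    list(ids = ids, name = nm, parents = parents, children = children,
         depth = depth, ancestors = anc, root = root,
         obsolete = obsolete, alt = alt,
         n_edges = sum(lengths(parents))),
    class = "hpo_ontology"
  )
}

obo_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE)) {
    if (!file.exists(x)) stop("OBO input not found: ", x)
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(sprintf("hpo_ontology: %d terms, %d is_a edges, root %s, max depth %d\n",
              length(x$ids), x$n_edges, x$root, max(x$depth)))
  invisible(x)
}

#' Serialize an ontology back to OBO text
#'
#' Writes the live terms and their `is_a` edges as OBO stanzas. Obsolete-term
#' bookkeeping is not serialized; a parse -> format -> parse round trip
#' preserves the term and edge counts of the live graph.
#'
#' @param ontology An `hpo_ontology`.
#' @return A character vector of OBO lines.
#' @export
format_obo <- function(ontology) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  out <- c("format-version: 1.2", "")
  for (id in ontology$ids) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$name[[id]]))
    for (p in ontology$parents[[id]]) {
      out <- c(out, paste0("is_a: ", p, " ! ", ontology$name[[p]]))
    }
    out <- c(out, "")
  }
  out
}

#' Resolve term identifiers against an ontology
#'
#' Maps alternative ids and obsolete ids (via `replaced_by`, followed
#' transitively) to live term ids. Unknown ids, and obsolete ids without a
#' replacement, raise an error naming the offending identifier.
#'
#' @param ontology An `hpo_ontology`.
#' @param terms Character vector of term ids.
#' @return Character vector of live term ids, same length as `terms`.
#' @export
resolve_terms <- function(ontology, terms) {
  terms <- as.character(terms)
  out <- character(length(terms))
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    seen <- character(0)
    repeat {
      if (t %in% ontology$ids) break
      if (t %in% names(ontology$alt)) {
        t <- ontology$alt[[t]]
        next
      }
      if (t %in% names(ontology$obsolete)) {
        rep_ <- ontology$obsolete[[t]]
        if (is.na(rep_)) stop("obsolete term without replacement: ", terms[[i]])
        if (rep_ %in% seen) stop("circular replacement chain for term: ", terms[[i]])
        seen <- c(seen, t)
        t <- rep_
        next
      }
      stop("unknown term ID: ", t)
    }
    out[[i]] <- t
  }
  out
}

#' Ancestors of a term (reflexive)
#'
#' The reflexive transitive closure over `is_a`: always contains the term
#' itself and the ontology root.
#'
#' @param ontology An `hpo_ontology`.
#' @param term A term id (alt/obsolete ids are resolved first).
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(ontology, term) {
  t <- resolve_terms(ontology, term)
  ontology$ancestors[[t]]
}

#' Construct a disease-annotation corpus
#'
#' @param disease_terms Named list: disease id -> character vector of HPO
#'   term ids annotated to that disease.
#' @param disease_names Optional named character vector of display names.
#' @return An object of class `annotation_corpus` with elements
#'   `disease_terms`, `disease_names` and `n_diseases`.
#' @export
annotation_corpus <- function(disease_terms, disease_names = NULL) {
  if (!length(disease_terms)) stop("empty annotation corpus")
  if (is.null(names(disease_terms)) || any(!nzchar(names(disease_terms)))) {
    stop("disease_terms must be a named list keyed by disease id")
  }
  disease_terms <- lapply(disease_terms, function(x) unique(as.character(x)))
  if (any(lengths(disease_terms) == 0L)) stop("every disease needs at least one term")
  if (is.null(disease_names)) {
    disease_names <- stats::setNames(names(disease_terms), names(disease_terms))
  }
  structure(
    list(disease_terms = disease_terms,
         disease_names = disease_names[names(disease_terms)],
         n_diseases = length(disease_terms)),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d diseases, %d annotations\n",
              x$n_diseases, sum(lengths(x$disease_terms))))
  invisible(x)
}

#' Read an HPOA-style disease-annotation file
#'
#' Tab-delimited with `#`-prefixed comment lines skipped; columns
#' `database_id`, `disease_name`, `qualifier`, `hpo_id`. Rows whose qualifier
#' is `NOT` (negated phenotypes) are dropped. When an ontology is supplied,
#' term ids are resolved through alt/obsolete maps and rows whose term cannot
#' be resolved are dropped with a warning.
#'
#' @param path Path to the annotation file.
#' @param ontology Optional `hpo_ontology` used to resolve term ids.
#' @return An `annotation_corpus`.
#' @export
read_hpoa <- function(path, ontology = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) && grepl("^database_id\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) stop("no annotation rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 4L
  if (any(!ok)) warning(sum(!ok), " malformed annotation row(s) skipped")
  parts <- parts[ok]
  db <- vapply(parts, `[[`, character(1), 1L)
  nm <- vapply(parts, `[[`, character(1), 2L)
  qual <- vapply(parts, `[[`, character(1), 3L)
  hpo <- vapply(parts, `[[`, character(1), 4L)
  keep <- toupper(qual) != "NOT"
  db <- db[keep]; nm <- nm[keep]; hpo <- hpo[keep]
  if (!is.null(ontology)) {
    uniq <- unique(hpo)
    res <- vapply(uniq, function(t) {
      tryCatch(resolve_terms(ontology, t), error = function(e) NA_character_)
    }, character(1))
    bad <- uniq[is.na(res)]
    if (length(bad)) {
      warning("dropping annotations with unresolvable term(s): ",
              paste(bad, collapse = ", "))
    }
    hpo2 <- unname(res[hpo])
    keep2 <- !is.na(hpo2)
    db <- db[keep2]; nm <- nm[keep2]; hpo <- hpo2[keep2]
  }
  if (!length(db)) stop("no usable annotation rows in ", path)
  annotation_corpus(split(hpo, db),
                    disease_names = stats::setNames(nm, db)[!duplicated(db)])
}

#' Information content of ontology terms from a disease corpus
#'
#' Disease-frequency information content: `ic(t) = -ln(n_t / N)` where `n_t`
#' is the number of corpus diseases annotated to `t` or any descendant of `t`
#' (annotations propagate to all ancestors) and `N` the corpus size. The root
#' therefore always has IC 0, and IC never decreases along a child edge.
#' Terms with no annotated descendant get an infinite-IC sentinel and are
#' excluded from MICA search.
#'
#' @param ontology An `hpo_ontology`.
#' @param corpus An `annotation_corpus`.
#' @return Named numeric vector of natural-log information content, one entry
#'   per ontology term, with attribute `n_diseases`.
#' @export
compute_ic <- function(ontology, corpus) {
  stopifnot(inherits(ontology, "hpo_ontology"), inherits(corpus, "annotation_corpus"))
  if (corpus$n_diseases < 1L) stop("empty annotation corpus")
  counts <- stats::setNames(integer(length(ontology$ids)), ontology$ids)
  for (terms in corpus$disease_terms) {
    tt <- resolve_terms(ontology, unique(terms))
    a <- unique(unlist(ontology$ancestors[tt], use.names = FALSE))
    counts[a] <- counts[a] + 1L
  }
  ic <- -log(counts / corpus$n_diseases)
  ic[counts == 0L] <- Inf
  attr(ic, "n_diseases") <- corpus$n_diseases
  ic
}

#' Most informative common ancestor of two terms
#'
#' Among common ancestors with finite information content, returns the one
#' with maximal IC; ties are broken by greater depth, then lexicographically
#' smaller term id. The root is always a common ancestor (IC 0), so the
#' result is always defined.
#'
#' @param ontology An `hpo_ontology`.
#' @param ic IC table from [compute_ic()].
#' @param t1,t2 Term ids.
#' @return A list with elements `term` and `ic`.
#' @export
mica <- function(ontology, ic, t1, t2) {
  tt <- resolve_terms(ontology, c(t1, t2))
  common <- intersect(ontology$ancestors[[tt[1]]], ontology$ancestors[[tt[2]]])
  cand <- common[is.finite(ic[common])]
  if (!length(cand)) cand <- ontology$root
  o <- order(-ic[cand], -ontology$depth[cand], cand)
  best <- cand[o[1]]
  list(term = best, ic = unname(ic[[best]]))
}

# Deepest common ancestor; ties broken lexicographically.
lca_term <- function(ontology, t1, t2) {
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  o <- order(-ontology$depth[common], common)
  common[o[1]]
}
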