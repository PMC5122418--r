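# Ontology DAG, structural information content, Lin and best-match-average
# semantic similarity.

#' Construct an ontology DAG
#'
#' Builds the directed acyclic graph of ontology terms used throughout the
#' package. Edges are child-to-parent \code{is_a} links; the graph must have
#' exactly one root (a term with no parent) and no cycles.
#'
#' @param terms Character vector of term identifiers.
#' @param parents Named list mapping each term to a character vector of its
#'   direct parents (empty vector for the root).
#' @param namespace Annotation category label (e.g. \code{"biological_process"}).
#' @return An object of class \code{OntologyDag} with elements \code{terms},
#'   \code{parents}, \code{children}, \code{root} and \code{namespace}.
#' @export
ontology_dag <- function(terms, parents, namespace = "biological_process") {
  terms <- sort(unique(as.character(terms)))
  parents <- parents[terms]
  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  names(parents) <- terms
  bad <- setdiff(unlist(parents), terms)
  if (length(bad) > 0L)
    stop("parent term(s) not in term set: ", paste(bad, collapse = ", "))
  dag <- structure(
    list(terms = terms, parents = parents, children = NULL,
         root = NA_character_, namespace = namespace),
    class = "OntologyDag")
  dag$children <- invert_edges(parents, terms)
  dag <- validate_dag(dag)
  dag
}

invert_edges <- function(parents, terms) {
  children <- lapply(stats::setNames(terms, terms), function(t) character(0))
  for (child in names(parents)) {
    for (p in parents[[child]]) children[[p]] <- c(children[[p]], child)
  }
  lapply(children, sort)
}

# Kahn topological sort (parents before children). Errors on a cycle,
# naming one offending edge.
validate_dag <- function(dag) {
  terms <- dag$terms
  roots <- terms[vapply(dag$parents[terms], length, 1L) == 0L]
  n_par <- vapply(dag$parents[terms], length, 1L)
  indeg <- stats::setNames(n_par, terms)
  queue <- terms[indeg == 0L]
  order <- character(0)
  while (length(queue) > 0L) {
    t <- queue[1L]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in dag$children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(terms)) {
    left <- setdiff(terms, order)
    t <- left[1L]
    p <- intersect(dag$parents[[t]], left)[1L]
    stop("ontology graph contains a cycle (edge ", t, " -> ", p, ")")
  }
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ", length(roots),
         if (length(roots) > 0L) paste0(": ", paste(roots, collapse = ", ")) else "")
  dag$root <- roots
  dag$toporder <- order
  dag
}

#' @export
print.OntologyDag <- function(x, ...) {
  cat("OntologyDag:", length(x$terms), "terms,",
      sum(vapply(x$parents, length, 1L)), "is_a edges, namespace",
      x$namespace, "\n  root:", x$root, "\n")
  invisible(x)
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses \code{[Term]} stanzas (fields \code{id}, \code{name},
#' \code{namespace}, \code{is_a}, \code{is_obsolete}), keeps a single
#' namespace, drops obsolete terms and all non-\code{is_a} relations.
#'
#' @param path Path to an OBO file.
#' @param namespace Namespace to retain. \code{NULL} (default) keeps the
#'   namespace of the majority of terms; an error is raised if the requested
#'   namespace annotates no term.
#' @return An \code{OntologyDag}.
#' @export
load_obo <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)   # trailing comments
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  recs <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block) & nzchar(block)]
    field <- sub(":.*$", "", block)
    value <- trimws(sub("^[^:]+:", "", block))
    recs[[i]] <- list(
      id = value[field == "id"][1L],
      namespace = value[field == "namespace"][1L],
      is_a = value[field == "is_a"],
      obsolete = any(field == "is_obsolete" & value == "true"))
  }
  recs <- Filter(function(r) !is.na(r$id) && !r$obsolete, recs)
  ns <- vapply(recs, function(r) r$namespace, "")
  requested <- !is.null(namespace)
  if (!requested) {
    tab <- table(ns[!is.na(ns)])
    namespace <- if (length(tab) > 0L) names(tab)[which.max(tab)] else NA_character_
  }
  if (is.na(namespace)) {
    keep <- rep(TRUE, length(recs))
    namespace <- "unspecified"
  } else {
    keep <- !is.na(ns) & ns == namespace
    if (!any(keep))
      stop("namespace '", namespace, "' not present in ", path)
  }
  recs <- recs[keep]
  ids <- vapply(recs, function(r) r$id, "")
  parents <- lapply(recs, function(r) intersect(r$is_a, ids))
  names(parents) <- ids
  ontology_dag(ids, parents, namespace = namespace)
}

#' Write an ontology DAG as OBO 1.2
#'
#' @param dag An \code{OntologyDag}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", t),
                 paste0("namespace: ", dag$namespace),
                 paste0("is_a: ", dag$parents[[t]]),
                 ""), con)
  }
  invisible(path)
}

#' Ancestors of a term (including the term itself)
#'
#' @param dag An \code{OntologyDag}.
#' @param term Term identifier.
#' @return Character vector of ancestor term ids, the term itself included.
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in ontology: ", term)
  seen <- character(0)
  stack <- term
  while (length(stack) > 0L) {
    t <- stack[1L]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, dag$parents[[t]])
  }
  sort(seen)
}

#' Descendants of a term (including the term itself)
#'
#' @param dag An \code{OntologyDag}.
#' @param term Term identifier.
#' @return Character vector of descendant term ids, the term itself included.
#' @export
term_descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in ontology: ", term)
  seen <- character(0)
  stack <- term
  while (length(stack) > 0L) {
    t <- stack[1L]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, dag$children[[t]])
  }
  sort(seen)
}

#' Structural information content of every term
#'
#' For each term t, n_t is the number of its descendants plus itself,
#' p_t = n_t / N with N the total number of terms, and IC(t) = -log(p_t)
#' (natural log). The root has p = 1 and IC 0; IC never increases from a
#' child to its parent.
#'
#' @param dag An \code{OntologyDag}.
#' @return A data frame with columns \code{term}, \code{n_t}, \code{p},
#'   \code{ic}, one row per term.
#' @export
information_content <- function(dag) {
  terms <- dag$terms
  N <- length(terms)
  idx <- stats::setNames(seq_len(N), terms)
  # descendant index sets, children before parents
  desc <- vector("list", N)
  for (t in rev(dag$toporder)) {
    i <- idx[[t]]
    d <- idx[[t]]
    for (ch in dag$children[[t]]) d <- c(d, desc[[idx[[ch]]]])
    desc[[i]] <- unique(d)
  }
  n_t <- vapply(desc, length, 1L)[idx[terms]]
  p <- n_t / N
  data.frame(term = terms, n_t = as.integer(n_t), p = p, ic = -log(p),
             stringsAsFactors = FALSE)
}

#' Write an information-content table as TSV
#'
#' @param ic Data frame from \code{\link{information_content}}.
#' @param path Output path.
#' @export
write_ic_table <- function(ic, path) {
  utils::write.table(ic, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ic_lookup <- function(ic_map) {
  if (is.data.frame(ic_map)) stats::setNames(ic_map$ic, ic_map$term) else ic_map
}

#' Most informative common ancestor of two terms
#'
#' The shared ancestor (terms count as their own ancestors) with maximal IC;
#' IC ties are broken by lexicographically smallest identifier so the reported
#' MICA is deterministic (any maximal-IC ancestor gives the same Lin score).
#'
#' @param t1,t2 Term identifiers.
#' @param ic_map Data frame from \code{\link{information_content}} or a named
#'   numeric vector of ICs.
#' @param dag An \code{OntologyDag}.
#' @return The MICA term identifier.
#' @export
mica <- function(t1, t2, ic_map, dag) {
  ic <- ic_lookup(ic_map)
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  common <- sort(common)                    # lexicographic tie-break
  common[which.max(ic[common])]
}

#' Lin semantic similarity between two terms
#'
#' \code{2 * IC(MICA) / (IC(t1) + IC(t2))}, in [0, 1]. When both ICs are zero
#' the formula is 0/0: the identity pair (root with itself) scores 1 and any
#' other such pair scores 0.
#'
#' @inheritParams mica
#' @return Similarity in [0, 1].
#' @export
lin_similarity <- function(t1, t2, ic_map, dag) {
  ic <- ic_lookup(ic_map)
  if (!t1 %in% dag$terms) stop("term not in ontology: ", t1)
  if (!t2 %in% dag$terms) stop("term not in ontology: ", t2)
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(if (t1 == t2) 1 else 0)
  m <- mica(t1, t2, ic, dag)
  unname(2 * ic[[m]] / denom)
}

# Pairwise Lin matrix for two term vectors, sharing one ancestor cache.
lin_matrix <- function(set1, set2, ic_map, dag) {
  ic <- ic_lookup(ic_map)
  all_terms <- unique(c(set1, set2))
  anc <- lapply(stats::setNames(all_terms, all_terms),
                function(t) term_ancestors(dag, t))
  m <- matrix(0, length(set1), length(set2), dimnames = list(set1, set2))
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      t1 <- set1[i]; t2 <- set2[j]
      denom <- ic[[t1]] + ic[[t2]]
      if (denom == 0) { m[i, j] <- if (t1 == t2) 1 else 0; next }
      common <- intersect(anc[[t1]], anc[[t2]])
      m[i, j] <- 2 * max(ic[common]) / denom
    }
  }
  m
}

#' Best-match-average similarity between two term sets
#'
#' Builds the |S1| x |S2| Lin similarity matrix and scores the pair of sets as
#' the mean of all row maxima and all column maxima:
#' \code{(sum(rowMax) + sum(colMax)) / (|S1| + |S2|)}. Symmetric in its two
#' set arguments and bounded in [0, 1].
#'
#' @param set1,set2 Non-empty character vectors of term identifiers.
#' @inheritParams mica
#' @return An object of class \code{TermSetSimilarity}: list with
#'   \code{score} and the Lin \code{pair_matrix}.
#' @export
bma_similarity <- function(set1, set2, ic_map, dag) {
  if (length(set1) == 0L || length(set2) == 0L)
    stop("best-match-average similarity requires two non-empty term sets")
  m <- lin_matrix(unique(set1), unique(set2), ic_map, dag)
  structure(list(score = bma_score(m), pair_matrix = m),
            class = "TermSetSimilarity")
}

#' Best-match-average score of a precomputed similarity matrix
#'
#' @param m Numeric matrix of pairwise term similarities.
#' @return \code{(sum(rowMax) + sum(colMax)) / (nrow + ncol)}.
#' @export
bma_score <- function(m) {
  (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) / (nrow(m) + ncol(m))
}

#' @export
print.TermSetSimilarity <- function(x, ...) {
  cat("TermSetSimilarity: score", format(x$score, digits = 4),
      sprintf("(%d x %d term pairs)\n", nrow(x$pair_matrix), ncol(x$pair_matrix)))
  invisible(x)
}
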