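# Ontology annotation handling and elim-style Fisher enrichment.

#' Build an annotation map with ancestor propagation
#'
#' Direct gene annotations are propagated up the DAG: the gene set of a term
#' is the union of the direct annotations of the term and all its
#' descendants, so \code{propagated(parent)} always contains
#' \code{propagated(child)}.
#'
#' @param direct Named list term -> character vector of directly annotated
#'   genes. Terms absent from the DAG are dropped.
#' @param dag An \code{OntologyDag}.
#' @return An object of class \code{AnnotationMap}: list with \code{direct},
#'   \code{propagated} and \code{universe} (all genes with >= 1 annotation).
#' @export
annotation_map <- function(direct, dag) {
  direct <- direct[names(direct) %in% dag$terms]
  direct <- lapply(direct, function(g) sort(unique(as.character(g))))
  prop <- lapply(stats::setNames(dag$terms, dag$terms),
                 function(t) character(0))
  # children before parents
  for (t in rev(dag$toporder)) {
    g <- direct[[t]]
    for (ch in dag$children[[t]]) g <- c(g, prop[[ch]])
    prop[[t]] <- sort(unique(g))
  }
  structure(list(direct = direct, propagated = prop,
                 universe = sort(unique(unlist(direct)))),
            class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat("AnnotationMap:", length(x$direct), "annotated terms,",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read gene annotations from a two-column TSV (gene, term)
#'
#' @param path TSV path with columns \code{gene} and \code{term} (header
#'   required).
#' @param dag An \code{OntologyDag}.
#' @return An \code{AnnotationMap}.
#' @export
read_annotations <- function(path, dag) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_map(split(tab$gene, tab$term), dag)
}

#' Read gene annotations from a GMT file
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @param dag An \code{OntologyDag}.
#' @return An \code{AnnotationMap}.
#' @export
read_gmt <- function(path, dag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  direct <- lapply(fields, function(f) f[-(1:2)])
  names(direct) <- vapply(fields, `[[`, "", 1L)
  annotation_map(direct, dag)
}

#' Write an annotation map as GMT
#'
#' @param ann An \code{AnnotationMap}.
#' @param path Output path.
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(names(ann$direct), function(t) {
    paste(c(t, t, ann$direct[[t]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher / hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least \code{k} annotated
#' genes when \code{n} genes are drawn from a background of \code{M} genes of
#' which \code{K} carry the annotation. Identical to the one-sided Fisher
#' exact test on the corresponding 2x2 table.
#'
#' @param k Annotated genes in the study set.
#' @param n Study-set size.
#' @param K Annotated genes in the background.
#' @param M Background size.
#' @return p-value in (0, 1].
#' @export
fisher_enrich_term <- function(k, n, K, M) {
  if (k < 0 || n > M || K > M || k > min(n, K))
    stop("inconsistent enrichment counts (k=", k, ", n=", n,
         ", K=", K, ", M=", M, ")")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

# longest path from the root to each term
term_depths <- function(dag) {
  depth <- stats::setNames(rep(0L, length(dag$terms)), dag$terms)
  for (t in dag$toporder) {            # parents before children
    for (ch in dag$children[[t]])
      depth[ch] <- max(depth[ch], depth[t] + 1L)
  }
  depth
}

#' elim-style ontology enrichment
#'
#' Tests terms from most to least specific (decreasing depth, ties broken
#' lexicographically) with a one-sided Fisher test. Whenever a term is
#' significant at \code{alpha}, the genes currently annotated to it are
#' removed from the annotation sets of all of its ancestors before those are
#' tested, which suppresses enrichment signals that a general term merely
#' inherits from a specific one. All terms with p < \code{alpha} are
#' reported; no multiple-testing correction is applied.
#'
#' @param study_genes Character vector of study genes (intersected with the
#'   background universe).
#' @param annotation An \code{AnnotationMap}.
#' @param dag An \code{OntologyDag}.
#' @param alpha Significance (and elimination) threshold, default 0.01.
#' @param universe Optional background gene universe; defaults to all genes
#'   annotated in \code{annotation}.
#' @param entity_id Identifier stored in the profile.
#' @param all_terms If \code{TRUE}, report every tested term regardless of
#'   significance (elim pruning still applies).
#' @return An object of class \code{EnrichmentProfile}: a data frame with
#'   columns \code{term}, \code{p}, \code{k}, \code{n}, \code{K}, \code{M},
#'   ordered by p then term, with attribute \code{entity_id}.
#' @export
elim_enrich <- function(study_genes, annotation, dag, alpha = 0.01,
                        universe = NULL, entity_id = NA_character_,
                        all_terms = FALSE) {
  if (is.null(universe)) universe <- annotation$universe
  universe <- unique(universe)
  study <- intersect(unique(study_genes), universe)
  if (length(study) == 0L) {
    warning("empty study set after restricting to the background universe")
    return(enrichment_profile(empty_profile_rows(), entity_id))
  }
  M <- length(universe)
  n <- length(study)
  depth <- term_depths(dag)
  order <- dag$terms[order(-depth[dag$terms], dag$terms)]

  ann <- lapply(annotation$propagated, function(g) intersect(g, universe))
  rows <- vector("list", length(order))
  for (i in seq_along(order)) {
    t <- order[i]
    genes_t <- ann[[t]]
    K <- length(genes_t)
    if (K == 0L) next
    k <- length(intersect(study, genes_t))
    p <- fisher_enrich_term(k, n, K, M)
    rows[[i]] <- data.frame(term = t, p = p, k = k, n = n, K = K, M = M,
                            stringsAsFactors = FALSE)
    if (p < alpha) {
      for (a in setdiff(term_ancestors(dag, t), t))
        ann[[a]] <- setdiff(ann[[a]], genes_t)
    }
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) res <- empty_profile_rows()
  if (!all_terms) res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  enrichment_profile(res, entity_id)
}

#' Classic (non-elim) Fisher enrichment over all terms
#'
#' Same counting as \code{\link{elim_enrich}} but with no gene elimination:
#' every term is tested against its full propagated annotation set.
#'
#' @inheritParams elim_enrich
#' @return An \code{EnrichmentProfile}.
#' @export
classic_enrich <- function(study_genes, annotation, dag, alpha = 0.01,
                           universe = NULL, entity_id = NA_character_,
                           all_terms = FALSE) {
  if (is.null(universe)) universe <- annotation$universe
  universe <- unique(universe)
  study <- intersect(unique(study_genes), universe)
  if (length(study) == 0L) {
    warning("empty study set after restricting to the background universe")
    return(enrichment_profile(empty_profile_rows(), entity_id))
  }
  M <- length(universe)
  n <- length(study)
  rows <- lapply(dag$terms, function(t) {
    genes_t <- intersect(annotation$propagated[[t]], universe)
    K <- length(genes_t)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, genes_t))
    data.frame(term = t, p = fisher_enrich_term(k, n, K, M),
               k = k, n = n, K = K, M = M, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) res <- empty_profile_rows()
  if (!all_terms) res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  enrichment_profile(res, entity_id)
}

empty_profile_rows <- function() {
  data.frame(term = character(0), p = numeric(0), k = integer(0),
             n = integer(0), K = integer(0), M = integer(0),
             stringsAsFactors = FALSE)
}

enrichment_profile <- function(rows, entity_id) {
  attr(rows, "entity_id") <- entity_id
  class(rows) <- c("EnrichmentProfile", "data.frame")
  rows
}

#' Significant terms of an enrichment profile
#' @param profile An \code{EnrichmentProfile}.
#' @return Character vector of term ids.
#' @export
profile_terms <- function(profile) profile$term

#' Write enrichment profiles as TSV (entity, term, p, k, n, K, M)
#'
#' @param profiles Named list of \code{EnrichmentProfile} objects.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(id) {
    pr <- profiles[[id]]
    if (nrow(pr) == 0L) return(NULL)
    cbind(data.frame(entity = id, stringsAsFactors = FALSE),
          as.data.frame(pr))
  }))
  if (is.null(rows)) rows <- cbind(data.frame(entity = character(0)),
                                   empty_profile_rows())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read enrichment profiles from TSV written by \code{write_profiles}
#'
#' @param path TSV path.
#' @return Named list of \code{EnrichmentProfile} objects.
#' @export
read_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$entity), function(d) {
    rows <- d[, c("term", "p", "k", "n", "K", "M")]
    rownames(rows) <- NULL
    enrichment_profile(rows, d$entity[1L])
  })
  out[order(names(out))]
}
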