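# Permutation-null negative score generation and ROC/AUC evaluation.

#' Permutation-null similarity scores for one association
#'
#' For a gold-standard small molecule-miRNA pair, draws random term sets of
#' the same size as the miRNA's enriched term set (without replacement from
#' \code{term_universe}) and rescoring them against the small molecule's true
#' term set yields a null distribution of "fake" similarity scores.
#'
#' @param sm_terms Character vector: the small molecule's enriched terms.
#' @param n_mirna_terms Size of the miRNA's enriched term set.
#' @param dag An \code{OntologyDag}.
#' @param ic_map Information-content table.
#' @param term_universe Pool to sample random term sets from (for example the
#'   union of all terms enriched in any entity, or the whole ontology).
#' @param n_perm Number of permutations (default 99).
#' @param seed Integer seed; same seed reproduces the same scores.
#' @return Numeric vector of \code{n_perm} best-match-average scores.
#' @export
permuted_scores <- function(sm_terms, n_mirna_terms, dag, ic_map,
                            term_universe, n_perm = 99L, seed = 1L) {
  term_universe <- unique(term_universe)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(term_universe) < n_mirna_terms)
    stop("term universe (", length(term_universe),
         ") smaller than the required set size (", n_mirna_terms, ")")
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) {
    fake <- sample(term_universe, n_mirna_terms)
    bma_similarity(sm_terms, fake, ic_map, dag)$score
  }, 0)
}

#' Assemble ROC input from gold-standard pairs
#'
#' Each gold pair contributes one positive instance (its true similarity
#' score) and \code{n_perm} negative instances from
#' \code{\link{permuted_scores}}.
#'
#' @param gold_pairs Data frame with columns \code{small_molecule} and
#'   \code{mirna}.
#' @param sm_profiles,mirna_profiles Named lists of \code{EnrichmentProfile}
#'   objects or term vectors.
#' @param dag,ic_map Ontology and IC table.
#' @param term_universe Sampling pool; defaults to the union of all terms
#'   enriched in any entity.
#' @param n_perm Negatives per gold pair (default 99).
#' @param seed Integer seed.
#' @return An object of class \code{RocInput}: list of data frames
#'   \code{positives} and \code{negatives} (columns pair_id, score).
#' @export
make_roc_input <- function(gold_pairs, sm_profiles, mirna_profiles, dag,
                           ic_map, term_universe = NULL, n_perm = 99L,
                           seed = 1L) {
  get_terms <- function(p) if (is.data.frame(p)) profile_terms(p) else as.character(p)
  sm_terms <- lapply(sm_profiles, get_terms)
  mi_terms <- lapply(mirna_profiles, get_terms)
  if (is.null(term_universe))
    term_universe <- unique(c(unlist(sm_terms), unlist(mi_terms)))
  pos <- vector("list", nrow(gold_pairs))
  neg <- vector("list", nrow(gold_pairs))
  for (i in seq_len(nrow(gold_pairs))) {
    sm <- gold_pairs$small_molecule[i]
    mi <- gold_pairs$mirna[i]
    if (!sm %in% names(sm_terms) || !mi %in% names(mi_terms))
      stop("gold pair references unknown entity: ", sm, " / ", mi)
    pair_id <- paste(sm, mi, sep = "|")
    pos[[i]] <- data.frame(
      pair_id = pair_id,
      score = bma_similarity(sm_terms[[sm]], mi_terms[[mi]], ic_map, dag)$score,
      stringsAsFactors = FALSE)
    neg[[i]] <- data.frame(
      pair_id = pair_id,
      score = permuted_scores(sm_terms[[sm]], length(mi_terms[[mi]]), dag,
                              ic_map, term_universe, n_perm = n_perm,
                              seed = seed + i),
      stringsAsFactors = FALSE)
  }
  structure(list(positives = do.call(rbind, pos),
                 negatives = do.call(rbind, neg)),
            class = "RocInput")
}

#' @export
print.RocInput <- function(x, ...) {
  cat("RocInput:", nrow(x$positives), "positives,", nrow(x$negatives),
      "negatives\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps a score threshold over the pooled unique scores to produce
#' sensitivity/specificity points, and integrates the curve by the
#' trapezoidal rule. Ties receive half credit, so the AUC equals the
#' Mann-Whitney statistic U / (n_pos * n_neg).
#'
#' @param roc_input A \code{RocInput}, or a list with numeric elements
#'   \code{positives} and \code{negatives} (bare scores).
#' @return List with \code{auc} and \code{curve}, a data frame of
#'   (threshold, tpr, fpr) rows from the most to the least stringent cutoff.
#' @export
roc_auc <- function(roc_input) {
  get_scores <- function(x) if (is.data.frame(x)) x$score else as.numeric(x)
  pos <- get_scores(roc_input$positives)
  neg <- get_scores(roc_input$negatives)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("ROC needs at least one positive and one negative instance")
  thresholds <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(pos >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(neg >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr))
}
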