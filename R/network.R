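# Small molecule x miRNA similarity matrix, normal-quantile thresholding,
# association network, and auxiliary overlap / structure similarity scores.

#' Pairwise functional similarity between two entity collections
#'
#' Scores every small molecule against every miRNA with the best-match-average
#' Lin similarity of their enriched term sets. Entities with empty profiles
#' are dropped with a message.
#'
#' @param sm_profiles Named list of \code{EnrichmentProfile} objects (or bare
#'   character term vectors) for small molecules.
#' @param mirna_profiles Same, for miRNAs.
#' @param dag An \code{OntologyDag}.
#' @param ic_map Information-content table from
#'   \code{\link{information_content}}.
#' @return A small-molecules x miRNAs numeric matrix of scores in [0, 1],
#'   class \code{SimilarityMatrix}.
#' @export
build_similarity_matrix <- function(sm_profiles, mirna_profiles, dag, ic_map) {
  get_terms <- function(p) if (is.data.frame(p)) profile_terms(p) else as.character(p)
  sm_terms <- lapply(sm_profiles, get_terms)
  mi_terms <- lapply(mirna_profiles, get_terms)
  drop_empty <- function(x, what) {
    empty <- vapply(x, length, 1L) == 0L
    if (any(empty))
      message("dropping ", sum(empty), " ", what, " with empty profiles: ",
              paste(names(x)[empty], collapse = ", "))
    x[!empty]
  }
  sm_terms <- drop_empty(sm_terms, "small molecule(s)")
  mi_terms <- drop_empty(mi_terms, "miRNA(s)")
  if (length(sm_terms) == 0L || length(mi_terms) == 0L)
    stop("no entities with non-empty enrichment profiles")

  # one shared Lin matrix over the term vocabulary, then indexed per pair
  vocab <- sort(unique(c(unlist(sm_terms), unlist(mi_terms))))
  missing <- setdiff(vocab, dag$terms)
  if (length(missing) > 0L)
    stop("profile terms absent from the ontology: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  lin_all <- lin_matrix(vocab, vocab, ic_map, dag)

  scores <- matrix(0, length(sm_terms), length(mi_terms),
                   dimnames = list(names(sm_terms), names(mi_terms)))
  for (i in seq_along(sm_terms)) {
    for (j in seq_along(mi_terms)) {
      scores[i, j] <- bma_score(lin_all[sm_terms[[i]], mi_terms[[j]],
                                        drop = FALSE])
    }
  }
  if (all(scores == 0))
    warning("all similarity scores are zero: the two collections share no ",
            "informative vocabulary")
  class(scores) <- c("SimilarityMatrix", class(scores))
  scores
}

#' Upper normal quantile cutoff
#'
#' \code{cutoff = mu + qnorm(1 - alpha) * sigma}: the value a normal score
#' distribution exceeds with probability \code{alpha}.
#'
#' @param mu,sigma Normal mean and standard deviation (sigma > 0).
#' @param alpha Upper-tail significance level in (0, 0.5].
#' @return The cutoff value.
#' @export
normal_cutoff <- function(mu, sigma, alpha) {
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  mu + stats::qnorm(1 - alpha) * sigma
}

#' Fit a normal score distribution and derive the significance cutoff
#'
#' Moment-matches a normal distribution to the observed similarity scores
#' (sample mean and standard deviation) and sets the association cutoff at
#' the upper one-sided \code{1 - alpha} quantile. With the score distribution
#' reported for the full-scale analysis (mean 0.4882, sd 0.0965) and
#' alpha = 0.01 the cutoff is 0.7127.
#'
#' @param scores Numeric vector or \code{SimilarityMatrix} of scores
#'   (>= 2 values).
#' @param alpha Significance level in (0, 0.5], default 0.01.
#' @return An object of class \code{NormalFit}: list with \code{mu},
#'   \code{sigma}, \code{alpha}, \code{cutoff}.
#' @export
fit_threshold <- function(scores, alpha = 0.01) {
  x <- as.numeric(scores)
  if (length(x) < 2L) stop("need at least two scores to fit a distribution")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("scores have zero variance; no threshold can be fitted")
  structure(list(mu = mu, sigma = sigma, alpha = alpha,
                 cutoff = normal_cutoff(mu, sigma, alpha)),
            class = "NormalFit")
}

#' @export
print.NormalFit <- function(x, ...) {
  cat(sprintf("NormalFit: mu = %.4f, sigma = %.4f, alpha = %g -> cutoff %.4f\n",
              x$mu, x$sigma, x$alpha, x$cutoff))
  invisible(x)
}

#' Threshold a similarity matrix into a bipartite association network
#'
#' Keeps every small molecule-miRNA pair whose score is at or above the
#' fitted cutoff (closed inequality, so a score exactly at the cutoff
#' qualifies).
#'
#' @param matrix A \code{SimilarityMatrix} (small molecules x miRNAs).
#' @param fit A \code{NormalFit}, or a single numeric cutoff.
#' @return An object of class \code{AssociationNetwork}: list with
#'   \code{edges} (data frame small_molecule, mirna, score, sorted by
#'   decreasing score), \code{sm_degree}, \code{mirna_degree} and
#'   \code{cutoff}.
#' @export
threshold_network <- function(matrix, fit) {
  cutoff <- if (inherits(fit, "NormalFit")) fit$cutoff else as.numeric(fit)
  hits <- which(matrix >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    small_molecule = rownames(matrix)[hits[, 1L]],
    mirna = colnames(matrix)[hits[, 2L]],
    score = matrix[hits],
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$small_molecule, edges$mirna), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    edges = edges,
    sm_degree = table(factor(edges$small_molecule, levels = rownames(matrix))),
    mirna_degree = table(factor(edges$mirna, levels = colnames(matrix))),
    cutoff = cutoff), class = "AssociationNetwork")
}

#' @export
print.AssociationNetwork <- function(x, ...) {
  cat("AssociationNetwork:", nrow(x$edges), "associations between",
      sum(x$sm_degree > 0), "small molecules and",
      sum(x$mirna_degree > 0), "miRNAs (cutoff",
      format(x$cutoff, digits = 4), ")\n")
  invisible(x)
}

#' Per-drug miRNA partner sets of a network
#' @param network An \code{AssociationNetwork}.
#' @return Named list drug -> character vector of associated miRNAs.
#' @export
network_partners <- function(network) {
  lapply(split(network$edges$mirna, network$edges$small_molecule), unique)
}

#' Write a network edge list as TSV and optionally GraphML
#'
#' @param network An \code{AssociationNetwork}.
#' @param path Output TSV path (columns small_molecule, mirna, score).
#' @param graphml_path Optional GraphML output path for network viewers.
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    e <- network$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$small_molecule, to = e$mirna, weight = e$score),
      directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% e$mirna
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Meet/Min overlap coefficient
#'
#' Size of the intersection divided by the size of the smaller set; used to
#' quantify shared target genes between two miRNAs.
#'
#' @param set1,set2 Non-empty character vectors.
#' @return Overlap in [0, 1].
#' @export
meet_min <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  if (length(set1) == 0L || length(set2) == 0L)
    stop("Meet/Min is undefined for empty sets")
  length(intersect(set1, set2)) / min(length(set1), length(set2))
}

#' Tanimoto similarity of two binary fingerprints
#'
#' Bits on in both fingerprints divided by bits on in either; two all-zero
#' fingerprints score 0.
#'
#' @param fp1,fp2 Equal-length binary (0/1) vectors.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(fp1, fp2) {
  if (length(fp1) != length(fp2))
    stop("fingerprints differ in length (", length(fp1), " vs ",
         length(fp2), ")")
  fp1 <- as.integer(fp1); fp2 <- as.integer(fp2)
  both <- sum(fp1 & fp2)
  either <- sum(fp1 | fp2)
  if (either == 0L) return(0)
  both / either
}

#' Read binary fingerprints from TSV (id, bitstring)
#'
#' @param path TSV with columns \code{id} and \code{bits} (a string of 0s
#'   and 1s).
#' @return Named list id -> integer 0/1 vector.
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  out <- lapply(strsplit(tab$bits, ""), as.integer)
  names(out) <- tab$id
  out
}

#' Consensus miRNA target voting across prediction algorithms
#'
#' A (miRNA, gene) pair is considered a reliable target when it appears in at
#' least \code{min_algorithms} distinct prediction tables.
#'
#' @param prediction_tables List (>= 2) of data frames with columns
#'   \code{mirna} and \code{gene}, one per prediction algorithm.
#' @param min_algorithms Minimum number of supporting algorithms (default 2).
#' @return Named list mirna -> character vector of target genes.
#' @export
vote_targets <- function(prediction_tables, min_algorithms = 2L) {
  if (length(prediction_tables) < 2L)
    stop("consensus voting needs at least two prediction tables")
  pairs <- unique(do.call(rbind, lapply(seq_along(prediction_tables),
    function(i) {
      d <- unique(prediction_tables[[i]][, c("mirna", "gene")])
      d$alg <- i
      d
    })))
  counts <- stats::aggregate(alg ~ mirna + gene, pairs, length)
  kept <- counts[counts$alg >= min_algorithms, , drop = FALSE]
  lapply(split(kept$gene, kept$mirna), function(g) sort(unique(g)))
}

#' Shared-target count versus similarity score
#'
#' For every network edge with target annotations on both sides, counts the
#' target genes shared by the drug and the miRNA, then reports the Spearman
#' rank correlation (mid-ranked ties) between shared-target counts and edge
#' scores.
#'
#' @param network An \code{AssociationNetwork}.
#' @param drug_targets Named list drug -> target gene vector.
#' @param mirna_targets Named list mirna -> target gene vector.
#' @return List with the per-edge data frame (\code{edges}: small_molecule,
#'   mirna, score, shared_targets), \code{rho}, \code{p} and a \code{note}
#'   when the correlation is undefined (< 3 usable edges or constant counts).
#' @export
overlap_vs_similarity <- function(network, drug_targets, mirna_targets) {
  e <- network$edges
  usable <- e$small_molecule %in% names(drug_targets) &
    e$mirna %in% names(mirna_targets)
  e <- e[usable, , drop = FALSE]
  e$shared_targets <- mapply(function(d, m) {
    length(intersect(drug_targets[[d]], mirna_targets[[m]]))
  }, e$small_molecule, e$mirna)
  rownames(e) <- NULL
  if (nrow(e) < 3L)
    return(list(edges = e, rho = NA_real_, p = NA_real_,
                note = "fewer than 3 edges with targets; correlation undefined"))
  if (length(unique(e$shared_targets)) == 1L || length(unique(e$score)) == 1L)
    return(list(edges = e, rho = NA_real_, p = NA_real_,
                note = "constant values; rank correlation undefined"))
  ct <- suppressWarnings(
    stats::cor.test(e$shared_targets, e$score, method = "spearman"))
  list(edges = e, rho = unname(ct$estimate), p = ct$p.value, note = NULL)
}
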