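# Drug-disease repurposing by hypergeometric enrichment of shared miRNAs.

#' Hypergeometric test for one drug-disease pair
#'
#' Models the drug's associated miRNAs as draws from a universe containing
#' the disease's miRNAs as successes, and scores the overlap with the
#' upper-tail probability P(X >= k).
#'
#' @param drug_mirnas Character vector: miRNAs associated with the drug.
#' @param disease_mirnas Character vector: miRNAs associated with the
#'   disease.
#' @param universe Character vector of all miRNAs under consideration; both
#'   sets must be subsets of it.
#' @return List with \code{k} (shared miRNAs) and \code{p}.
#' @export
drug_disease_test <- function(drug_mirnas, disease_mirnas, universe) {
  drug_mirnas <- unique(drug_mirnas)
  disease_mirnas <- unique(disease_mirnas)
  universe <- unique(universe)
  if (!all(drug_mirnas %in% universe))
    stop("drug miRNAs outside the universe: ",
         paste(setdiff(drug_mirnas, universe), collapse = ", "))
  if (!all(disease_mirnas %in% universe))
    stop("disease miRNAs outside the universe: ",
         paste(setdiff(disease_mirnas, universe), collapse = ", "))
  k <- length(intersect(drug_mirnas, disease_mirnas))
  p <- stats::phyper(k - 1, length(disease_mirnas),
                     length(universe) - length(disease_mirnas),
                     length(drug_mirnas), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement, mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read a disease-miRNA association table
#'
#' @param path TSV with columns \code{disease} and \code{mirna}.
#' @return Named list disease -> character vector of miRNAs.
#' @export
read_disease_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab$mirna, tab$disease), function(m) sort(unique(m)))
}

#' Drug repositioning by shared miRNAs
#'
#' For every drug in the association network and every disease in the map,
#' tests the overlap of their miRNA sets with \code{\link{drug_disease_test}}
#' and controls the FDR over the tested family with Benjamini-Hochberg. By
#' default only pairs sharing at least one miRNA enter the family (pairs with
#' no overlap are untestable non-candidates); set \code{include_zero = TRUE}
#' to test them too, which enlarges the family.
#'
#' @param network An \code{AssociationNetwork}, or a named list drug ->
#'   miRNA vector.
#' @param disease_map Named list disease -> miRNA vector (see
#'   \code{\link{read_disease_map}}).
#' @param fdr_cutoff FDR threshold for the reported significant pairs
#'   (default 0.1).
#' @param universe Optional miRNA universe; defaults to the union of the
#'   network's and the map's miRNAs.
#' @param include_zero Test pairs with zero shared miRNAs (default FALSE).
#' @return An object of class \code{RepurposingResult}: list with
#'   \code{tested} (data frame drug, disease, shared_mirnas, k, p, fdr sorted
#'   by p), \code{significant} (rows with fdr < cutoff), \code{universe_size}
#'   and \code{fdr_cutoff}.
#' @export
run_repurposing <- function(network, disease_map, fdr_cutoff = 0.1,
                            universe = NULL, include_zero = FALSE) {
  drug_map <- if (inherits(network, "AssociationNetwork"))
    network_partners(network) else network
  if (is.null(universe))
    universe <- union(unlist(drug_map), unlist(disease_map))
  universe <- unique(universe)
  rows <- list()
  for (drug in names(drug_map)) {
    for (disease in names(disease_map)) {
      shared <- intersect(drug_map[[drug]], disease_map[[disease]])
      if (length(shared) == 0L && !include_zero) next
      ht <- drug_disease_test(drug_map[[drug]], disease_map[[disease]],
                              universe)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, disease = disease,
        shared_mirnas = paste(sort(shared), collapse = ","),
        k = ht$k, p = ht$p, stringsAsFactors = FALSE)
    }
  }
  tested <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(drug = character(0), disease = character(0),
               shared_mirnas = character(0), k = integer(0), p = numeric(0))
  tested$fdr <- bh_fdr(tested$p)
  tested <- tested[order(tested$p, tested$drug, tested$disease), ,
                   drop = FALSE]
  rownames(tested) <- NULL
  structure(list(tested = tested,
                 significant = tested[tested$fdr < fdr_cutoff, , drop = FALSE],
                 universe_size = length(universe),
                 fdr_cutoff = fdr_cutoff),
            class = "RepurposingResult")
}

#' @export
print.RepurposingResult <- function(x, ...) {
  cat("RepurposingResult:", nrow(x$tested), "drug-disease pairs tested,",
      nrow(x$significant), "significant at FDR <", x$fdr_cutoff,
      "(universe", x$universe_size, "miRNAs)\n")
  invisible(x)
}

#' Write a repurposing result as TSV
#'
#' @param result A \code{RepurposingResult}.
#' @param path Output path (columns drug, disease, shared_mirnas, k, p, fdr).
#' @param significant_only Write only rows below the FDR cutoff (default
#'   TRUE).
#' @export
write_repurposing <- function(result, path, significant_only = TRUE) {
  tab <- if (significant_only) result$significant else result$tested
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
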