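# End-to-end orchestration: signatures -> enrichment -> similarity ->
# threshold -> network, with optional ROC evaluation, repurposing and
# survival stages, and a provenance record for every run.

#' Build a pipeline configuration
#'
#' Collects input paths and the thresholds of every stage. Expression inputs
#' are described by a manifest TSV with one row per (entity, dataset)
#' expression matrix; alternatively a precomputed signature TSV can be
#' supplied, skipping the differential-expression stage.
#'
#' @param obo Path to the ontology OBO file.
#' @param annotations Path to a gene-term annotation TSV (columns gene,
#'   term) or GMT file.
#' @param out_dir Output directory for the run.
#' @param signatures Optional path to a signature TSV (entity, gene,
#'   direction).
#' @param expression_manifest Optional manifest TSV with columns
#'   \code{entity}, \code{entity_class} ("small_molecule" or "mirna"),
#'   \code{dataset_id}, \code{expr_path}, \code{sheet_path},
#'   \code{method} ("sam", "foldchange" or "amplitude").
#' @param entity_classes Path to a TSV (entity, entity_class) naming which
#'   signature entities are small molecules and which are miRNAs; required
#'   when \code{signatures} is used.
#' @param gold_pairs Optional TSV (small_molecule, mirna) enabling the ROC
#'   evaluation stage.
#' @param disease_map Optional TSV (disease, mirna) enabling the repurposing
#'   stage.
#' @param clinical,expression Optional cohort TSVs enabling the survival
#'   stage.
#' @param alpha_enrich Enrichment significance level (default 0.01).
#' @param alpha_network Network threshold significance level (default 0.01).
#' @param fdr_de SAM FDR cutoff (default 0.05).
#' @param amplitude_cutoff Amplitude cutoff (default 2/3).
#' @param min_support Cross-dataset combination support (default 2).
#' @param n_perm ROC permutations per gold pair (default 99).
#' @param fdr_repurpose Repurposing FDR cutoff (default 0.1).
#' @param seed Integer seed used by every stochastic stage.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(obo, annotations, out_dir,
                            signatures = NULL, expression_manifest = NULL,
                            entity_classes = NULL,
                            gold_pairs = NULL, disease_map = NULL,
                            clinical = NULL, expression = NULL,
                            alpha_enrich = 0.01, alpha_network = 0.01,
                            fdr_de = 0.05, amplitude_cutoff = 2 / 3,
                            min_support = 2L, n_perm = 99L,
                            fdr_repurpose = 0.1, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "PipelineConfig")
  stopifnot(alpha_enrich > 0, alpha_enrich < 1,
            alpha_network > 0, alpha_network <= 0.5,
            fdr_de >= 0, fdr_de <= 1, amplitude_cutoff > 0,
            min_support >= 1, n_perm >= 1,
            fdr_repurpose > 0, fdr_repurpose <= 1)
  if (is.null(signatures) && is.null(expression_manifest))
    stop("either signatures or an expression manifest is required")
  if (!is.null(signatures) && is.null(entity_classes))
    stop("entity_classes is required with precomputed signatures")
  required <- c(obo = obo, annotations = annotations, signatures = signatures,
                expression_manifest = expression_manifest,
                entity_classes = entity_classes, gold_pairs = gold_pairs,
                disease_map = disease_map, clinical = clinical,
                expression = expression)
  missing <- required[!vapply(required, file.exists, TRUE)]
  if (length(missing) > 0L)
    stop("input path(s) do not exist: ",
         paste(names(missing), missing, sep = " = ", collapse = "; "))
  cfg
}

de_call_stage <- function(cfg) {
  manifest <- utils::read.delim(cfg$expression_manifest,
                                stringsAsFactors = FALSE)
  per_dataset <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    profile <- read_expression(row$expr_path,
                               if (nzchar(row$sheet_path)) row$sheet_path,
                               channel_mode = "single")
    sig <- switch(row$method,
                  sam = call_de_sam(profile, fdr_cutoff = cfg$fdr_de,
                                    seed = cfg$seed),
                  foldchange = call_de_foldchange(profile),
                  amplitude = call_de_amplitude(profile,
                                                cutoff = cfg$amplitude_cutoff),
                  stop("unknown DE method: ", row$method))
    sig$entity_id <- row$entity
    sig
  })
  entities <- vapply(per_dataset, `[[`, "", "entity_id")
  sigs <- lapply(split(per_dataset, entities), function(group) {
    if (length(group) == 1L) group[[1L]]
    else combine_signatures(group, min_support = cfg$min_support)
  })
  classes <- manifest$entity_class[match(names(sigs), manifest$entity)]
  list(signatures = sigs, classes = stats::setNames(classes, names(sigs)))
}

#' Run the full association pipeline
#'
#' Stages: differential-expression calling (or signature loading) ->
#' elim enrichment -> best-match-average similarity matrix -> normal
#' threshold fit -> association network, then optionally permutation-ROC
#' evaluation, drug-disease repurposing and survival stratification, as
#' enabled by the configuration. All outputs and a provenance record
#' (package version, seed, configuration) are written to
#' \code{cfg$out_dir}.
#'
#' @param cfg A \code{PipelineConfig}.
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{signatures}, \code{profiles}, \code{similarity}, \code{fit},
#'   \code{network}, and when enabled \code{roc}, \code{repurposing},
#'   \code{stratification}).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dag <- stage("ontology", load_obo(cfg$obo))
  ic <- information_content(dag)
  ann <- stage("annotations", {
    first <- readLines(cfg$annotations, n = 1L)
    if (grepl("\tgene|^gene\t|^gene$", strsplit(first, "\t")[[1L]][1L]))
      read_annotations(cfg$annotations, dag)
    else read_gmt(cfg$annotations, dag)
  })

  if (!is.null(cfg$signatures)) {
    sigs <- stage("signatures", read_signatures(cfg$signatures))
    cls_tab <- utils::read.delim(cfg$entity_classes, stringsAsFactors = FALSE)
    classes <- stats::setNames(cls_tab$entity_class, cls_tab$entity)[names(sigs)]
  } else {
    de <- stage("de-call", de_call_stage(cfg))
    sigs <- de$signatures
    classes <- de$classes
    write_signatures(sigs, file.path(cfg$out_dir, "signatures.tsv"))
  }

  profiles <- stage("enrich", lapply(sigs, function(s) {
    elim_enrich(signature_genes(s), ann, dag, alpha = cfg$alpha_enrich,
                entity_id = s$entity_id)
  }))
  write_profiles(profiles, file.path(cfg$out_dir, "enrichment.tsv"))

  sm_ids <- names(profiles)[classes[names(profiles)] == "small_molecule"]
  mi_ids <- names(profiles)[classes[names(profiles)] == "mirna"]
  sim <- stage("similarity",
               build_similarity_matrix(profiles[sm_ids], profiles[mi_ids],
                                       dag, ic))
  utils::write.table(
    data.frame(small_molecule = rownames(sim)[row(sim)],
               mirna = colnames(sim)[col(sim)], score = as.vector(sim)),
    file.path(cfg$out_dir, "similarity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  fit <- stage("threshold", fit_threshold(sim, alpha = cfg$alpha_network))
  network <- stage("network", threshold_network(sim, fit))
  write_network(network, file.path(cfg$out_dir, "network.tsv"),
                file.path(cfg$out_dir, "network.graphml"))

  out <- list(signatures = sigs, profiles = profiles, similarity = sim,
              fit = fit, network = network)

  if (!is.null(cfg$gold_pairs)) {
    gold <- utils::read.delim(cfg$gold_pairs, stringsAsFactors = FALSE)
    roc_in <- stage("evaluate",
                    make_roc_input(gold, profiles[sm_ids], profiles[mi_ids],
                                   dag, ic, n_perm = cfg$n_perm,
                                   seed = cfg$seed))
    out$roc <- roc_auc(roc_in)
    utils::write.table(out$roc$curve, file.path(cfg$out_dir, "roc_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$disease_map)) {
    dmap <- read_disease_map(cfg$disease_map)
    out$repurposing <- stage("repurpose",
                             run_repurposing(network, dmap,
                                             fdr_cutoff = cfg$fdr_repurpose))
    write_repurposing(out$repurposing,
                      file.path(cfg$out_dir, "repurposing.tsv"),
                      significant_only = FALSE)
  }

  if (!is.null(cfg$clinical)) {
    cohort <- stage("survival", read_cohort(cfg$clinical, cfg$expression))
    out$stratification <- stratify_cohort(cohort, seed = cfg$seed)
    write_km_tables(out$stratification,
                    file.path(cfg$out_dir, "km_curves.tsv"))
  }

  provenance <- list(
    package = "smirnet",
    version = as.character(utils::packageVersion("smirnet")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    timestamp = NULL)  # deliberately omitted: outputs are byte-stable per seed
  jsonlite::write_json(provenance,
                       file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out)
}
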