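# Writes a complete synthetic input directory for pipeline runs: ontology,
# gene-term annotations, entity signatures derived from the scenario's term
# profiles, gold pairs, a disease map and a survival cohort.
write_pipeline_inputs <- function(dir, seed = 1L, n_genes = 400L,
                                  genes_per_term = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- make_association_scenario(seed = seed)
  write_obo(scen$dag, file.path(dir, "ontology.obo"))

  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  direct <- lapply(setNames(scen$dag$terms, scen$dag$terms),
                   function(t) sample(genes, genes_per_term))
  ann <- annotation_map(direct, scen$dag)
  write.table(data.frame(gene = unlist(direct),
                         term = rep(names(direct), lengths(direct))),
              file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  profs <- c(scen$sm_profiles, scen$mirna_profiles)
  sigs <- lapply(names(profs), function(id) {
    signature_set(id, up = unique(unlist(ann$propagated[profs[[id]]])))
  })
  write_signatures(sigs, file.path(dir, "signatures.tsv"))
  write.table(data.frame(
    entity = names(profs),
    entity_class = rep(c("small_molecule", "mirna"),
                       c(length(scen$sm_profiles),
                         length(scen$mirna_profiles)))),
    file.path(dir, "entity_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scen$truth$planted_pairs, file.path(dir, "gold_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # diseases built around planted miRNAs plus random fillers
  mirnas <- names(scen$mirna_profiles)
  dmap <- data.frame(
    disease = rep(c("disease_planted", "disease_random"), each = 3),
    mirna = c(scen$truth$planted_pairs$mirna[1:3],
              sample(mirnas, 3)))
  write.table(dmap, file.path(dir, "disease_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sv <- make_survival(n_per_group = 50, seed = seed)
  write.table(data.frame(patient = sv$cohort$patient, time = sv$cohort$time,
                         event = sv$cohort$event),
              file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(patient = rownames(sv$cohort$mirna_expr),
                         sv$cohort$mirna_expr, check.names = FALSE),
              file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(scen$truth, file.path(dir, "truth.json"))
  invisible(scen)
}
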