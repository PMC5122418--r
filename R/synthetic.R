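# Synthetic fixtures with known ground truth: ontology DAGs, two-class
# expression matrices, association scenarios and survival cohorts. Every
# generator is a pure function of its parameters and seed.

term_ids <- function(n) sprintf("SYN:%07d", seq_len(n))

#' Generate a random single-root ontology DAG
#'
#' Builds a balanced tree backbone (each node's parent is determined by
#' \code{branching}); with \code{p_extra_parent > 0} additional is_a edges to
#' random earlier non-ancestor terms turn the tree into a proper DAG.
#'
#' @param n_terms Number of terms (>= 3).
#' @param branching Children per node in the tree backbone (default 2).
#' @param seed Integer seed.
#' @param p_extra_parent Probability that a non-root term gains a second
#'   parent (default 0, i.e. a tree).
#' @param obo_path If non-NULL, the DAG is also written there as OBO 1.2.
#' @return An \code{OntologyDag}.
#' @export
make_dag <- function(n_terms, branching = 2L, seed = 1L,
                     p_extra_parent = 0, obo_path = NULL) {
  if (n_terms < 3L) stop("a synthetic ontology needs at least 3 terms")
  ids <- term_ids(n_terms)
  parents <- lapply(seq_len(n_terms), function(i) {
    if (i == 1L) character(0) else ids[(i - 2L) %/% branching + 1L]
  })
  names(parents) <- ids
  if (p_extra_parent > 0) {
    set.seed(seed)
    for (i in 3:n_terms) {
      if (stats::runif(1) < p_extra_parent) {
        # candidate second parents: earlier terms, excluding current ancestors
        anc <- i
        cur <- i
        while (cur != 1L) {
          cur <- (cur - 2L) %/% branching + 1L
          anc <- c(anc, cur)
        }
        cand <- setdiff(seq_len(i - 1L), anc)
        if (length(cand) > 0L)
          parents[[i]] <- c(parents[[i]], ids[cand[sample.int(length(cand), 1L)]])
      }
    }
  }
  dag <- ontology_dag(ids, parents)
  if (!is.null(obo_path)) write_obo(dag, obo_path)
  dag
}

#' Generate a two-class expression profile with planted DE genes
#'
#' Gene-level baselines are drawn on the log2 scale (normal around 8);
#' planted genes are shifted by \code{effect * noise_sd} (up or down) in the
#' treatment samples. Returned on the linear scale
#' (\code{scale = "linear"}, the default, emulating unlogged array
#' intensities) or log2 scale.
#'
#' @param n_genes Total genes.
#' @param n_treat,n_ctrl Samples per class.
#' @param planted_up,planted_down Numbers of up-/down-shifted genes (disjoint
#'   sets, the first genes of the matrix).
#' @param effect Shift in units of \code{noise_sd} (default 3).
#' @param noise_sd Per-measurement log2-scale noise standard deviation
#'   (default 0.5).
#' @param seed Integer seed.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return List with the \code{profile} (an \code{ExpressionProfile}) and
#'   \code{truth} (planted gene ids with directions, parameters, seed).
#' @export
make_expression <- function(n_genes = 220L, n_treat = 5L, n_ctrl = 5L,
                            planted_up = 10L, planted_down = 10L,
                            effect = 3, noise_sd = 0.5, seed = 1L,
                            scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (planted_up + planted_down > n_genes)
    stop("more planted genes than genes")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, mean = 8, sd = 1)
  m <- matrix(stats::rnorm(n_genes * (n_treat + n_ctrl), mean = base,
                           sd = noise_sd),
              nrow = n_genes, ncol = n_treat + n_ctrl)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("t%02d", seq_len(n_treat)),
                   sprintf("c%02d", seq_len(n_ctrl)))
  up <- genes[seq_len(planted_up)]
  down <- genes[planted_up + seq_len(planted_down)]
  shift <- effect * noise_sd
  m[up, seq_len(n_treat)] <- m[up, seq_len(n_treat)] + shift
  m[down, seq_len(n_treat)] <- m[down, seq_len(n_treat)] - shift
  labels <- rep(c("treatment", "control"), c(n_treat, n_ctrl))
  profile <- if (scale == "linear")
    expression_profile(2^m, labels, "single", log2_scale = FALSE)
  else expression_profile(m, labels, "single", log2_scale = TRUE)
  list(profile = profile,
       truth = list(up = up, down = down, effect = effect,
                    noise_sd = noise_sd, seed = seed, scale = scale))
}

#' Generate a planted small molecule-miRNA association scenario
#'
#' Every entity receives an enriched term set drawn from the leaves-biased
#' lower half of a synthetic ontology. For each planted pair (sm_i, mir_i),
#' the two term sets share \code{round(term_overlap * n_terms_per_entity)}
#' terms; all other terms, and all terms of background entities, are drawn
#' independently. Intended for end-to-end exercises: similarity matrix,
#' threshold fit, network recovery and permutation-ROC evaluation.
#'
#' @param n_sm,n_mirna Numbers of small molecules and miRNAs.
#' @param n_planted_pairs Planted associated pairs (pair i links sm_i with
#'   mir_i); must not exceed \code{min(n_sm, n_mirna)}.
#' @param term_overlap Fraction of each planted pair's terms that are shared,
#'   in (0, 1].
#' @param n_terms_per_entity Enriched terms per entity (default 8).
#' @param dag_terms Ontology size (default 200).
#' @param branching DAG branching factor (default 3).
#' @param seed Integer seed.
#' @return List with \code{dag}, \code{ic}, \code{sm_profiles} and
#'   \code{mirna_profiles} (named term-set lists), and \code{truth}
#'   (data frame of planted pairs plus all parameters).
#' @export
make_association_scenario <- function(n_sm = 20L, n_mirna = 10L,
                                      n_planted_pairs = 5L,
                                      term_overlap = 0.8,
                                      n_terms_per_entity = 8L,
                                      dag_terms = 200L, branching = 3L,
                                      seed = 1L) {
  if (term_overlap <= 0 || term_overlap > 1)
    stop("term_overlap must lie in (0, 1]")
  if (n_planted_pairs > min(n_sm, n_mirna))
    stop("more planted pairs than entities")
  dag <- make_dag(dag_terms, branching = branching, seed = seed)
  ic <- information_content(dag)
  # sample from specific (deep) terms so random sets are dissimilar
  depth <- term_depths(dag)
  pool <- dag$terms[depth >= stats::median(depth)]
  set.seed(seed + 1L)
  draw <- function(n, exclude = character(0)) {
    sample(setdiff(pool, exclude), n)
  }
  sm_ids <- sprintf("SM%03d", seq_len(n_sm))
  mi_ids <- sprintf("miR-%03d", seq_len(n_mirna))
  sm_profiles <- lapply(stats::setNames(sm_ids, sm_ids),
                        function(id) draw(n_terms_per_entity))
  mirna_profiles <- lapply(stats::setNames(mi_ids, mi_ids),
                           function(id) draw(n_terms_per_entity))
  n_shared <- max(1L, round(term_overlap * n_terms_per_entity))
  planted <- data.frame(small_molecule = sm_ids[seq_len(n_planted_pairs)],
                        mirna = mi_ids[seq_len(n_planted_pairs)],
                        stringsAsFactors = FALSE)
  if (n_planted_pairs > 0L) {
    for (i in seq_len(n_planted_pairs)) {
      shared <- draw(n_shared)
      sm_profiles[[planted$small_molecule[i]]] <-
        c(shared, draw(n_terms_per_entity - n_shared, exclude = shared))
      mirna_profiles[[planted$mirna[i]]] <-
        c(shared, draw(n_terms_per_entity - n_shared, exclude = shared))
    }
  }
  list(dag = dag, ic = ic, sm_profiles = sm_profiles,
       mirna_profiles = mirna_profiles,
       truth = list(planted_pairs = planted, term_overlap = term_overlap,
                    n_shared = n_shared,
                    n_terms_per_entity = n_terms_per_entity, seed = seed))
}

#' Generate a two-group survival cohort with a planted hazard ratio
#'
#' Event times are exponential with baseline rate 0.1 for the good-prognosis
#' group and \code{hazard_ratio} times that for the poor group; censoring
#' times are exponential with rate chosen to censor approximately
#' \code{censor_rate} of the baseline group. Each miRNA's expression is
#' normal with the good group shifted up by \code{expr_separation} standard
#' deviations, matching the direction reported for prognosis-marker miRNAs.
#'
#' @param n_per_group Patients per group.
#' @param hazard_ratio Poor-over-good hazard ratio (> 0).
#' @param censor_rate Approximate censoring fraction in (0, 1) (default 0.3).
#' @param expr_separation Expression shift between groups, in SD units
#'   (default 2).
#' @param n_mirnas miRNA columns (default 3).
#' @param seed Integer seed.
#' @return List with \code{cohort} (a \code{SurvivalCohort}) and
#'   \code{truth} (true group labels and parameters).
#' @export
make_survival <- function(n_per_group = 200L, hazard_ratio = 2,
                          censor_rate = 0.3, expr_separation = 2,
                          n_mirnas = 3L, seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (censor_rate <= 0 || censor_rate >= 1)
    stop("censor_rate must lie in (0, 1)")
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("good", "poor"), each = n_per_group)
  base_rate <- 0.1
  rate <- ifelse(group == "good", base_rate, base_rate * hazard_ratio)
  t_event <- stats::rexp(n, rate = rate)
  cens_rate <- base_rate * censor_rate / (1 - censor_rate)
  t_cens <- stats::rexp(n, rate = cens_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  expr <- matrix(stats::rnorm(n * n_mirnas,
                              mean = 8 + ifelse(group == "good",
                                                expr_separation, 0)),
                 nrow = n, ncol = n_mirnas,
                 dimnames = list(sprintf("p%04d", seq_len(n)),
                                 sprintf("miR-%03d", seq_len(n_mirnas))))
  cohort <- survival_cohort(rownames(expr), time, event, expr)
  list(cohort = cohort,
       truth = list(group = stats::setNames(group, rownames(expr)),
                    hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                    expr_separation = expr_separation, seed = seed))
}

#' Write a generator truth record as JSON
#'
#' @param truth The \code{truth} element returned by a generator.
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an expression profile and its sample sheet as TSV
#'
#' @param profile An \code{ExpressionProfile}.
#' @param expr_path Expression TSV output path.
#' @param sheet_path Sample-sheet TSV output path (columns sample, class,
#'   dataset_id).
#' @param dataset_id Dataset label for the sheet (default "d1").
#' @export
write_expression <- function(profile, expr_path, sheet_path,
                             dataset_id = "d1") {
  tab <- data.frame(gene = rownames(profile$matrix), profile$matrix,
                    check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample = colnames(profile$matrix),
                      class = profile$class_labels,
                      dataset_id = dataset_id)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}
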