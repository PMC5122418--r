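test_that("one-sided enrichment p-value matches exhaustive tail summation", {
  expect_equal(fisher_enrich_term(0, 5, 5, 50), 1)
  expect_equal(fisher_enrich_term(5, 5, 5, 5), 1)
  expect_equal(fisher_enrich_term(3, 5, 5, 50), oracle_hyper_tail(3, 5, 5, 50))

  set.seed(11)
  for (i in 1:100) {
    M <- sample(10:60, 1)
    n <- sample(1:M, 1)
    K <- sample(1:M, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisher_enrich_term(k, n, K, M),
                 oracle_hyper_tail(k, n, K, M), tolerance = 1e-12)
  }
  expect_error(fisher_enrich_term(6, 5, 5, 50), "inconsistent")
  expect_error(fisher_enrich_term(2, 5, 60, 50), "inconsistent")
})

test_that("enrichment p equals the one-sided Fisher exact test on the 2x2 table", {
  set.seed(3)
  for (i in 1:20) {
    M <- sample(15:40, 1); n <- sample(2:10, 1); K <- sample(2:12, 1)
    k <- sample(max(0, n + K - M):min(n, K), 1)
    tab <- matrix(c(k, n - k, K - k, M - n - K + k), 2)
    expect_equal(fisher_enrich_term(k, n, K, M),
                 fisher.test(tab, alternative = "greater")$p.value)
  }
})

test_that("annotation propagation is the union over descendants", {
  for (seed in 1:3) {
    dag <- make_dag(30, branching = 3, seed = seed, p_extra_parent = 0.3)
    set.seed(seed)
    genes <- sprintf("g%02d", 1:60)
    direct <- lapply(setNames(dag$terms, dag$terms),
                     function(t) sample(genes, sample(0:4, 1)))
    ann <- annotation_map(direct, dag)
    for (t in dag$terms) {
      brute <- sort(unique(unlist(direct[term_descendants(dag, t)])))
      expect_equal(ann$propagated[[t]], brute)
      for (ch in dag$children[[t]])
        expect_true(all(ann$propagated[[ch]] %in% ann$propagated[[t]]))
    }
    # idempotence: re-propagating the propagated map changes nothing
    ann2 <- annotation_map(ann$propagated, dag)
    expect_equal(ann2$propagated, ann$propagated)
  }
})

# chain root -> A -> B; all study genes sit in B
chain_fixture <- function() {
  dag <- ontology_dag(c("r", "A", "B"),
                      list(r = character(0), A = "r", B = "A"))
  direct <- list(B = c("g1", "g2", "g3", "g4"),
                 A = c("g5", "g6"),
                 r = c("g7", "g8", "g9", "g10"))
  list(dag = dag, ann = annotation_map(direct, dag))
}

test_that("elim removes a significant term's genes from its ancestors", {
  fx <- chain_fixture()
  study <- c("g1", "g2", "g3", "g4")

  elim <- elim_enrich(study, fx$ann, fx$dag, alpha = 0.01, all_terms = TRUE)
  classic <- classic_enrich(study, fx$ann, fx$dag, alpha = 0.01,
                            all_terms = TRUE)
  pe <- setNames(elim$p, elim$term)
  pc <- setNames(classic$p, classic$term)

  # B is significant under both: all 4 study genes among its 4 of 10
  expect_equal(pc[["B"]], oracle_hyper_tail(4, 4, 4, 10))
  expect_lt(pc[["B"]], 0.01)
  expect_equal(pe[["B"]], pc[["B"]])

  # classic A inherits B's genes (K = 6, k = 4); elim tests A without them
  expect_equal(pc[["A"]], oracle_hyper_tail(4, 4, 6, 10))
  expect_equal(pe[["A"]], oracle_hyper_tail(0, 4, 2, 10))
  expect_gt(pe[["A"]], pc[["A"]])

  # only B is reported at alpha = 0.01
  sig <- elim_enrich(study, fx$ann, fx$dag, alpha = 0.01)
  expect_equal(profile_terms(sig), "B")
})

test_that("without significant terms elim equals classic Fisher everywhere", {
  dag <- make_dag(20, branching = 2, seed = 4)
  set.seed(4)
  genes <- sprintf("g%02d", 1:50)
  direct <- lapply(setNames(dag$terms, dag$terms),
                   function(t) sample(genes, 2))
  ann <- annotation_map(direct, dag)
  study <- sample(genes, 5)    # diffuse: nothing should reach 0.01
  elim <- elim_enrich(study, ann, dag, alpha = 1e-6, all_terms = TRUE)
  classic <- classic_enrich(study, ann, dag, alpha = 1e-6, all_terms = TRUE)
  expect_equal(elim[order(elim$term), c("term", "p", "k", "K")],
               classic[order(classic$term), c("term", "p", "k", "K")],
               ignore_attr = TRUE)
})

test_that("elim pruning is branch-local", {
  # two disjoint branches under one root
  dag <- ontology_dag(c("r", "A1", "A2", "B1", "B2"),
                      list(r = character(0), A1 = "r", A2 = "A1",
                           B1 = "r", B2 = "B1"))
  direct <- list(A2 = sprintf("a%d", 1:4), A1 = sprintf("a%d", 5:6),
                 B2 = sprintf("b%d", 1:4), B1 = sprintf("b%d", 5:6),
                 r = sprintf("c%d", 1:8))
  ann <- annotation_map(direct, dag)
  study <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:2))
  full <- elim_enrich(study, ann, dag, alpha = 0.05, all_terms = TRUE)
  # p-values in the A branch do not depend on the B branch's genes
  dagA <- ontology_dag(c("r", "A1", "A2"),
                       list(r = character(0), A1 = "r", A2 = "A1"))
  annA <- annotation_map(direct[c("A2", "A1", "r")], dagA)
  onlyA <- elim_enrich(study, annA, dagA, alpha = 0.05,
                       universe = ann$universe, all_terms = TRUE)
  pf <- setNames(full$p, full$term)
  pa <- setNames(onlyA$p, onlyA$term)
  expect_equal(pf[c("A1", "A2")], pa[c("A1", "A2")])
})

test_that("empty study sets warn and yield empty profiles", {
  fx <- chain_fixture()
  expect_warning(res <- elim_enrich(character(0), fx$ann, fx$dag), "empty")
  expect_equal(nrow(res), 0L)
  expect_warning(elim_enrich("not_annotated", fx$ann, fx$dag), "empty")
})

test_that("GMT and TSV annotation readers agree and profiles round-trip", {
  dag <- make_dag(12, branching = 2, seed = 9)
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  direct <- lapply(setNames(dag$terms, dag$terms),
                   function(t) sort(sample(genes, 3)))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(vapply(names(direct), function(t)
    paste(c(t, t, direct[[t]]), collapse = "\t"), ""), gmt)
  write.table(data.frame(gene = unlist(direct),
                         term = rep(names(direct), lengths(direct))),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  a1 <- read_gmt(gmt, dag)
  a2 <- read_annotations(tsv, dag)
  expect_equal(a1$propagated, a2$propagated)

  leaf <- dag$terms[lengths(dag$children) == 0][1]
  study <- direct[[leaf]]
  prof <- elim_enrich(study, a1, dag, alpha = 0.05, entity_id = "e1")
  expect_gt(nrow(prof), 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(list(e1 = prof), f)
  back <- read_profiles(f)
  expect_equal(back$e1$term, prof$term)
  expect_equal(back$e1$p, prof$p)
})
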