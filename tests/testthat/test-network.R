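test_that("similarity matrix hits the BMA identity and root-only cases", {
  dag <- tree7()
  ic <- information_content(dag)
  sm <- list(SM1 = c("SYN:0000004", "SYN:0000005"))
  # identical term sets score 1
  mi <- list(miA = c("SYN:0000004", "SYN:0000005"),
             # only the root in common with SM1's terms: 0
             miB = c("SYN:0000006", "SYN:0000007"))
  m <- build_similarity_matrix(sm, mi, dag, ic)
  expect_equal(unname(m["SM1", "miA"]), 1)
  expect_equal(unname(m["SM1", "miB"]), 0)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("entities with empty profiles are dropped with a message", {
  dag <- tree7()
  ic <- information_content(dag)
  sm <- list(SM1 = c("SYN:0000004"), SM2 = character(0))
  mi <- list(miA = c("SYN:0000005"))
  expect_message(m <- build_similarity_matrix(sm, mi, dag, ic), "SM2")
  expect_equal(rownames(m), "SM1")
})

test_that("planted pairs score above the background score distribution", {
  for (seed in 1:3) {
    scen <- make_association_scenario(seed = seed)
    m <- build_similarity_matrix(scen$sm_profiles, scen$mirna_profiles,
                                 scen$dag, scen$ic)
    tp <- scen$truth$planted_pairs
    planted_idx <- cbind(match(tp$small_molecule, rownames(m)),
                         match(tp$mirna, colnames(m)))
    planted <- m[planted_idx]
    background <- m[-(planted_idx[, 1] + (planted_idx[, 2] - 1) * nrow(m))]
    expect_gt(min(planted), quantile(background, 0.95))
  }
})

test_that("the normal threshold reproduces the reported cutoff and degenerate cases", {
  # two scores with exactly the reported sample moments
  mu <- 0.4882; sigma <- 0.0965
  scores <- c(mu - sigma / sqrt(2), mu + sigma / sqrt(2))
  fit <- fit_threshold(scores, alpha = 0.01)
  expect_equal(fit$mu, mu)
  expect_equal(fit$sigma, sigma)
  expect_equal(round(fit$cutoff, 4), 0.7127)

  expect_equal(normal_cutoff(0.3, 0.1, 0.5), 0.3)          # z(0.5) = 0
  expect_equal(normal_cutoff(0, 1, 0.01), qnorm(0.99))     # ~2.3263
  expect_error(fit_threshold(rep(0.5, 10)), "zero variance")
  expect_error(fit_threshold(0.5), "at least two")
})

test_that("the fitted cutoff is shift- and scale-equivariant", {
  set.seed(8)
  x <- rnorm(200, 0.5, 0.1)
  f0 <- fit_threshold(x)
  f_shift <- fit_threshold(x + 0.2)
  expect_equal(f_shift$cutoff, f0$cutoff + 0.2)
  f_scale <- fit_threshold(x * 3)
  expect_equal(f_scale$cutoff - f_scale$mu, 3 * (f0$cutoff - f0$mu))
})

test_that("network thresholding keeps scores at or above the cutoff", {
  m <- matrix(c(0.9, 0.2, 0.75, 0.1, 0.3, 0.4, 0.5, 0.6, 0.75), 3,
              dimnames = list(paste0("SM", 1:3), paste0("mi", 1:3)))
  net <- threshold_network(m, 0.75)
  expect_equal(nrow(net$edges), 3L)            # closed inequality: 0.75 counts
  expect_true(all(net$edges$score >= 0.75))
  expect_equal(sum(net$sm_degree), 3L)

  empty <- threshold_network(m, 0.95)
  expect_equal(nrow(empty$edges), 0L)

  scen <- make_association_scenario(seed = 1)
  sim <- build_similarity_matrix(scen$sm_profiles, scen$mirna_profiles,
                                 scen$dag, scen$ic)
  net2 <- threshold_network(sim, fit_threshold(sim, 0.01))
  got <- paste(net2$edges$small_molecule, net2$edges$mirna)
  want <- paste(scen$truth$planted_pairs$small_molecule,
                scen$truth$planted_pairs$mirna)
  expect_setequal(got, want)
})

test_that("Meet/Min and Tanimoto behave as overlap coefficients", {
  expect_equal(meet_min(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(meet_min(c("a", "b"), c("a", "b")), 1)
  expect_equal(meet_min(c("a"), c("b")), 0)
  expect_equal(meet_min(c("a", "b", "c", "d"), c("a", "x")), 1 / 2)
  expect_error(meet_min(character(0), "a"), "empty")

  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")

  # symmetry on random fingerprints
  set.seed(5)
  for (i in 1:10) {
    f1 <- rbinom(32, 1, 0.4); f2 <- rbinom(32, 1, 0.4)
    expect_equal(tanimoto(f1, f2), tanimoto(f2, f1))
    expect_gte(tanimoto(f1, f2), 0); expect_lte(tanimoto(f1, f2), 1)
    s1 <- letters[1:sample(2:8, 1)]; s2 <- letters[sample(2:10, 1):10]
    expect_equal(meet_min(s1, s2), meet_min(s2, s1))
  }
})

test_that("fingerprint reader parses bitstrings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tbits", "cpd1\t1100", "cpd2\t1010"), f)
  fps <- read_fingerprints(f)
  expect_equal(fps$cpd1, c(1L, 1L, 0L, 0L))
  expect_equal(tanimoto(fps$cpd1, fps$cpd2), 1 / 3)
})

test_that("target voting keeps pairs supported by enough algorithms", {
  tabs <- lapply(1:7, function(i) {
    data.frame(mirna = "miR-1", gene = "gA", stringsAsFactors = FALSE)
  })
  tabs[[1]] <- rbind(tabs[[1]], data.frame(mirna = "miR-1", gene = "gB"))
  tabs[[2]] <- rbind(tabs[[2]], data.frame(mirna = "miR-1", gene = "gB"),
                     data.frame(mirna = "miR-2", gene = "gC"))
  voted <- vote_targets(tabs, min_algorithms = 2)
  expect_true("gA" %in% voted[["miR-1"]])       # in all 7 tables
  expect_true("gB" %in% voted[["miR-1"]])       # in exactly 2
  expect_false("miR-2" %in% names(voted))       # gC in 1 table only
  expect_error(vote_targets(tabs[1]), "at least two")

  # duplicates within one table do not count twice
  dup <- list(data.frame(mirna = "m", gene = c("g", "g")),
              data.frame(mirna = "x", gene = "y"))
  expect_false("m" %in% names(vote_targets(dup, 2)))
})

test_that("shared-target counts correlate with similarity as reported", {
  edges <- data.frame(small_molecule = paste0("SM", 1:5),
                      mirna = paste0("mi", 1:5),
                      score = c(0.95, 0.9, 0.85, 0.8, 0.75))
  net <- structure(list(edges = edges), class = "AssociationNetwork")
  # counts strictly increasing with score -> perfect rank correlation
  drug_targets <- lapply(setNames(5:1, paste0("SM", 1:5)),
                         function(n) paste0("t", seq_len(n)))
  mirna_targets <- lapply(setNames(paste0("mi", 1:5), paste0("mi", 1:5)),
                          function(x) paste0("t", 1:5))
  res <- overlap_vs_similarity(net, drug_targets, mirna_targets)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.05)

  # constant counts: undefined, flagged
  const_targets <- lapply(drug_targets, function(x) "t1")
  res2 <- overlap_vs_similarity(net, const_targets, mirna_targets)
  expect_true(is.na(res2$rho))
  expect_match(res2$note, "undefined")

  # 5-point hand data against the rank formula
  drug_targets3 <- lapply(setNames(c(3, 1, 4, 2, 5), paste0("SM", 1:5)),
                          function(n) paste0("t", seq_len(n)))
  res3 <- overlap_vs_similarity(net, drug_targets3, mirna_targets)
  expect_equal(res3$rho,
               oracle_spearman(res3$edges$shared_targets, res3$edges$score))

  # fewer than 3 usable edges
  res4 <- overlap_vs_similarity(net, drug_targets[1:2], mirna_targets)
  expect_true(is.na(res4$rho))
})
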