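test_that("amplitude statistic has the documented boundary and limits", {
  expect_identical(amplitude(2, 1), 2 / 3)       # exact 2-fold boundary
  expect_equal(amplitude(3, 3), 0)
  expect_equal(amplitude(5, 0), 2)
  expect_equal(amplitude(0, 5), -2)
  expect_true(is.na(amplitude(0, 0)))
  expect_error(amplitude(-1, 2), "non-negative")
})

test_that("amplitude is antisymmetric, monotone in t, and |A|>2/3 iff fold change > 2", {
  set.seed(1)
  t <- runif(500, 0.01, 100)
  c <- runif(500, 0.01, 100)
  expect_equal(amplitude(t, c), -amplitude(c, t))
  # strictly increasing in t for fixed c
  expect_true(all(diff(amplitude(seq(0.1, 50, length.out = 200), 7)) > 0))
  a <- amplitude(t, c)
  fc <- pmax(t, c) / pmin(t, c)
  expect_equal(abs(a) > 2 / 3, fc > 2)
})

make_sam_profile <- function(seed) make_expression(seed = seed)

test_that("SAM-style caller recovers planted genes and controls false calls", {
  ex <- make_sam_profile(1)
  sig <- call_de_sam(ex$profile, fdr_cutoff = 0.05, seed = 1)
  planted <- c(ex$truth$up, ex$truth$down)
  recovered <- sum(ex$truth$up %in% sig$up) + sum(ex$truth$down %in% sig$down)
  expect_gte(recovered, 18)
  null_genes <- setdiff(rownames(ex$profile$matrix), planted)
  false_rate <- mean(null_genes %in% c(sig$up, sig$down))
  expect_lte(false_rate, 0.05)
})

test_that("SAM caller returns nothing without signal or with a zero cutoff", {
  ex <- make_sam_profile(2)
  # identical treatment and control matrices: no evidence at all
  m <- ex$profile$matrix
  m[, 1:5] <- m[, 6:10]
  flat <- expression_profile(m, ex$profile$class_labels, "single")
  sig <- call_de_sam(flat, fdr_cutoff = 0.05, seed = 1)
  expect_length(c(sig$up, sig$down), 0)

  sig0 <- call_de_sam(ex$profile, fdr_cutoff = 0, seed = 1)
  expect_length(c(sig0$up, sig0$down), 0)

  one <- expression_profile(m[, c(1, 6, 7)],
                            c("treatment", "control", "control"), "single")
  expect_error(call_de_sam(one), "fold-change")
})

test_that("SAM null false-call rate stays within twice the FDR cutoff", {
  rates <- vapply(1:50, function(s) {
    exn <- make_expression(planted_up = 0, planted_down = 0,
                           n_genes = 100, seed = s)
    sn <- call_de_sam(exn$profile, fdr_cutoff = 0.05, n_perm = 100, seed = s)
    (length(sn$up) + length(sn$down)) / 100
  }, 0)
  expect_lte(mean(rates), 2 * 0.05)
})

test_that("fold-change caller applies per-sample ratios and a strict majority", {
  # one gene, 3 treatment samples with ratios (2.5, 3, 0.3) to a unit control
  m <- rbind(gA = c(2.5, 3, 0.3, 1),
             gB = c(2.5, 2.1, 0.3, 1),      # up in 2 of 3: strict majority
             gC = c(3, 0.25, 1, 1),         # up 1, down 1 of 3: no call
             gD = c(0.2, 0.4, 0.5, 1))      # down in 3 of 3
  prof <- expression_profile(m, c("treatment", "treatment", "treatment",
                                  "control"), "single")
  sig <- call_de_foldchange(prof)
  expect_setequal(sig$up, c("gA", "gB"))
  expect_setequal(sig$down, "gD")
  expect_false("gC" %in% c(sig$up, sig$down))

  # up in exactly 2 of 4 samples fails the strict majority
  m4 <- rbind(gE = c(4, 4, 1, 1, 1))
  prof4 <- expression_profile(m4, c(rep("treatment", 4), "control"), "single")
  expect_length(call_de_foldchange(prof4)$up, 0)

  # up in one sample, down in the other (of 2): no call either way
  m2 <- rbind(gF = c(4, 0.25, 1))
  prof2 <- expression_profile(m2, c("treatment", "treatment", "control"),
                              "single")
  s2 <- call_de_foldchange(prof2)
  expect_length(c(s2$up, s2$down), 0)
})

test_that("fold-change caller handles double-channel ratios and bad controls", {
  # double-channel: columns are already per-sample ratios
  m <- rbind(gA = c(2.5, 4, 8), gB = c(0.4, 0.3, 0.6), gC = c(1, 1, 1))
  prof <- expression_profile(m, channel_mode = "double")
  sig <- call_de_foldchange(prof)
  expect_setequal(sig$up, "gA")
  expect_setequal(sig$down, "gB")

  # a non-positive control invalidates the gene's ratios
  mz <- rbind(gZ = c(4, 4, 0), gY = c(4, 4, 2))
  pz <- expression_profile(mz, c("treatment", "treatment", "control"),
                           "single")
  sz <- call_de_foldchange(pz)
  expect_false("gZ" %in% c(sz$up, sz$down))
  expect_true("gY" %in% sz$up)
})

test_that("amplitude caller agrees with the strict 2-fold rule", {
  # ratio exactly 2 gives A = 2/3, not above the cutoff: no call
  m <- rbind(g1 = c(2, 1), g2 = c(2.01, 1), g3 = c(0.49, 1))
  prof <- expression_profile(m, c("treatment", "control"), "single")
  sig <- call_de_amplitude(prof)
  expect_false("g1" %in% sig$up)
  expect_true("g2" %in% sig$up)
  expect_true("g3" %in% sig$down)
})

test_that("log2-scale profiles are unlogged before ratio rules", {
  m <- rbind(g1 = c(3, 1), g2 = c(1, 3))    # log2 values: ratios 4 and 1/4
  prof <- expression_profile(m, c("treatment", "control"), "single",
                             log2_scale = TRUE)
  sig <- call_de_foldchange(prof)
  expect_setequal(sig$up, "g1")
  expect_setequal(sig$down, "g2")
})

test_that("signature combination enforces support and conflict rules", {
  sigs <- list(signature_set("e", up = c("a", "b"), down = "z"),
               signature_set("e", up = c("a", "c"), down = "z"),
               signature_set("e", up = "d", down = c("z", "a")))
  comb <- combine_signatures(sigs, min_support = 2)
  # a: up twice and down once -> up; b, c, d: once only; z: down three times
  expect_setequal(comb$up, "a")
  expect_setequal(comb$down, "z")

  # qualifying in both directions is a conflict
  sigs2 <- list(signature_set("e", up = "g"), signature_set("e", up = "g"),
                signature_set("e", down = "g"), signature_set("e", down = "g"))
  expect_length(unlist(combine_signatures(sigs2, 2)[c("up", "down")]), 0)

  expect_setequal(combine_signatures(sigs, min_support = 3)$down, "z")
})

test_that("signature construction discards conflict genes and round-trips TSV", {
  sig <- signature_set("sm1", up = c("a", "b", "c"), down = c("c", "d"))
  expect_setequal(sig$up, c("a", "b"))
  expect_setequal(sig$down, "d")
  expect_length(intersect(sig$up, sig$down), 0)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(list(sig, signature_set("sm2", up = "x")), f)
  back <- read_signatures(f)
  expect_equal(names(back), c("sm1", "sm2"))
  expect_equal(back$sm1$up, sig$up)
  expect_equal(back$sm1$down, sig$down)
})
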