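# QC statistics and the gene filter.

test_that("completeness score: gap-free 1.0, half-missing 0.5, empty
           errors", {
  m <- matrix("A", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  a <- new_alignment(m, "DNA")
  expect_equal(completeness_score(a)$overall, 1)
  m2 <- m; m2[, 1:5] <- NA
  expect_equal(completeness_score(new_alignment(m2, "DNA"))$overall, 0.5)
  expect_error(completeness_score(
    new_alignment(matrix(character(0), 0, 0,
                         dimnames = list(character(0), NULL)), "DNA")))
})

test_that("RCFV: identical sequences 0; hand-computed binary example
           0.2; invariant to row/column permutation", {
  m <- matrix(rep(c("A", "C", "G", "T"), 5), 3, 20, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  expect_equal(rcfv(new_alignment(m, "DNA"))$rcfv, 0)
  b <- rbind(t1 = rep(c("A", "C"), c(6, 4)),
             t2 = rep(c("A", "C"), c(4, 6)))
  expect_equal(rcfv(new_alignment(b, "DNA"))$rcfv, 0.2,
               tolerance = 1e-12)
  set.seed(1)
  phy <- fixture_tree5()
  aln <- codon_to_nuc(simulate_codon_alignment(phy,
    sim_config(seed = 2, n_sites = 100)))
  r1 <- rcfv(aln)$rcfv
  perm <- new_alignment(aln$mat[sample(nrow(aln$mat)),
                                sample(ncol(aln$mat))], "DNA")
  expect_equal(rcfv(perm)$rcfv, r1, tolerance = 1e-12)
})

test_that("chi-square composition test: homogeneous counts give p = 1;
           toy deviation gives the closed-form statistic", {
  m <- rbind(A = rep(c("A", "C"), 50), B = rep(c("A", "C"), 50))
  r <- chi2_composition_test(new_alignment(m, "DNA"))
  expect_equal(r$statistic, c(0, 0))
  expect_equal(r$p, c(1, 1))
  m2 <- rbind(A = rep(c("A", "C"), c(90, 10)),
              B = rep(c("A", "C"), c(10, 90)))
  r2 <- chi2_composition_test(new_alignment(m2, "DNA"))
  expect_equal(r2$statistic[1], 64, tolerance = 1e-12)
  expect_equal(r2$df[1], 1) # zero-frequency states dropped
  expect_equal(r2$p[1], pchisq(64, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(r2$heterogeneous))
})

test_that("Bowker test: identical rows give statistic 0 / df 0 / p NA;
           single asymmetric pair gives 16/6; symmetric divergence
           gives p = 1", {
  m <- rbind(u = rep(c("A", "C", "G"), 10),
             v = rep(c("A", "C", "G"), 10))
  b <- bowker_pairwise_matrix(new_alignment(m, "DNA"))
  expect_equal(b$statistic["u", "v"], 0)
  expect_equal(b$df["u", "v"], 0)
  expect_true(is.na(b$p["u", "v"]))
  m2 <- rbind(u = c(rep("A", 5), "G", rep("C", 4)),
              v = c(rep("G", 5), "A", rep("C", 4)))
  b2 <- bowker_pairwise_matrix(new_alignment(m2, "DNA"))
  expect_equal(b2$statistic["u", "v"], 16 / 6, tolerance = 1e-12)
  expect_equal(b2$df["u", "v"], 1)
  m3 <- rbind(u = c(rep("A", 5), rep("G", 5), rep("C", 2)),
              v = c(rep("G", 5), rep("A", 5), rep("C", 2)))
  b3 <- bowker_pairwise_matrix(new_alignment(m3, "DNA"))
  expect_equal(b3$statistic["u", "v"], 0)
  expect_equal(b3$p["u", "v"], 1)
})

test_that("filter_genes applies each rule and reports reasons", {
  phy <- fixture_tree5()
  mk <- function(seed) codon_to_nuc(simulate_codon_alignment(
    phy, sim_config(seed = seed, n_sites = 150)))
  genes <- list(good1 = mk(1), good2 = mk(2), sparse = mk(3),
                biased = mk(4))
  genes$sparse <- corrupt_alignment(genes$sparse, 0.5, seed = 1)
  cb <- corrupt_alignment(simulate_codon_alignment(
    phy, sim_config(seed = 4, n_sites = 150)),
    bias_taxa = c("a", "b"), gc_shift = 30, seed = 2)
  genes$biased <- codon_to_nuc(cb)
  # thresholds disabled -> identity
  all_kept <- filter_genes(genes, min_completeness = NULL,
                           max_rcfv = NULL, chi2_alpha = NULL,
                           bowker_max_frac = NULL)
  expect_identical(names(all_kept$retained), names(genes))
  res <- filter_genes(genes, min_completeness = 0.7, max_rcfv = 0.025,
                      chi2_alpha = NULL, bowker_max_frac = NULL)
  rep <- res$report
  expect_true(rep$removed[rep$gene == "sparse"])
  expect_match(rep$reason[rep$gene == "sparse"], "completeness")
  expect_true(rep$removed[rep$gene == "biased"])
  expect_match(rep$reason[rep$gene == "biased"], "rcfv")
  expect_false(rep$removed[rep$gene == "good1"])
  expect_error(filter_genes(genes["sparse"], min_completeness = 0.9),
               "relax")
})

test_that("chi-square composition p-values are roughly uniform under a
           homogeneous simulation", {
  phy <- fixture_tree5()
  ps <- unlist(lapply(1:30, function(i) {
    a <- codon_to_nuc(simulate_codon_alignment(
      phy, sim_config(seed = 100 + i, n_sites = 120)))
    chi2_composition_test(a)$p
  }))
  expect_gt(mean(ps), 0.3) # uniform mean 0.5; heterogeneity would sink it
  expect_lt(mean(ps < 0.05), 0.12)
})
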