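# Codon branch models, selection scans, group means and 4D rates.

test_that("identical sequences give a flagged degenerate fit", {
  phy <- fixture_tree4()
  m <- matrix("ATG", 4, 40, dimnames = list(c("a", "b", "c", "d"), NULL))
  fit <- fit_branch_model(new_alignment(m, "CODON"), phy, "one_ratio")
  expect_equal(fit$flag, "no_variation")
  expect_true(all(is.na(fit$omega)))
  expect_equal(sum(fit$edge_len), 0)
})

test_that("alignments under 30 codons are rejected", {
  phy <- fixture_tree4()
  m <- matrix("ATG", 4, 10, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_error(fit_branch_model(new_alignment(m, "CODON"), phy),
               "30 codons")
})

test_that("foreground edge classes mark the clade and error on unknown
           tips", {
  phy <- fixture_tree5()
  cls <- foreground_edge_classes(phy, c("d", "e"))
  tp <- amphievo:::prep_phylo(phy)
  expect_equal(sum(cls), 3) # stem + two terminal edges
  stem_only <- foreground_edge_classes(phy, c("d", "e"), within = FALSE)
  expect_equal(sum(stem_only), 1)
  expect_error(foreground_edge_classes(phy, "zz"), "zz")
})

test_that("BH adjustment matches the textbook example and scan calls
           respect the direction condition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # direction: a gene with omega_fg < omega_bg is never an FEG
  res <- data.frame(p_adj = c(0.001, 0.001),
                    omega_fg = c(2, 0.1), omega_bg = c(0.2, 0.3))
  call <- ifelse(res$p_adj < 0.05 & res$omega_fg > res$omega_bg,
                 "FEG", "none")
  expect_equal(call, c("FEG", "none"))
})

test_that("group mean dN/dS excludes omega > 5 and warns on empty
           groups; elevated group detected by rank-sum", {
  rates <- data.frame(gene = "g", label = c("s1", "s2", "s3", "f1"),
                      omega = c(0.1, 0.3, 6.0, 0.2))
  gm <- group_mean_dnds(rates, c(s1 = "sal", s2 = "sal", s3 = "sal",
                                 f1 = "frog"))
  expect_equal(unname(gm$means["sal"]), 0.2)
  expect_equal(unname(gm$means["frog"]), 0.2)
  rates2 <- data.frame(label = c("x", "y"), omega = c(7, 0.2))
  expect_warning(
    gm2 <- group_mean_dnds(rates2, c(x = "gx", y = "gy")),
    "no surviving")
  expect_true(is.na(gm2$means["gx"]))
  expect_error(group_mean_dnds(rates, c(s1 = "sal")), "not mapped")
  set.seed(3)
  rr <- data.frame(label = c(rep("hi", 60), rep("lo", 60)),
                   omega = c(rlnorm(60, log(0.6), 0.4),
                             rlnorm(60, log(0.2), 0.4)))
  gmap <- c(hi = "HI", lo = "LO")
  g3 <- group_mean_dnds(rr, gmap)
  expect_lt(g3$wilcoxon["HI", "LO"], 0.05)
})

test_that("two-taxon codon fit matches the closed-form pairwise
           likelihood at its own MLEs", {
  phy <- ape::read.tree(text = "(x:0.1,y:0.1);")
  aln <- simulate_codon_alignment(phy, sim_config(seed = 6, n_sites = 120,
                                                  omega = c(bg = 0.4)))
  fit <- fit_branch_model(aln, phy, "one_ratio", passes = 2)
  pi <- fit$pi
  Q <- build_codon_Q(fit$kappa, fit$omega, pi)
  P <- as.matrix(Matrix::expm(Q * sum(fit$edge_len)))
  codons <- sense_codons()
  ref <- sum(log(pi[match(aln$mat[1, ], codons)] *
                 P[cbind(match(aln$mat[1, ], codons),
                         match(aln$mat[2, ], codons))]))
  expect_equal(fit$loglik, ref, tolerance = 1e-6)
})

test_that("free-ratio fit reports per-branch omega and dN/dS identities
           hold", {
  phy <- fixture_tree4()
  aln <- simulate_codon_alignment(phy, sim_config(seed = 10,
                                                  n_sites = 200))
  fit <- fit_branch_model(aln, phy, "free_ratio", passes = 2)
  br <- fit$branch_rates
  ok <- br$dS > 1e-8
  expect_equal(br$omega[ok], br$dN[ok] / br$dS[ok], tolerance = 1e-6)
  expect_true(all(br$dN >= 0 & br$dS >= 0))
})

test_that("4D site extraction and rates behave", {
  phy <- fixture_tree4()
  aln <- simulate_codon_alignment(phy, sim_config(seed = 3,
                                                  n_sites = 400))
  r <- fourfold_rates(aln, phy, min_sites = 10)
  expect_true(all(r$rates$rate >= 0))
  expect_gt(r$n_sites, 10)
  # a column set that cannot qualify
  m <- matrix("ATG", 4, 40, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_error(fourfold_rates(new_alignment(m, "CODON"), phy),
               "no 4-fold")
})

test_that("psg LRT statistic is clamped non-negative and the alternative
           never undercuts the null", {
  phy <- fixture_tree4()
  g <- list(simulate_codon_alignment(phy, sim_config(seed = 21,
                                                     n_sites = 60)))
  res <- psg_scan(g, phy, "a", passes = 1)
  expect_gte(res$lrt, 0)
  expect_gte(res$loglik_alt, res$loglik_null - 1e-6)
  expect_true(res$p >= 0 && res$p <= 1)
})
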