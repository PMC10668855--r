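# Fixed-topology fits, AU test, GAC and MP-EST supertrees.

test_that("two identical sequences drive the branch length to zero and
           the log-likelihood to the base-frequency sum", {
  phy <- ape::read.tree(text = "(p:0.1,q:0.1);")
  m <- rbind(p = c("A", "C", "G", "T", "A"),
             q = c("A", "C", "G", "T", "A"))
  fit <- fit_fixed_topology(new_alignment(m, "DNA"), phy, gamma = FALSE,
                            passes = 2)
  expect_lt(sum(fit$edge_len), 1e-4)
  expect_equal(fit$loglik, sum(log(fit$pi[c(1, 2, 3, 4, 1)])),
               tolerance = 1e-3)
})

test_that("fixed-parameter 3-taxon likelihood equals brute-force
           enumeration", {
  phy <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,c:0.3);")
  pi <- c(0.3, 0.2, 0.3, 0.2)
  rates <- c(1, 3, 1, 1, 3, 1)
  set.seed(4)
  m <- matrix(sample(c("A", "C", "G", "T"), 3 * 6, TRUE), 3, 6,
              dimnames = list(c("a", "b", "c"), NULL))
  # fix everything, keep the given branch lengths out of the optimizer by
  # evaluating via the engine directly
  Q <- build_gtr_Q(rates, pi)
  tp <- amphievo:::prep_phylo(phy, rownames(m))
  tips <- amphievo:::tip_partials(
    new_alignment(m[tp$tip.label, , drop = FALSE], "DNA"),
    c("A", "C", "G", "T"))
  eQ <- eigen_Q(Q, pi)
  ll <- amphievo:::model_pattern_loglik(
    tp, tips, pi, rep(list(eQ), nrow(tp$edge)), tp$edge.length)
  for (s in seq_len(ncol(m)))
    expect_equal(ll[s],
                 log(enum_site_lik(phy, m[, s], Q, pi,
                                   c("A", "C", "G", "T"))),
                 tolerance = 1e-8)
})

test_that("AU test: identical vectors get identical p-values (with a
           warning) and a dominant topology is never the most rejected", {
  set.seed(1)
  base <- rnorm(200, -3, 0.5)
  m <- rbind(T1 = base, T2 = base, T3 = base - 0.05)
  expect_warning(p <- au_test(m, n_boot = 500, seed = 2), "identical")
  expect_equal(unname(p["T1"]), unname(p["T2"]), tolerance = 1e-12)
  m2 <- rbind(best = rnorm(200, -3, 0.3),
              worse = rnorm(200, -3.4, 0.3),
              worst = rnorm(200, -3.8, 0.3))
  p2 <- au_test(m2, n_boot = 1000, seed = 3)
  expect_gte(p2["best"], max(p2[c("worse", "worst")]))
  # invariance to site order
  perm <- sample(ncol(m2))
  p3 <- au_test(m2[, perm], n_boot = 1000, seed = 3)
  expect_equal(p2, p3, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hypothesis support counts respect the alpha boundaries", {
  set.seed(2)
  genes <- lapply(1:4, function(i)
    rbind(H1 = rnorm(100, -2.9, 0.4), H2 = rnorm(100, -3.6, 0.4)))
  hs <- hypothesis_support_counts(genes, alpha = 0, n_boot = 300,
                                  seed = 1)
  expect_equal(unname(hs$counts), c(4, 4)) # every p >= 0
  hs2 <- hypothesis_support_counts(genes, alpha = 1.000001,
                                   n_boot = 300, seed = 1)
  expect_equal(unname(hs2$counts), c(0, 0))
  expect_error(hypothesis_support_counts(
    list(genes[[1]], genes[[2]][1, , drop = FALSE])), "gene 2")
})

test_that("Sankoff step-matrix score equals brute-force enumeration on
           4 taxa", {
  taxa <- c("a", "b", "c", "d")
  g1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  g2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  steps <- array(0, c(4, 4, 2))
  steps[, , 1] <- gac_step_matrix(g1, taxa)
  steps[, , 2] <- gac_step_matrix(g2, taxa)
  cand <- ape::read.tree(text = "((a,b),(c,d));")
  mine <- sankoff_scores(cand, taxa, steps)
  for (g in 1:2)
    expect_equal(mine[g],
                 enum_sankoff(cand, seq_len(4), steps[, , g]))
})

test_that("GAC: identical gene trees recover their own topology", {
  gt <- replicate(20, ape::read.tree(
    text = "((a:1,b:1):1,((c:1,d:1):1,e:1):1);"), simplify = FALSE)
  res <- gac_supertree(gt)
  ref <- ape::unroot(gt[[1]])
  expect_true(ape::all.equal.phylo(res$tree, ref,
                                   use.edge.length = FALSE))
  expect_error(gac_supertree(list(ape::read.tree(text = "(a:1,b:1);"))),
               "3 shared")
})

test_that("MP-EST: triplet probabilities are exact at t = 0, the
           estimate hits the cap under full concordance, and t = 0.5 is
           recovered from 1000 draws", {
  expect_equal(triplet_probs(0), rep(1 / 3, 3))
  sp <- ape::read.tree(text = "((a:1,b:1):0.5,c:1.5);")
  # full concordance -> t at the cap
  gtc <- replicate(50, ape::read.tree(text = "((a:1,b:1):1,c:2);"),
                   simplify = FALSE)
  fitc <- mpest_fit(gtc, sp)
  expect_equal(unname(fitc$branch_lengths), 10, tolerance = 1e-4)
  # t = 0.5 recovery
  gt <- simulate_gene_trees(sp, 1000, seed = 7)
  fit <- mpest_fit(gt, sp)
  expect_equal(unname(fit$branch_lengths), 0.5, tolerance = 0.1)
  # unrooted gene trees are rejected
  ur <- lapply(gt[1:3], ape::unroot)
  expect_error(mpest_fit(ur, sp), "rooted")
})

test_that("data simulated on one topology favors it in likelihood", {
  H <- list(
    H1 = ape::read.tree(text = "((a,b),(d,e),c);"),
    H2 = ape::read.tree(text = "((a,c),(b,d),e);"),
    H3 = ape::read.tree(text = "((a,d),(b,c),e);"))
  sim <- fixture_tree5() # ((a,b),(c,(d,e))) backbone: H1-compatible
  wins <- 0
  for (i in 1:10) {
    aln <- codon_to_nuc(simulate_codon_alignment(
      sim, sim_config(seed = 40 + i, n_sites = 120)))
    m <- site_loglik_matrix(aln, H, gamma = FALSE, passes = 2)
    if (which.max(attr(m, "loglik")) == 1) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
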