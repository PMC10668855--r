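# Synthetic-data generators.

test_that("zero-length branches copy the root draw to every tip and the
           same seed reproduces byte-identical alignments", {
  phy <- fixture_tree5()
  phy$edge.length[] <- 0
  cfg <- sim_config(seed = 3, n_sites = 50)
  a <- simulate_codon_alignment(phy, cfg)
  expect_true(all(apply(a$mat, 2, function(col) length(unique(col)) == 1)))
  b <- simulate_codon_alignment(phy, cfg)
  expect_identical(a$mat, b$mat)
  p <- simulate_protein_alignment(phy, cfg)
  expect_true(all(apply(p$mat, 2, function(col) length(unique(col)) == 1)))
})

test_that("unknown branch class errors naming the branch", {
  phy <- fixture_tree5()
  phy$edge.class <- rep("mystery", nrow(phy$edge))
  expect_error(simulate_codon_alignment(phy, sim_config(seed = 1)),
               "mystery")
})

test_that("planted parallel substitutions appear exactly where specified", {
  tr <- fixture_rooted6()
  cfg <- sim_config(seed = 8, n_sites = 30, planted = list(
    list(site = 10, clades = list(c("sal1", "sal2"), "anole"),
         anc = "V", derived = "L")))
  a <- simulate_protein_alignment(tr, cfg)
  expect_equal(unname(a$mat[c("sal1", "sal2", "anole"), 10]),
               rep("L", 3))
  expect_equal(unname(a$mat[c("frog", "out"), 10]), rep("V", 2))
  cfg$planted[[1]]$derived <- "V"
  expect_error(simulate_protein_alignment(tr, cfg), "ancestral")
})

test_that("large alpha kills site-rate variation in realized event
           counts", {
  tr <- fixture_rooted6()
  lo <- simulate_protein_alignment(tr, sim_config(seed = 4, n_sites = 400,
                                                  alpha = 0.3),
                                   track_events = TRUE)
  hi <- simulate_protein_alignment(tr, sim_config(seed = 4, n_sites = 400,
                                                  alpha = 200),
                                   track_events = TRUE)
  vlo <- var(colSums(attr(lo, "events")))
  vhi <- var(colSums(attr(hi, "events")))
  expect_lt(vhi, vlo)
  # near-homogeneous rates: variance close to Poisson (mean)
  cs <- colSums(attr(hi, "events"))
  expect_lt(var(cs) / mean(cs), 1.5)
})

test_that("realized per-branch event counts match t*L expectation", {
  tr <- read.tree(text = "((a:0.2,b:0.1):0.1,c:0.3);")
  L <- 10000
  a <- simulate_protein_alignment(tr, sim_config(seed = 6, n_sites = L,
                                                 alpha = 1e6),
                                  track_events = TRUE)
  ev <- rowSums(attr(a, "events"))
  tp <- amphievo:::prep_phylo(tr)
  expe <- tp$edge.length * L
  # 3 standard errors of a Poisson count
  expect_true(all(abs(ev - expe) <= 3 * sqrt(expe) + 1))
})

test_that("MSC gene-tree triplet frequencies match the closed form", {
  # long internal branch: almost always concordant
  sp <- read.tree(text = "((a:1,b:1):10,c:11);")
  gt <- simulate_gene_trees(sp, 300, seed = 2)
  tc <- triplet_counts(gt)
  expect_gte(tc$counts[1, "ab"] / 300, 0.99)
  # star tree: all three topologies equally likely
  sp0 <- read.tree(text = "((a:1,b:1):0.0001,c:1.0001);")
  gt0 <- simulate_gene_trees(sp0, 600, seed = 3)
  tc0 <- triplet_counts(gt0)
  expect_true(all(abs(tc0$counts / 600 - 1 / 3) < 0.08))
  # determinism
  gt2 <- simulate_gene_trees(sp, 5, seed = 11)
  gt3 <- simulate_gene_trees(sp, 5, seed = 11)
  expect_identical(lapply(gt2, ape::write.tree),
                   lapply(gt3, ape::write.tree))
  expect_error(simulate_gene_trees({
    s <- sp; s$edge.length[1] <- -1; s
  }, 2, 1), "negative")
})

test_that("corrupt_alignment: exact missing fraction, identity at zero,
           and RCFV increase under GC bias", {
  phy <- fixture_tree5()
  aln <- simulate_codon_alignment(phy, sim_config(seed = 5, n_sites = 1000))
  expect_identical(corrupt_alignment(aln, 0)$mat, aln$mat)
  cr <- corrupt_alignment(aln, missing_frac = 0.5, seed = 2)
  expect_equal(completeness_score(cr)$overall, 0.5, tolerance = 0.01)
  gc <- corrupt_alignment(aln, bias_taxa = c("a", "b"), gc_shift = 4,
                          seed = 3)
  expect_gt(rcfv(codon_to_nuc(gc))$rcfv, rcfv(codon_to_nuc(aln))$rcfv)
  expect_error(corrupt_alignment(aln, bias_taxa = "nope", gc_shift = 1),
               "not in alignment")
})

test_that("alignment round-trips through FASTA and trees through newick", {
  phy <- fixture_tree5()
  aln <- simulate_codon_alignment(phy, sim_config(seed = 9, n_sites = 20))
  aln2 <- corrupt_alignment(aln, 0.1, seed = 1)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(aln2, fa)
  back <- read_alignment(fa, "CODON")
  expect_identical(back$mat, aln2$mat)
  prot <- simulate_protein_alignment(phy, sim_config(seed = 9,
                                                     n_sites = 25))
  fa2 <- tempfile(fileext = ".fasta")
  write_alignment(prot, fa2)
  expect_identical(read_alignment(fa2, "AA")$mat, prot$mat)
  nw <- tempfile(fileext = ".nwk")
  ape::write.tree(phy, nw)
  expect_equal(ape::read.tree(nw)$tip.label, phy$tip.label)
})

test_that("qPCR generator encodes fold-changes in delta-Ct exactly at
           zero noise", {
  truth <- data.frame(gene = "G1", time = c(0, 5),
                      fold = c(1, 0.125))
  ct <- make_qpcr_table(truth, noise_sd = 0, seed = 1)
  rq <- relative_quantification(ct)
  expect_equal(rq$ddct[rq$time == 5], 3)
  expect_equal(rq$rq[rq$time == 5], 0.125)
  expect_equal(rq$rq[rq$time == 0], 1)
  expect_warning(make_qpcr_table(truth, bio_reps = 1, noise_sd = 0),
                 "replicates")
})
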