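# Ancestral reconstruction and parallel/common substitution analysis.

test_that("reconstruction of an invariant column is confident and a
           4-taxon marginal matches enumeration", {
  tr <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1):0;")
  m <- rbind(a = c("V", "V"), b = c("V", "L"),
             c = c("V", "V"), d = c("V", "V"))
  aln <- new_alignment(m, "AA")
  rec <- ancestral_reconstruct(aln, tr, alpha = 1, k = 1)
  # invariant column: all internal nodes V with high posterior
  expect_true(all(rec$map[5:7, 1] == "V"))
  expect_true(all(rec$posterior[5:7, 1] > 0.99))
  # enumeration oracle for the marginal at the root, site 2
  mod <- aa_model("JTT")
  phy <- reorder(tr, "postorder")
  num <- vapply(seq_len(20), function(s) {
    # joint prob of data with root fixed at s, summing the other internal
    # node states: enumerate by conditioning
    tot <- 0
    for (s2 in 1:20) for (s3 in 1:20) {
      P <- function(t) as.matrix(Matrix::expm(mod$Q * t))
      P1 <- P(0.1)
      # tree: root(s) -> in1(s2){a,b}, in2(s3){c,d}
      tot <- tot + P1[s, s2] * P1[s, s3] *
        P1[s2, match("V", mod$states)] * P1[s2, match("L", mod$states)] *
        P1[s3, match("V", mod$states)] * P1[s3, match("V", mod$states)]
    }
    mod$pi[s] * tot
  }, numeric(1))
  post_ref <- num / sum(num)
  root <- 5 # ape root number for 4 tips
  expect_equal(rec$map[root, 2],
               mod$states[which.max(post_ref)])
  expect_equal(rec$posterior[root, 2], max(post_ref), tolerance = 1e-6)
  expect_error(ancestral_reconstruct(aln, ape::unroot(tr)), "rooted")
})

test_that("planted group-stem changes are recovered and non-shared
           changes are not", {
  tr <- fixture_rooted6()
  cfg <- sim_config(seed = 12, n_sites = 120, planted = list(
    list(site = 50, clades = list(c("sal1", "sal2")),
         anc = "V", derived = "L")))
  aln <- simulate_protein_alignment(tr, cfg)
  rec <- ancestral_reconstruct(aln, tr, alpha = 1, k = 4)
  ch <- group_shared_changes(aln, rec, c("sal1", "sal2"))
  hit <- ch[ch$site == 50, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ancestral, "V")
  expect_equal(hit$derived, "L")
  # a site where one member is derived and the other ancestral: no record
  aln$mat["sal1", 60] <- "W"; aln$mat["sal2", 60] <- "A"
  rec2 <- ancestral_reconstruct(aln, tr, alpha = 1, k = 4)
  ch2 <- group_shared_changes(aln, rec2, c("sal1", "sal2"))
  expect_false(60 %in% ch2$site)
  # constant alignment yields an empty list
  cm <- matrix("M", 5, 20,
               dimnames = list(tr$tip.label, NULL))
  recc <- ancestral_reconstruct(new_alignment(cm, "AA"), tr)
  expect_equal(nrow(group_shared_changes(new_alignment(cm, "AA"), recc,
                                         c("sal1", "sal2"))), 0)
  # non-monophyletic group is rejected
  expect_error(group_shared_changes(aln, rec, c("sal1", "frog")),
               "monophyletic")
})

test_that("classification reproduces the published salamander/lizard and
           salamander/bat/mole-rat patterns", {
  # OGFR-style: V190L & V190L parallel; P231K vs P231R common
  sal <- data.frame(site = c(190, 231), branch = "sal",
                    ancestral = c("V", "P"), derived = c("L", "K"),
                    posterior = 1)
  anole <- data.frame(site = c(190, 231), branch = "anole",
                      ancestral = c("V", "P"), derived = c("L", "R"),
                      posterior = 1)
  calls <- classify_pairwise_changes(sal, anole)
  expect_equal(calls$class[calls$site == 190], "parallel")
  expect_equal(calls$class[calls$site == 231], "common")
  # PTGES2-style: E183A vs E183D common
  s2 <- data.frame(site = 183, branch = "sal", ancestral = "E",
                   derived = "A", posterior = 1)
  nmr <- data.frame(site = 183, branch = "nmr", ancestral = "E",
                    derived = "D", posterior = 1)
  expect_equal(classify_pairwise_changes(s2, nmr)$class, "common")
  # SIRT1-style: K375R & K375R parallel
  s3 <- data.frame(site = 375, branch = "sal", ancestral = "K",
                   derived = "R", posterior = 1)
  n3 <- data.frame(site = 375, branch = "nmr", ancestral = "K",
                   derived = "R", posterior = 1)
  expect_equal(classify_pairwise_changes(s3, n3)$class, "parallel")
  # same derived from different ancestors: excluded, with a reason
  s4 <- data.frame(site = 7, branch = "x", ancestral = "A",
                   derived = "S", posterior = 1)
  n4 <- data.frame(site = 7, branch = "y", ancestral = "T",
                   derived = "S", posterior = 1)
  out <- classify_pairwise_changes(s4, n4)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "excluded")$site, 7)
})

test_that("null parallel probability: trivial cases and Poisson
           monotonicity", {
  r0 <- parallel_null_probability(0, 10, 100, 0)
  expect_equal(r0$expected, 0)
  expect_equal(r0$p, 1)
  ru <- parallel_null_probability(10, 10, 100, 0, model = "uniform")
  expect_equal(ru$expected, 10 * 10 / 100 / 19, tolerance = 1e-12)
  ps <- vapply(0:5, function(k)
    parallel_null_probability(10, 10, 100, k, model = "uniform")$p,
    numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(
    rz <- parallel_null_probability(0, 0, 10, 2), "misfit")
  expect_equal(rz$p, 0)
})

test_that("exclusive-pair site filter drops sites with changes on other
           branches", {
  tr <- fixture_rooted6()
  cfg <- sim_config(seed = 19, n_sites = 80)
  aln <- simulate_protein_alignment(tr, cfg)
  # plant an unmistakable frog-only change at site 5 on an otherwise
  # constant column
  aln$mat[, 5] <- "M"; aln$mat["frog", 5] <- "W"
  rec <- ancestral_reconstruct(aln, tr, alpha = 1, k = 4)
  keep <- exclusive_pair_sites(rec, list(c("sal1", "sal2"), "anole"))
  expect_false(5 %in% keep)
})

test_that("reconstruction accuracy and planting round-trip meet the
           stated rates (scaled replicates)", {
  tr <- fixture_rooted6() # total length ~1.35
  mod <- aa_model("JTT")
  # accuracy of MAP states vs simulated truth, 500 sites
  aln <- simulate_protein_alignment(tr, sim_config(seed = 31,
                                                   n_sites = 500,
                                                   alpha = 1))
  truth <- attr(aln, "node_states")
  rec <- ancestral_reconstruct(aln, attr(aln, "tree"), alpha = 1, k = 4)
  internal <- (length(tr$tip.label) + 1):nrow(truth)
  acc <- mean(rec$map[internal, ] ==
                matrix(mod$states[truth[internal, ]],
                       length(internal)))
  expect_gte(acc, 0.90)
  # planted stem changes recovered at threshold 0.7 (5 x 200 sites)
  hits <- vapply(1:5, function(r) {
    cfg <- sim_config(seed = 40 + r, n_sites = 200, planted = list(
      list(site = 100, clades = list(c("sal1", "sal2")),
           anc = "A", derived = "T")))
    a <- simulate_protein_alignment(tr, cfg)
    rc <- ancestral_reconstruct(a, tr, alpha = 1, k = 4)
    ch <- group_shared_changes(a, rc, c("sal1", "sal2"),
                               threshold = 0.7)
    any(ch$site == 100 & ch$ancestral == "A" & ch$derived == "T")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
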