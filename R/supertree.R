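# Supertree construction from gene trees: "genes as characters" (GAC)
# step-matrix parsimony scored by Sankoff dynamic programming, and
# MP-EST-style multispecies-coalescent triplet pseudo-likelihood.

#' Step matrix of a gene tree (nodal distances)
#'
#' Each gene is one multistate character whose states are the taxa; the
#' cost of changing state a -> b is the number of edges between tips a and
#' b in the gene tree.
#'
#' @param gene_tree `phylo`
#' @param taxa taxon order for the matrix
#' @return taxa x taxa integer matrix of nodal distances
#' @export
gac_step_matrix <- function(gene_tree, taxa) {
  stopifnot(all(taxa %in% gene_tree$tip.label))
  tr <- ape::keep.tip(gene_tree, taxa)
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- stats::cophenetic(tr)[taxa, taxa]
  D
}

# Sankoff minimum cost of one topology for all genes at once.
#   steps: k x k x G array of per-gene step matrices (state order = taxa)
# Tip i has its own state with cost 0.  Returns numeric(G) of minima.
sankoff_scores <- function(topology, taxa, steps) {
  tp <- prep_phylo(topology)
  stopifnot(setequal(tp$tip.label, taxa))
  k <- length(taxa); G <- dim(steps)[3]
  BIG <- 1e9
  cost <- vector("list", tp$ntip + tp$nnode)
  for (i in seq_len(tp$ntip)) {
    C <- matrix(BIG, k, G)
    C[match(tp$tip.label[i], taxa), ] <- 0
    cost[[i]] <- C
  }
  E <- tp$edge
  for (e in seq_len(nrow(E))) {
    par <- E[e, 1]; ch <- E[e, 2]
    Cc <- cost[[ch]]
    M <- matrix(BIG, k, G)
    for (s in seq_len(k)) {
      # min_t steps[s, t, g] + Cc[t, g], vectorized over genes
      tmp <- steps[s, , ] + Cc # k x G (recycling ok: both k x G)
      M[s, ] <- do.call(pmin, lapply(seq_len(k), function(t) tmp[t, ]))
    }
    cost[[par]] <- if (is.null(cost[[par]])) M else cost[[par]] + M
  }
  Cr <- cost[[tp$root]]
  do.call(pmin, lapply(seq_len(k), function(s) Cr[s, ]))
}

newick_key <- function(phy) {
  ape::write.tree(ape::rotateConstr(phy, sort(phy$tip.label)))
}

# candidate unrooted topologies: exhaustive for <= 7 taxa, else NNI
# hill-climb from a majority-rule consensus start
gac_candidates <- function(taxa) {
  phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
}

#' GAC supertree by step-matrix parsimony
#'
#' Scores candidate species topologies by the Sankoff minimum over all
#' gene characters (equal weights) and returns the minimum-score tree.
#' Search is exhaustive for <= 7 taxa, otherwise NNI hill-climbing from a
#' majority-rule consensus of the gene trees.  Ties are broken by
#' lexicographic Newick order.  Bootstrap support is computed by
#' resampling genes.
#'
#' @param gene_trees list of `phylo` (pruned to their shared taxa)
#' @param n_boot gene-resampling bootstrap replicates (0 disables)
#' @param seed RNG seed for the bootstrap
#' @return list with `tree` (unrooted `phylo`), `score`, `support`
#'   (bootstrap proportion of replicates recovering each internal split;
#'   NULL when n_boot = 0)
#' @export
gac_supertree <- function(gene_trees, n_boot = 0, seed = 1) {
  taxa <- Reduce(intersect, lapply(gene_trees, `[[`, "tip.label"))
  if (length(taxa) < 3) stop("fewer than 3 shared taxa")
  taxa <- sort(taxa)
  k <- length(taxa); G <- length(gene_trees)
  steps <- array(0, c(k, k, G))
  for (g in seq_len(G))
    steps[, , g] <- gac_step_matrix(gene_trees[[g]], taxa)
  best_of <- function(gene_idx) {
    S <- steps[, , gene_idx, drop = FALSE]
    if (k <= 7) {
      cands <- gac_candidates(taxa)
      sc <- vapply(cands, function(tr)
        sum(sankoff_scores(tr, taxa, S)), numeric(1))
      mn <- min(sc)
      tied <- which(sc <= mn + 1e-9)
      if (length(tied) > 1) {
        keys <- vapply(cands[tied], newick_key, character(1))
        tied <- tied[order(keys)][1]
      }
      list(tree = cands[[tied[1]]], score = mn)
    } else {
      cur <- ape::unroot(ape::consensus(gene_trees, p = 0.5,
                                        check.labels = TRUE))
      cur <- ape::multi2di(cur)
      cur_sc <- sum(sankoff_scores(cur, taxa, S))
      repeat {
        nb <- phangorn::nni(cur)
        sc <- vapply(nb, function(tr)
          sum(sankoff_scores(tr, taxa, S)), numeric(1))
        if (min(sc) < cur_sc - 1e-9) {
          tied <- which(sc <= min(sc) + 1e-9)
          if (length(tied) > 1) {
            keys <- vapply(nb[tied], newick_key, character(1))
            tied <- tied[order(keys)][1]
          }
          cur <- nb[[tied[1]]]; cur_sc <- min(sc)
        } else break
      }
      list(tree = cur, score = cur_sc)
    }
  }
  main <- best_of(seq_len(G))
  support <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    reps <- lapply(seq_len(n_boot), function(b)
      best_of(sample.int(G, G, replace = TRUE))$tree)
    pp <- ape::prop.part(c(list(main$tree), reps))
    support <- ape::prop.clades(main$tree, part = pp) / (n_boot + 1)
  }
  list(tree = main$tree, score = main$score, support = support)
}

# ---- MP-EST-style triplet pseudo-likelihood ------------------------------

#' Rooted-triplet topology counts from gene trees
#'
#' @param gene_trees list of rooted `phylo`
#' @param taxa taxa to use (default: shared set)
#' @return list: `triples` (matrix of taxon triples, rows sorted) and
#'   `counts` (rows matching `triples`; columns = which pair is the
#'   cherry: ab, ac, bc)
#' @export
triplet_counts <- function(gene_trees, taxa = NULL) {
  if (is.null(taxa))
    taxa <- Reduce(intersect, lapply(gene_trees, `[[`, "tip.label"))
  taxa <- sort(taxa)
  if (length(taxa) < 3) stop("fewer than 3 shared taxa")
  trip <- t(utils::combn(taxa, 3))
  counts <- matrix(0L, nrow(trip), 3,
                   dimnames = list(NULL, c("ab", "ac", "bc")))
  for (g in gene_trees) {
    if (!ape::is.rooted(g))
      stop("gene trees must be rooted (define an outgroup)")
    ch <- cherry_of_triples(g, trip)
    for (r in seq_len(nrow(trip)))
      if (!is.na(ch[r])) counts[r, ch[r]] <- counts[r, ch[r]] + 1L
  }
  list(triples = trip, counts = counts)
}

# which pair of each triple is the cherry in rooted tree g: the pair whose
# MRCA is not the triple's overall MRCA (strictly deeper)
cherry_of_triples <- function(g, trip) {
  M <- ape::mrca(g)
  ntip <- length(g$tip.label)
  dep <- node_depths(g)
  apply(trip, 1, function(tx) {
    i <- match(tx, g$tip.label)
    mab <- M[i[1], i[2]]; mac <- M[i[1], i[3]]; mbc <- M[i[2], i[3]]
    d <- c(dep[mab], dep[mac], dep[mbc])
    top <- which.max(d)
    if (sum(d == max(d)) > 1) return(NA_integer_) # polytomy
    top
  })
}

node_depths <- function(phy) {
  tp <- prep_phylo(phy)
  dep <- numeric(tp$ntip + tp$nnode)
  E <- tp$edge
  for (k in rev(seq_len(nrow(E)))) dep[E[k, 2]] <- dep[E[k, 1]] + 1
  dep
}

#' MP-EST pseudo-likelihood fit for a rooted species topology
#'
#' Each taxon triple's rooted-triplet counts are scored by the
#' multispecies-coalescent trinomial: the concordant topology has
#' probability 1 - (2/3) exp(-T), each discordant (1/3) exp(-T), where T
#' is the summed length (coalescent units) of the internal branches
#' separating the triple's two coalescence nodes.  Internal branch
#' lengths are optimized numerically (capped at `t_max`).
#'
#' @param gene_trees list of rooted `phylo`, or a precomputed
#'   [triplet_counts()] result
#' @param species_topology rooted `phylo`
#' @param t_max upper bound on branch lengths in coalescent units
#'   (default 10; estimates at the bound indicate no observed discordance)
#' @return list with `pseudo_loglik`, `branch_lengths` (per internal
#'   edge, coalescent units), `tree` (species topology with internal
#'   branch lengths set)
#' @export
mpest_fit <- function(gene_trees, species_topology, t_max = 10) {
  tc <- if (is.list(gene_trees) && !is.null(gene_trees$counts))
    gene_trees else triplet_counts(gene_trees)
  stopifnot(ape::is.rooted(species_topology))
  tp <- prep_phylo(species_topology)
  E <- tp$edge
  internal <- which(E[, 2] > tp$ntip)
  M <- ape::mrca(tp$phy)
  dep <- node_depths(tp$phy)
  # map each triple to (concordant column, internal edges on the path)
  path_edges <- function(n1, n2) { # n2 an ancestor of n1
    out <- integer(0)
    while (n1 != n2) {
      k <- which(E[, 2] == n1)
      out <- c(out, k)
      n1 <- E[k, 1]
    }
    out
  }
  maps <- lapply(seq_len(nrow(tc$triples)), function(r) {
    tx <- tc$triples[r, ]
    i <- match(tx, tp$tip.label)
    mab <- M[i[1], i[2]]; mac <- M[i[1], i[3]]; mbc <- M[i[2], i[3]]
    d <- c(dep[mab], dep[mac], dep[mbc])
    conc <- which.max(d)
    lower <- c(mab, mac, mbc)[conc]
    upper <- c(mab, mac, mbc)[-conc][1] # triple MRCA
    ed <- intersect(path_edges(lower, upper), internal)
    list(conc = conc, edges = ed)
  })
  npar <- length(internal)
  idx <- stats::setNames(seq_len(npar), internal)
  obj <- function(tv) {
    ll <- 0
    for (r in seq_along(maps)) {
      mp <- maps[[r]]
      Tt <- sum(tv[idx[as.character(mp$edges)]])
      pc <- 1 - (2 / 3) * exp(-Tt)
      pd <- (1 / 3) * exp(-Tt)
      n <- tc$counts[r, ]
      nc <- n[mp$conc]; nd <- sum(n) - nc
      ll <- ll + nc * log(max(pc, 1e-300)) + nd * log(max(pd, 1e-300))
    }
    -ll
  }
  o <- stats::optim(rep(1, npar), obj, method = "L-BFGS-B",
                    lower = 1e-6, upper = t_max)
  tr <- tp$phy
  tr$edge.length <- rep(0, nrow(E))
  tr$edge.length[internal] <- o$par
  list(pseudo_loglik = -o$value,
       branch_lengths = stats::setNames(o$par, internal),
       tree = tr)
}

#' MP-EST topology search (exhaustive over rooted topologies)
#'
#' @param gene_trees list of rooted `phylo`
#' @param t_max see [mpest_fit()]
#' @return list: `tree`, `pseudo_loglik` of the best rooted topology
#'   (<= 7 taxa only)
#' @export
mpest_search <- function(gene_trees, t_max = 10) {
  tc <- triplet_counts(gene_trees)
  taxa <- sort(unique(as.vector(tc$triples)))
  if (length(taxa) > 7) stop("exhaustive search limited to 7 taxa")
  cands <- phangorn::allTrees(length(taxa), rooted = TRUE,
                              tip.label = taxa)
  fits <- lapply(cands, function(tr) mpest_fit(tc, tr, t_max))
  lls <- vapply(fits, `[[`, numeric(1), "pseudo_loglik")
  best <- which(lls >= max(lls) - 1e-9)
  if (length(best) > 1) {
    keys <- vapply(cands[best], newick_key, character(1))
    best <- best[order(keys)]
  }
  list(tree = cands[[best[1]]], pseudo_loglik = lls[best[1]])
}

#' Closed-form rooted-triplet probabilities
#' @param t internal branch length in coalescent units
#' @return numeric(3): concordant, discordant, discordant
#' @export
triplet_probs <- function(t) {
  stopifnot(t >= 0)
  pd <- (1 / 3) * exp(-t)
  # concordant = 1/3 + (2/3)(1 - e^-t): exact 1/3 at t = 0
  c(1 / 3 + (2 / 3) * (1 - exp(-t)), pd, pd)
}
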