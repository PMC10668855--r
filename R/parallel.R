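# Ancestral amino-acid reconstruction and parallel/convergent substitution
# analysis: marginal posteriors by the up-down pruning algorithm,
# group-shared derived changes, parallel vs common classification of
# two-lineage coincidences, and Poisson chance probabilities.

#' Marginal ancestral reconstruction for amino-acid alignments
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over amino acids under an empirical model with
#' discrete-gamma rates, at the branch lengths carried by the tree.
#'
#' @param aln AA alignment
#' @param tree rooted `phylo` with branch lengths (expected
#'   substitutions/site)
#' @param model empirical model name (see [aa_model()])
#' @param alpha gamma shape; `Inf` or `k = 1` disables rate variation
#' @param k gamma categories (default 4)
#' @return list of class `anc_recon`: `map` (node x site MAP residues),
#'   `posterior` (node x site posterior of the MAP state), `tree`,
#'   `states`, `tip_labels`; node rows follow ape numbering
#'   (tips 1..n, root n+1, ...).  MAP ties are broken by one-letter-code
#'   order and counted in attribute `n_ties`.
#' @export
ancestral_reconstruct <- function(aln, tree, model = "JTT", alpha = 1,
                                  k = 4) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "AA")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  tp <- prep_phylo(tree, aln_taxa(aln))
  mod <- aa_model(model)
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  cp <- compress_patterns(m)
  tips <- tip_partials(new_alignment(m[, cp$cols, drop = FALSE], "AA"),
                       mod$states)
  rates <- if (k == 1 || !is.finite(alpha)) 1 else gamma_rates(alpha, k)
  w <- rep(1 / length(rates), length(rates))
  eQ <- eigen_Q(mod$Q, mod$pi)
  ne <- nrow(tp$edge)
  nn <- tp$ntip + tp$nnode
  npat <- length(cp$cols)
  post <- array(0, c(nn, 20, npat))
  site_l <- matrix(0, npat, length(rates))
  ref <- NULL
  for (ci in seq_along(rates)) {
    P <- lapply(seq_len(ne), function(e)
      prob_matrix(eQ, tp$edge.length[e] * rates[ci]))
    d <- engine_down(tp, tips, P, mod$pi)
    u <- engine_up(tp, d, P, mod$pi)
    site_l[, ci] <- d$pattern_loglik
    if (is.null(ref)) ref <- d$pattern_loglik
    for (v in (tp$ntip + 1):nn) {
      # joint marginal, rescaled by a per-site reference common to all
      # categories so category weights combine correctly
      J <- u$Fp[[v]] * d$part[[v]] # 20 x npat, joint up to scaling
      lsc <- u$flsc[[v]] + d$lsc[[v]]
      post[v, , ] <- post[v, , ] + t(t(J) * (w[ci] * exp(lsc - ref)))
    }
  }
  nsite <- ncol(m)
  map <- matrix(NA_character_, nn, nsite)
  pp <- matrix(NA_real_, nn, nsite)
  n_ties <- 0L
  for (v in (tp$ntip + 1):nn) {
    Pv <- post[v, , , drop = TRUE]
    if (npat == 1) Pv <- matrix(Pv, 20, 1)
    Pv <- t(t(Pv) / pmax(colSums(Pv), 1e-300))
    best <- apply(Pv, 2, function(col) {
      mb <- which(col >= max(col) - 1e-12)
      if (length(mb) > 1) n_ties <<- n_ties + 1L
      mb[order(mod$states[mb])][1]
    })
    map[v, ] <- mod$states[best][cp$index]
    pp[v, ] <- Pv[cbind(best, seq_len(npat))][cp$index]
  }
  for (i in seq_len(tp$ntip)) {
    map[i, ] <- m[i, ]
    pp[i, ] <- 1
  }
  structure(list(map = map, posterior = pp, tree = tp$phy,
                 states = mod$states, tip_labels = tp$tip.label),
            class = "anc_recon", n_ties = n_ties)
}

#' Amino-acid changes shared by all members of a group
#'
#' Emits a change record on the group's stem branch for every site where
#' all group members carry the same residue X, and the reconstruction of
#' the group MRCA's parent is a different residue Y with posterior at
#' least `threshold`.  Sites where any group member is missing are
#' skipped.
#'
#' @param aln AA alignment
#' @param rec [ancestral_reconstruct()] result for the same alignment/tree
#' @param group character vector of tip labels (monophyletic on the tree)
#' @param threshold minimum ancestral-state posterior (default 0.7)
#' @return data.frame (`change_record`): site, branch (label), ancestral,
#'   derived, posterior
#' @export
group_shared_changes <- function(aln, rec, group, threshold = 0.7) {
  stopifnot(inherits(rec, "anc_recon"))
  tp <- prep_phylo(rec$tree)
  miss <- setdiff(group, tp$tip.label)
  if (length(miss)) stop("group tips not in tree: ",
                         paste(miss, collapse = ", "))
  gi <- match(group, tp$tip.label)
  mrca <- if (length(gi) == 1) gi else
    ape::getMRCA(tp$phy, group)
  # monophyly check
  if (length(gi) > 1) {
    desc <- tips_below(tp, mrca)
    if (!setequal(tp$tip.label[desc], group))
      stop("group is not monophyletic on the tree")
  }
  stem <- which(tp$edge[, 2] == mrca)
  if (!length(stem)) stop("group spans the root; no stem branch")
  parent <- tp$edge[stem, 1]
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  out <- list()
  for (s in seq_len(ncol(m))) {
    obs <- m[gi, s]
    if (any(is.na(obs))) next
    ux <- unique(obs)
    if (length(ux) != 1) next
    anc <- rec$map[parent, s]
    pp <- rec$posterior[parent, s]
    if (!is.na(anc) && anc != ux && pp >= threshold)
      out[[length(out) + 1L]] <- data.frame(
        site = s, branch = paste(group, collapse = "+"),
        ancestral = anc, derived = ux, posterior = pp)
  }
  if (!length(out))
    return(data.frame(site = integer(0), branch = character(0),
                      ancestral = character(0), derived = character(0),
                      posterior = numeric(0)))
  do.call(rbind, out)
}

tips_below <- function(tp, node) {
  if (node <= tp$ntip) return(node)
  E <- tp$edge
  below <- vector("list", tp$ntip + tp$nnode)
  for (i in seq_len(tp$ntip)) below[[i]] <- i
  for (k in seq_len(nrow(E)))
    below[[E[k, 1]]] <- c(below[[E[k, 1]]], below[[E[k, 2]]])
  below[[node]]
}

#' Sites whose reconstructed changes are exclusive to two focal branches
#'
#' Scans the whole reconstruction for MAP-state changes (posterior of both
#' endpoint states >= threshold at internal nodes) and returns the sites
#' where changes occur on no branch other than the two focal lineages.
#'
#' @param rec [ancestral_reconstruct()] result
#' @param focal_branches list of two tip-label vectors (each a focal
#'   lineage: the stem of that clade, or a terminal branch for a single
#'   tip)
#' @param threshold posterior threshold for calling a change elsewhere
#' @return integer vector of site indices
#' @export
exclusive_pair_sites <- function(rec, focal_branches, threshold = 0.7) {
  tp <- prep_phylo(rec$tree)
  stem_edge <- function(tips) {
    node <- if (length(tips) == 1) match(tips, tp$tip.label)
            else ape::getMRCA(tp$phy, tips)
    which(tp$edge[, 2] == node)
  }
  focal <- vapply(focal_branches, stem_edge, integer(1))
  E <- tp$edge
  nsite <- ncol(rec$map)
  changed_elsewhere <- rep(FALSE, nsite)
  for (k in seq_len(nrow(E))) {
    if (k %in% focal) next
    a <- rec$map[E[k, 1], ]; b <- rec$map[E[k, 2], ]
    pa <- rec$posterior[E[k, 1], ]; pb <- rec$posterior[E[k, 2], ]
    chg <- !is.na(a) & !is.na(b) & a != b & pa >= threshold &
      pb >= threshold
    changed_elsewhere <- changed_elsewhere | chg
  }
  which(!changed_elsewhere)
}

#' Classify coincident changes on two lineages as parallel or common
#'
#' Joins two change-record tables by site.  A coincidence is "parallel"
#' when both lineages derived the same residue from the same ancestral
#' residue, "common" when the derived residues differ; coincidences with
#' equal derived residues but different ancestral residues are excluded
#' (returned in attribute `excluded`).
#'
#' @param changesA,changesB change records (see
#'   [group_shared_changes()]) for the two lineages
#' @param sites optional site whitelist (e.g. from
#'   [exclusive_pair_sites()])
#' @return data.frame (`parallel_call`): site, class, ancestral,
#'   derived_a, derived_b; attribute `excluded` lists dropped rows with a
#'   reason
#' @export
classify_pairwise_changes <- function(changesA, changesB, sites = NULL) {
  shared <- intersect(changesA$site, changesB$site)
  if (!is.null(sites)) shared <- intersect(shared, sites)
  rows <- list(); excl <- list()
  for (s in shared) {
    a <- changesA[changesA$site == s, ][1, ]
    b <- changesB[changesB$site == s, ][1, ]
    if (a$derived == b$derived) {
      if (a$ancestral == b$ancestral) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, class = "parallel", ancestral = a$ancestral,
          derived_a = a$derived, derived_b = b$derived)
      } else {
        excl[[length(excl) + 1L]] <- data.frame(
          site = s, reason = "same derived, different ancestral")
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, class = "common", ancestral = a$ancestral,
        derived_a = a$derived, derived_b = b$derived)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), class = character(0),
               ancestral = character(0), derived_a = character(0),
               derived_b = character(0))
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(site = integer(0), reason = character(0))
  out
}

# one-step substitution distribution given the ancestral residue, from an
# empirical model's rate matrix
one_step_probs <- function(model = "JTT") {
  mod <- aa_model(model)
  Q <- mod$Q
  diag(Q) <- 0
  Q / rowSums(Q)
}

#' Chance probability of observed parallel substitutions
#'
#' Under the null that `nA` and `nB` substitutions fall uniformly over
#' `L` sites, the expected number of parallel coincidences is
#' E = (nA * nB / L) * P(same derived residue), where the derived-residue
#' distribution conditions on the ancestral residue through the empirical
#' model's one-step probabilities ("model") or is uniform over the 19
#' alternatives ("uniform").  The p-value is the Poisson upper tail
#' P(X >= observed | E).
#'
#' @param nA,nB substitution counts on the two lineages
#' @param L number of sites
#' @param observed_parallel observed count of parallel coincidences
#' @param model `"model"` (empirical one-step, default) or `"uniform"`
#' @param ancestral optional character vector (length L) of ancestral
#'   residues per site; defaults to the model's stationary distribution
#' @param aa_model_name empirical model used for the one-step
#'   distribution
#' @return list with `expected`, `p`
#' @export
parallel_null_probability <- function(nA, nB, L, observed_parallel = 0,
                                      model = c("model", "uniform"),
                                      ancestral = NULL,
                                      aa_model_name = "JTT") {
  model <- match.arg(model)
  stopifnot(nA >= 0, nB >= 0, L > 0, observed_parallel >= 0)
  if (model == "uniform") {
    p_same_site <- rep(1 / 19, L)
  } else {
    OS <- one_step_probs(aa_model_name)
    p_same_by_anc <- rowSums(OS^2)
    mod <- aa_model(aa_model_name)
    p_same_site <- if (is.null(ancestral))
      rep(sum(mod$pi * p_same_by_anc), L)
    else {
      stopifnot(length(ancestral) == L)
      p_same_by_anc[match(ancestral, mod$states)]
    }
  }
  E <- sum((nA / L) * (nB / L) * p_same_site)
  if (E == 0 && observed_parallel > 0) {
    warning("expected count 0 with observed > 0: model misfit")
    return(list(expected = 0, p = 0))
  }
  p <- if (observed_parallel == 0) 1 else
    stats::ppois(observed_parallel - 1, E, lower.tail = FALSE)
  list(expected = E, p = p)
}
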