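# Shared Felsenstein-pruning engine used by the nucleotide, codon and
# amino-acid models.  Works on ape "phylo" trees reordered postorder, with
# per-pattern log-scaling to avoid underflow.  The up-down pass provides
# marginal ancestral posteriors and cheap single-branch likelihood curves
# for coordinate-wise branch-length optimization.

# Precompute traversal structure.  Trees are used as rooted at phylo's root
# node; for reversible models the likelihood does not depend on the root
# placement.
prep_phylo <- function(phy, taxa = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!is.null(taxa)) {
    if (!setequal(phy$tip.label, taxa))
      stop("tree leaf set does not match alignment taxa")
  }
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  list(phy = phy, edge = phy$edge, ntip = ntip,
       nnode = phy$Nnode, root = root,
       tip.label = phy$tip.label,
       edge.length = phy$edge.length)
}

# unique site patterns: returns list(index (pattern id per site), weight,
# cols (representative site per pattern))
compress_patterns <- function(mat) {
  key <- apply(mat, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                           collapse = "\r"))
  u <- !duplicated(key)
  pid <- match(key, key[u])
  list(index = pid, weight = as.numeric(table(factor(pid,
      levels = seq_len(sum(u))))), cols = which(u))
}

# Postorder (down) pass.
#   tips: list (by tip number) of states x npat indicator matrices
#   P: list (by edge row) of transition matrices
# Returns node partials, per-node log-scale vectors, per-pattern loglik.
engine_down <- function(tp, tips, P, pi) {
  nn <- tp$ntip + tp$nnode
  part <- vector("list", nn)
  lsc <- vector("list", nn)
  npat <- ncol(tips[[1]])
  zero <- numeric(npat)
  for (i in seq_len(tp$ntip)) {
    part[[i]] <- tips[[i]]
    lsc[[i]] <- zero
  }
  E <- tp$edge
  for (k in seq_len(nrow(E))) {
    par <- E[k, 1]; ch <- E[k, 2]
    msg <- P[[k]] %*% part[[ch]]
    if (is.null(part[[par]])) {
      part[[par]] <- msg
      lsc[[par]] <- lsc[[ch]]
    } else {
      part[[par]] <- part[[par]] * msg
      lsc[[par]] <- lsc[[par]] + lsc[[ch]]
    }
    mx <- apply(part[[par]], 2, max)
    mx[mx <= 0] <- 1
    part[[par]] <- part[[par]] / rep(mx, each = nrow(part[[par]]))
    lsc[[par]] <- lsc[[par]] + log(mx)
  }
  rootl <- colSums(pi * part[[tp$root]])
  list(part = part, lsc = lsc,
       pattern_loglik = log(rootl) + lsc[[tp$root]])
}

# Preorder (up) pass: F[[v]] such that per-pattern likelihood
# = colSums(F[[v]] * part[[v]]) * exp(flsc[[v]] + lsc[[v]]).
engine_up <- function(tp, down, P, pi) {
  nn <- tp$ntip + tp$nnode
  Fp <- vector("list", nn)
  flsc <- vector("list", nn)
  npat <- length(down$pattern_loglik)
  Fp[[tp$root]] <- matrix(pi, length(pi), npat)
  flsc[[tp$root]] <- numeric(npat)
  E <- tp$edge
  # children (edge rows) per parent
  kids <- split(seq_len(nrow(E)), E[, 1])
  # preorder = reverse postorder over edges
  for (k in rev(seq_len(nrow(E)))) {
    par <- E[k, 1]; ch <- E[k, 2]
    sibs <- setdiff(kids[[as.character(par)]], k)
    A <- Fp[[par]]
    sc <- flsc[[par]]
    for (s in sibs) {
      A <- A * (P[[s]] %*% down$part[[E[s, 2]]])
      sc <- sc + down$lsc[[E[s, 2]]]
    }
    Fc <- crossprod(P[[k]], A)
    mx <- apply(Fc, 2, max)
    mx[mx <= 0] <- 1
    Fp[[ch]] <- Fc / rep(mx, each = nrow(Fc))
    flsc[[ch]] <- sc + log(mx)
  }
  list(Fp = Fp, flsc = flsc)
}

# per-pattern likelihood (on the exp scale, with separate log-scale) of one
# edge as a function of its length, all else fixed:
#   L(t) = colSums( A * (P(t) %*% D) ), A combining the rest of the tree.
edge_lik_fun <- function(tp, down, up, P, k, eQ) {
  E <- tp$edge
  par <- E[k, 1]; ch <- E[k, 2]
  kids <- which(E[, 1] == par)
  A <- up$Fp[[par]]
  sc <- up$flsc[[par]]
  for (s in setdiff(kids, k)) {
    A <- A * (P[[s]] %*% down$part[[E[s, 2]]])
    sc <- sc + down$lsc[[E[s, 2]]]
  }
  D <- down$part[[ch]]
  sc <- sc + down$lsc[[ch]]
  function(t) {
    L <- colSums(A * (prob_matrix(eQ, t) %*% D))
    list(lik = L, lsc = sc)
  }
}

# total log-likelihood from per-pattern logliks and weights
sum_loglik <- function(pat_ll, weight) sum(pat_ll * weight)

# Mixture across rate categories: cats is a list of per-category
# pattern-loglik vectors, w their prior weights.  Log-sum-exp.
mix_loglik <- function(cats, w) {
  M <- do.call(cbind, cats)
  pos <- w > 0
  mx <- apply(M[, pos, drop = FALSE], 1, max)
  log(as.vector(exp(M - mx) %*% w)) + mx
}

# Full-likelihood evaluation for a (possibly branch-heterogeneous) model.
#   Plist_fun(rates): given a per-site rate multiplier, build P per edge.
# Used by the fitters; returns per-pattern logliks.
model_pattern_loglik <- function(tp, tips, pi, edge_eQ, edge_len,
                                 rates = 1, rate_w = 1) {
  cats <- lapply(seq_along(rates), function(ci) {
    P <- lapply(seq_along(edge_len), function(k)
      prob_matrix(edge_eQ[[k]], edge_len[k] * rates[ci]))
    engine_down(tp, tips, P, pi)$pattern_loglik
  })
  if (length(rates) == 1L) cats[[1]] else mix_loglik(cats, rate_w)
}
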