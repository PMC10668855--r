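# Shared fixtures and independent oracles used across the suite.

library(ape)

# -- brute-force likelihood by enumeration over internal-node states ------
# tipstates: named character vector (taxon -> state symbol) for ONE site.
# Independent of the package's pruning engine: walks every assignment of
# internal states and multiplies transition probabilities directly.
enum_site_lik <- function(phy, tipstates, Q, pi, states, rate = 1) {
  phy <- reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  E <- phy$edge
  P <- lapply(seq_len(nrow(E)), function(k) {
    ap <- Matrix::expm(Q * phy$edge.length[k] * rate)
    as.matrix(ap)
  })
  nst <- length(states)
  tot <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), nnode)))
  tipidx <- match(tipstates[phy$tip.label], states)
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= ntip) tipidx[node] else grid[g, node - ntip]
    }
    pr <- unname(pi[assign_state(ntip + 1)])
    for (k in seq_len(nrow(E))) {
      a <- assign_state(E[k, 1]); b <- assign_state(E[k, 2])
      if (is.na(b)) next # missing tip: sum over states handled below
      pr <- pr * P[[k]][a, b]
    }
    tot <- tot + pr
  }
  unname(tot)
}

# gamma-mixture enumeration
enum_site_lik_gamma <- function(phy, tipstates, Q, pi, states, rates) {
  mean(vapply(rates, function(r)
    enum_site_lik(phy, tipstates, Q, pi, states, rate = r), numeric(1)))
}

# exact one-sided (greater) Wilcoxon rank-sum p-value by enumeration
exact_wilcoxon_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  W_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(Ws >= W_obs - 1e-9)
}

# brute-force Sankoff minimum for a single character on a 4-taxon tree:
# enumerate assignments of internal states
enum_sankoff <- function(phy, tip_state_idx, step) {
  phy <- reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  E <- phy$edge
  k <- nrow(step)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- function(node) if (node <= ntip) tip_state_idx[node]
      else grid[g, node - ntip]
    cost <- 0
    for (e in seq_len(nrow(E)))
      cost <- cost + step[st(E[e, 1]), st(E[e, 2])]
    best <- min(best, cost)
  }
  best
}

# standard 5-taxon fixture tree
fixture_tree5 <- function() {
  read.tree(text = "((a:0.15,b:0.12):0.08,(c:0.1,(d:0.2,e:0.1):0.07):0.05);")
}

fixture_tree4 <- function() {
  read.tree(text = "((a:0.15,b:0.15):0.08,(c:0.15,d:0.2):0.05);")
}

# small rooted tree for reconstruction work
fixture_rooted6 <- function() {
  read.tree(text = paste0("(((sal1:0.1,sal2:0.1):0.1,frog:0.2):0.1,",
                          "(anole:0.2,out:0.3):0.05);"))
}
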