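# Generic maximum-likelihood machinery shared by the nucleotide, codon and
# amino-acid fitters: full-likelihood evaluation for (possibly mixture)
# models and coordinate-wise branch-length optimization using the up-down
# single-edge likelihood trick.
#
# A model is described by, per mixture category c and edge k, a cached
# eigendecomposition edge_eQ[[c]][[k]], a per-category rate multiplier
# rates[c] applied to branch lengths, and prior weights rate_w[c].

full_loglik <- function(tp, tips, pi_by_cat, edge_eQ, edge_len,
                        rates, rate_w, weight) {
  cats <- lapply(seq_along(rates), function(ci) {
    P <- lapply(seq_along(edge_len), function(k)
      prob_matrix(edge_eQ[[ci]][[k]], edge_len[k] * rates[ci]))
    engine_down(tp, tips, P, pi_by_cat[[ci]])$pattern_loglik
  })
  pat <- if (length(rates) == 1L) cats[[1]] else mix_loglik(cats, rate_w)
  list(loglik = sum(pat * weight), pattern_loglik = pat)
}

# One Jacobi-style sweep of per-edge Brent optimization.  Partials are
# computed once at the incoming branch lengths; each edge's conditional
# optimum is exact given the others, updates are applied jointly, and the
# sweep is accepted only if the total log-likelihood improved (else edges
# are re-optimized sequentially with fresh partials).
optimize_edge_lengths <- function(tp, tips, pi_by_cat, edge_eQ, edge_len,
                                  rates, rate_w, weight,
                                  lower = 1e-8, upper = 20, tol = 1e-5) {
  ne <- length(edge_len)
  ncat <- length(rates)
  build_closures <- function(el) {
    downs <- vector("list", ncat); ups <- vector("list", ncat)
    Ps <- vector("list", ncat)
    for (ci in seq_len(ncat)) {
      P <- lapply(seq_len(ne), function(k)
        prob_matrix(edge_eQ[[ci]][[k]], el[k] * rates[ci]))
      d <- engine_down(tp, tips, P, pi_by_cat[[ci]])
      u <- engine_up(tp, d, P, pi_by_cat[[ci]])
      downs[[ci]] <- d; ups[[ci]] <- u; Ps[[ci]] <- P
    }
    list(downs = downs, ups = ups, Ps = Ps)
  }
  edge_obj <- function(st, k) {
    fns <- lapply(seq_len(ncat), function(ci)
      edge_lik_fun(tp, st$downs[[ci]], st$ups[[ci]], st$Ps[[ci]], k,
                   edge_eQ[[ci]][[k]]))
    function(t) {
      M <- matrix(0, length(weight), ncat)
      S <- matrix(0, length(weight), ncat)
      for (ci in seq_len(ncat)) {
        r <- fns[[ci]](t * rates[ci])
        M[, ci] <- r$lik
        S[, ci] <- r$lsc
      }
      lM <- log(pmax(M, 1e-300)) + S
      pat <- if (ncat == 1L) lM[, 1] else {
        mx <- apply(lM, 1, max)
        log(as.vector(exp(lM - mx) %*% rate_w)) + mx
      }
      sum(pat * weight)
    }
  }
  ll0 <- full_loglik(tp, tips, pi_by_cat, edge_eQ, edge_len, rates,
                     rate_w, weight)$loglik
  st <- build_closures(edge_len)
  prop <- edge_len
  for (k in seq_len(ne)) {
    f <- edge_obj(st, k)
    o <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
    if (o$objective > f(edge_len[k])) prop[k] <- o$maximum
  }
  ll1 <- full_loglik(tp, tips, pi_by_cat, edge_eQ, prop, rates, rate_w,
                     weight)$loglik
  if (ll1 >= ll0 - 1e-9) return(list(edge_len = prop, loglik = max(ll1, ll0)))
  # fall back: sequential updates with fresh partials per edge
  cur <- edge_len
  for (k in seq_len(ne)) {
    st <- build_closures(cur)
    f <- edge_obj(st, k)
    o <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
    if (o$objective > f(cur[k])) cur[k] <- o$maximum
  }
  ll2 <- full_loglik(tp, tips, pi_by_cat, edge_eQ, cur, rates, rate_w,
                     weight)$loglik
  if (ll2 >= ll0) list(edge_len = cur, loglik = ll2)
  else list(edge_len = edge_len, loglik = ll0)
}

# Brent line search on a transformed scalar parameter.
brent_par <- function(f, lower, upper, log_scale = TRUE, tol = 1e-4) {
  if (log_scale) {
    o <- stats::optimize(function(x) f(exp(x)), log(c(lower, upper)),
                         maximum = TRUE, tol = tol)
    list(par = exp(o$maximum), value = o$objective)
  } else {
    o <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
    list(par = o$maximum, value = o$objective)
  }
}

# crude starting branch lengths from pairwise mismatch proportions
init_branch_lengths <- function(tp, mat) {
  ntip <- tp$ntip
  d <- 0.05
  if (ntip >= 2) {
    m1 <- mat[tp$tip.label[1], ]; m2 <- mat[tp$tip.label[2], ]
    ok <- !is.na(m1) & !is.na(m2)
    if (sum(ok) > 0) d <- max(0.02, mean(m1[ok] != m2[ok]))
  }
  rep(max(0.02, d / 2), nrow(tp$edge))
}
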