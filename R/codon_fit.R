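# Codon branch-model fitting (GY94-type): one-ratio, multi-ratio and
# free-ratio models, and the PAML-style dN/dS decomposition per branch.

#' Edge classes for a foreground clade
#'
#' Labels tree edges as foreground (1) or background (0).  The foreground
#' is the clade spanned by `fg_tips`: its stem edge plus, optionally, all
#' internal/terminal edges within the clade.
#'
#' @param phy `phylo` tree
#' @param fg_tips character vector of tip labels defining the foreground
#'   clade (a single tip gives a terminal foreground branch)
#' @param within include edges inside the clade (default TRUE); if FALSE
#'   only the stem edge is foreground
#' @return integer vector (one per edge, postorder) of class labels
#' @export
foreground_edge_classes <- function(phy, fg_tips, within = TRUE) {
  tp <- prep_phylo(phy)
  miss <- setdiff(fg_tips, tp$tip.label)
  if (length(miss))
    stop("foreground tips not in tree: ", paste(miss, collapse = ", "))
  ntip <- tp$ntip
  E <- tp$edge
  intip <- tp$tip.label %in% fg_tips
  # postorder accumulation of tip descendants per node
  below <- vector("list", ntip + tp$nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (k in seq_len(nrow(E)))
    below[[E[k, 1]]] <- c(below[[E[k, 1]]], below[[E[k, 2]]])
  cls <- integer(nrow(E))
  for (k in seq_len(nrow(E))) {
    d <- below[[E[k, 2]]]
    all_fg <- all(intip[d])
    if (all_fg) {
      is_stem <- setequal(tp$tip.label[d], fg_tips)
      if (is_stem || within) cls[k] <- 1L
    }
  }
  cls
}

# cache of eigendecompositions keyed by (kappa, omega) given pi
codon_eQ_cache <- function(pi, gauge = c("class", "neutral")) {
  gauge <- match.arg(gauge)
  env <- new.env(parent = emptyenv())
  function(kappa, omega) {
    key <- sprintf("%.12g_%.12g", kappa, omega)
    if (!is.null(env[[key]])) return(env[[key]])
    if (gauge == "class") {
      Q <- build_codon_Q(kappa, omega, pi, scale = TRUE)
    } else {
      Q <- build_codon_Q(kappa, omega, pi, scale = FALSE)
      mu <- -sum(pi * diag(build_codon_Q(kappa, 1, pi, scale = FALSE)))
      Q <- Q / mu
    }
    env[[key]] <- eigen_Q(Q, pi)
    env[[key]]
  }
}

# proportions of synonymous sites/flow under the model; PAML-style
# definitions used for the dN/dS decomposition
codon_flow <- function(kappa, omega, pi) {
  tab <- std_codon_table()
  Q <- build_codon_Q(kappa, omega, pi, scale = TRUE)
  flow <- pi * Q
  syn <- sum(flow[tab$single & tab$synonymous])
  rho_s <- syn # total rate is 1 after scaling
  Q1 <- build_codon_Q(kappa, 1, pi, scale = TRUE)
  flow1 <- pi * Q1
  p_s <- sum(flow1[tab$single & tab$synonymous])
  list(rho_s = rho_s, rho_n = 1 - rho_s, p_s = p_s, p_n = 1 - p_s)
}

#' Fit a branch codon model
#'
#' Maximum-likelihood fit of a GY94-type codon model with dN/dS shared
#' within branch classes: `one_ratio` (single omega), `two_ratio` (separate
#' foreground omega; requires `fg`), or `free_ratio` (one omega per
#' branch).  Codon frequencies are F3x4 from the alignment.  Each class's
#' rate matrix is scaled to one expected substitution per codon so branch
#' lengths are in substitutions/codon.
#'
#' @param aln codon alignment
#' @param tree `phylo` with leaf set equal to the alignment taxa
#' @param model `"one_ratio"`, `"two_ratio"` or `"free_ratio"`
#' @param fg tip labels of the foreground clade (two-ratio), or an integer
#'   per-edge class vector from [foreground_edge_classes()]
#' @param passes coordinate passes (default 3)
#' @param n_starts optimizer starts: 1 heuristic plus `n_starts - 1`
#'   random restarts (default 1; the scans use more when asked).  Fits
#'   whose restarts disagree by more than 0.5 log-units are flagged.
#' @param omega_max upper bound for omega (default 20)
#' @return list with `loglik`, `kappa`, `omega` (per class), `edge_len`,
#'   `branch_rates` (data.frame: per edge t, class, omega, dN, dS),
#'   `pi`, `flag` (character, "" when clean), `tree`.
#' @export
fit_branch_model <- function(aln, tree,
                             model = c("one_ratio", "two_ratio",
                                       "free_ratio"),
                             fg = NULL, passes = 3, n_starts = 1,
                             omega_max = 20) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "aln"), aln$alphabet == "CODON")
  if (ncol(aln$mat) < 30) stop("need at least 30 codons")
  tp <- prep_phylo(tree, aln_taxa(aln))
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  ne <- nrow(tp$edge)
  cls <- switch(model,
    one_ratio = rep(1L, ne),
    two_ratio = {
      if (is.null(fg)) stop("two_ratio model needs fg")
      cl <- if (is.numeric(fg)) as.integer(fg)
            else foreground_edge_classes(tp$phy, fg)
      cl + 1L # classes 1 (bg), 2 (fg)
    },
    free_ratio = seq_len(ne))
  ncls <- max(cls)
  pi <- f3x4_frequencies(aln)
  cp <- compress_patterns(m)
  tips <- tip_partials(
    new_alignment(m[, cp$cols, drop = FALSE], "CODON"), sense_codons())
  # degenerate input: no variation
  npat_var <- sum(vapply(seq_along(cp$cols), function(j) {
    col <- m[, cp$cols[j]]
    length(unique(col[!is.na(col)])) > 1
  }, logical(1)))
  if (npat_var == 0) {
    br <- data.frame(edge = seq_len(ne), parent = tp$edge[, 1],
                     child = tp$edge[, 2], class = cls, t = 0,
                     omega = NA_real_, dN = 0, dS = 0)
    return(list(loglik = NA_real_, kappa = NA_real_,
                omega = rep(NA_real_, ncls), edge_len = rep(0, ne),
                branch_rates = br, pi = pi,
                flag = "no_variation", tree = tp$phy))
  }
  cache <- codon_eQ_cache(pi, "class")

  one_fit <- function(kappa, omega, edge_len) {
    ll_full <- function(kappa, omega, el) {
      eqs <- lapply(omega, function(w) cache(kappa, w))
      edge_eQ <- list(lapply(seq_len(ne), function(k) eqs[[cls[k]]]))
      full_loglik(tp, tips, list(pi), edge_eQ, el, 1, 1, cp$weight)$loglik
    }
    for (p in seq_len(passes)) {
      eqs <- lapply(omega, function(w) cache(kappa, w))
      edge_eQ <- list(lapply(seq_len(ne), function(k) eqs[[cls[k]]]))
      r <- optimize_edge_lengths(tp, tips, list(pi), edge_eQ, edge_len,
                                 1, 1, cp$weight)
      edge_len <- r$edge_len
      o <- brent_par(function(kp) ll_full(kp, omega, edge_len), 0.2, 30,
                     tol = 3e-3)
      kappa <- o$par
      for (ci in seq_len(ncls)) {
        o <- brent_par(function(w) {
          om <- omega; om[ci] <- w
          ll_full(kappa, om, edge_len)
        }, 1e-4, omega_max, tol = 3e-3)
        omega[ci] <- o$par
      }
    }
    list(loglik = ll_full(kappa, omega, edge_len), kappa = kappa,
         omega = omega, edge_len = edge_len)
  }

  el0 <- init_branch_lengths(tp, m)
  starts <- list(list(kappa = 2, omega = rep(0.3, ncls), el = el0))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- list(
        kappa = stats::runif(1, 1, 5),
        omega = exp(stats::runif(ncls, log(0.05), log(2))),
        el = el0 * stats::runif(1, 0.5, 2))
  }
  fits <- lapply(starts, function(s) one_fit(s$kappa, s$omega, s$el))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(lls)]]
  flag <- if (length(lls) > 1 && diff(range(lls)) > 0.5)
    "restart_disagreement" else ""

  fl <- lapply(best$omega, function(w) codon_flow(best$kappa, w, pi))
  br <- data.frame(
    edge = seq_len(ne), parent = tp$edge[, 1], child = tp$edge[, 2],
    class = cls, t = best$edge_len,
    omega = best$omega[cls],
    dN = vapply(seq_len(ne), function(k)
      best$edge_len[k] * fl[[cls[k]]]$rho_n / (3 * fl[[cls[k]]]$p_n),
      numeric(1)),
    dS = vapply(seq_len(ne), function(k)
      best$edge_len[k] * fl[[cls[k]]]$rho_s / (3 * fl[[cls[k]]]$p_s),
      numeric(1)))
  lab <- character(ne)
  istip <- tp$edge[, 2] <= tp$ntip
  lab[istip] <- tp$tip.label[tp$edge[istip, 2]]
  br$label <- lab
  tr <- tp$phy; tr$edge.length <- best$edge_len
  list(loglik = best$loglik, kappa = best$kappa, omega = best$omega,
       edge_len = best$edge_len, branch_rates = br, pi = pi,
       flag = flag, tree = tr)
}
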