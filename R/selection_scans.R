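# Branch-site positive-selection model (Model A) and the gene-level
# selection scans: PSG (branch-site LRT), FEG (one-ratio vs multi-ratio
# LRT), group-mean dN/dS summaries and 4-fold degenerate site rates.

# Branch-site Model A.  Four site classes with proportions
#   p0 = w*q, p1 = w*(1-q), p2a = (1-w)*q, p2b = (1-w)*(1-q):
#   class 0: omega0 on all branches; class 1: omega 1 everywhere;
#   class 2a: omega0 background / omega2 foreground;
#   class 2b: 1 background / omega2 foreground.
# The null fixes omega2 = 1.  All rate matrices share the neutral gauge
# (scaled by the omega = 1 substitution rate) so elevated omega genuinely
# accelerates the foreground.
fit_branch_site <- function(aln, tree, fg, null = FALSE, passes = 3,
                            omega2_max = 50, init = NULL) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "CODON")
  tp <- prep_phylo(tree, aln_taxa(aln))
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  ne <- nrow(tp$edge)
  fgcls <- if (is.numeric(fg)) as.integer(fg)
           else foreground_edge_classes(tp$phy, fg)
  if (all(fgcls == 0L)) stop("no foreground edges")
  pi <- f3x4_frequencies(aln)
  cp <- compress_patterns(m)
  tips <- tip_partials(
    new_alignment(m[, cp$cols, drop = FALSE], "CODON"), sense_codons())
  cache <- codon_eQ_cache(pi, "neutral")

  # per-class (4) per-edge eigendecompositions for given params
  class_eQ <- function(kappa, w0, w2) {
    eq_w0 <- cache(kappa, w0); eq_1 <- cache(kappa, 1)
    eq_w2 <- cache(kappa, w2)
    list(
      lapply(seq_len(ne), function(k) eq_w0),                    # class 0
      lapply(seq_len(ne), function(k) eq_1),                     # class 1
      lapply(seq_len(ne), function(k)
        if (fgcls[k]) eq_w2 else eq_w0),                         # class 2a
      lapply(seq_len(ne), function(k)
        if (fgcls[k]) eq_w2 else eq_1))                          # class 2b
  }
  props <- function(w, q) c(w * q, w * (1 - q), (1 - w) * q,
                            (1 - w) * (1 - q))
  pat_ll_by_class <- function(kappa, w0, w2, el) {
    eQ <- class_eQ(kappa, w0, w2)
    lapply(1:4, function(ci) {
      P <- lapply(seq_len(ne), function(k) prob_matrix(eQ[[ci]][[k]], el[k]))
      engine_down(tp, tips, P, pi)$pattern_loglik
    })
  }
  mix_ll <- function(cats, w, q) {
    sum(mix_loglik(cats, props(w, q)) * cp$weight)
  }
  ll_full <- function(kappa, w0, w2, w, q, el)
    mix_ll(pat_ll_by_class(kappa, w0, w2, el), w, q)

  kappa <- 2; w0 <- 0.2; w2 <- if (null) 1 else 2
  w <- 0.85; q <- 0.8
  el <- init_branch_lengths(tp, m)
  if (!is.null(init)) {
    kappa <- init$kappa; w0 <- init$omega0
    w <- init$p[1] + init$p[2]
    q <- init$p[1] / max(w, 1e-9)
    q <- min(max(q, 1e-6), 1 - 1e-6)
    el <- init$edge_len
    if (!null && !is.null(init$omega2))
      w2 <- if (init$omega2 > 1.001) init$omega2 else 2
  }
  for (p in seq_len(passes)) {
    eQ <- class_eQ(kappa, w0, w2)
    r <- optimize_edge_lengths(tp, tips, rep(list(pi), 4), eQ, el,
                               rep(1, 4), props(w, q), cp$weight)
    el <- r$edge_len
    cats <- pat_ll_by_class(kappa, w0, w2, el)
    # mixture weights: cheap given cached class logliks
    clamp <- function(v) min(max(v, 1e-6), 1 - 1e-6)
    o <- stats::optim(stats::qlogis(c(clamp(w), clamp(q))),
                      function(th) {
                        v <- -mix_ll(cats, stats::plogis(th[1]),
                                     stats::plogis(th[2]))
                        if (!is.finite(v)) 1e10 else v
                      },
                      method = "Nelder-Mead",
                      control = list(maxit = 200))
    w <- clamp(stats::plogis(o$par[1])); q <- clamp(stats::plogis(o$par[2]))
    o <- brent_par(function(kp) ll_full(kp, w0, w2, w, q, el), 0.2, 30,
                   tol = 3e-3)
    kappa <- o$par
    o <- brent_par(function(v) ll_full(kappa, v, w2, w, q, el),
                   1e-4, 0.999, log_scale = FALSE, tol = 3e-3)
    w0 <- o$par
    if (!null) {
      o <- brent_par(function(v) ll_full(kappa, w0, v, w, q, el),
                     1, omega2_max, log_scale = TRUE, tol = 3e-3)
      w2 <- o$par
    }
  }
  cats <- pat_ll_by_class(kappa, w0, w2, el)
  pr <- props(w, q)
  pat <- mix_loglik(cats, pr)
  # naive empirical Bayes posterior of the selected classes (2a+2b) at the
  # MLEs; reported per site.  NOT a Bayes-empirical-Bayes probability.
  M <- do.call(cbind, cats)
  mx <- apply(M, 1, max)
  post <- exp(M - mx) * rep(pr, each = nrow(M))
  post <- post / rowSums(post)
  sel_post <- (post[, 3] + post[, 4])[cp$index]
  list(loglik = sum(pat * cp$weight), kappa = kappa, omega0 = w0,
       omega2 = w2, p = pr, edge_len = el,
       site_posterior = sel_post)
}

#' Branch-site scan for positively selected genes (PSGs)
#'
#' For each gene, fits branch-site Model A (alternative: foreground
#' omega2 >= 1 free; null: omega2 = 1) on the given foreground, performs a
#' chi-square(df = 1) likelihood-ratio test, and adjusts p-values across
#' genes by Benjamini-Hochberg FDR.  Per-site posterior probabilities of
#' the positively selected class are naive empirical Bayes values at the
#' MLEs (not BEB).
#'
#' @param genes named list of codon alignments
#' @param tree `phylo` shared by all genes
#' @param fg foreground tip labels (or per-edge class vector)
#' @param alpha FDR threshold for the PSG call (default 0.05)
#' @param passes optimizer passes per fit
#' @return data.frame per gene: loglik_null, loglik_alt, lrt, df, p,
#'   p_adj, omega2, call; attribute `site_posterior` (list).
#' @export
psg_scan <- function(genes, tree, fg, alpha = 0.05, passes = 3) {
  stopifnot(length(genes) >= 1)
  if (is.null(names(genes))) names(genes) <- paste0("g", seq_along(genes))
  rows <- lapply(names(genes), function(g) {
    nul <- fit_branch_site(genes[[g]], tree, fg, null = TRUE,
                           passes = passes)
    # the alternative nests the null: warm-starting it at the null optimum
    # guarantees loglik_alt >= loglik_null up to line-search tolerance
    alt <- fit_branch_site(genes[[g]], tree, fg, null = FALSE,
                           passes = passes, init = nul)
    lrt <- max(0, 2 * (alt$loglik - nul$loglik))
    data.frame(gene = g, loglik_null = nul$loglik,
               loglik_alt = alt$loglik, lrt = lrt, df = 1,
               p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               omega2 = alt$omega2,
               site_max_post = max(alt$site_posterior))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$call <- ifelse(res$p_adj < alpha & res$omega2 > 1, "PSG", "none")
  res
}

#' One-ratio vs multi-ratio scan for fast-evolving genes (FEGs)
#'
#' Null: a single dN/dS for the whole tree.  Alternative: a separate
#' dN/dS on the foreground.  LRT with df = number of extra omega
#' parameters; BH-FDR across genes; a gene is an FEG when the adjusted
#' p-value is below `alpha` AND the foreground omega exceeds the
#' background omega.
#'
#' @inheritParams psg_scan
#' @param n_starts optimizer starts per fit (see [fit_branch_model()])
#' @return data.frame per gene with loglik_null, loglik_alt, lrt, df, p,
#'   p_adj, omega_fg, omega_bg, call.
#' @export
feg_scan <- function(genes, tree, fg, alpha = 0.05, passes = 3,
                     n_starts = 1) {
  stopifnot(length(genes) >= 1)
  if (is.null(names(genes))) names(genes) <- paste0("g", seq_along(genes))
  rows <- lapply(names(genes), function(g) {
    one <- fit_branch_model(genes[[g]], tree, "one_ratio",
                            passes = passes, n_starts = n_starts)
    two <- fit_branch_model(genes[[g]], tree, "two_ratio", fg = fg,
                            passes = passes, n_starts = n_starts)
    df <- length(two$omega) - length(one$omega)
    if (df <= 0) stop("foreground configuration yields no extra parameter")
    lrt <- max(0, 2 * (two$loglik - one$loglik))
    data.frame(gene = g, loglik_null = one$loglik,
               loglik_alt = two$loglik, lrt = lrt, df = df,
               p = stats::pchisq(lrt, df = df, lower.tail = FALSE),
               omega_bg = two$omega[1], omega_fg = two$omega[2],
               flag = paste(one$flag, two$flag, sep = ""))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$call <- ifelse(res$p_adj < alpha & res$omega_fg > res$omega_bg,
                     "FEG", "none")
  res
}

#' Group mean dN/dS with the > 5 exclusion rule
#'
#' Averages terminal-branch dN/dS within each group after excluding
#' abnormal values (dN/dS > 5); also returns the per-group value vectors
#' for distribution comparisons (Wilcoxon) and a genes x groups matrix
#' suitable for clustering/heatmaps.
#'
#' @param rates data.frame of terminal-branch rates with columns `gene`,
#'   `label` (taxon), `omega`
#' @param group_map named character vector: taxon -> group
#' @param cutoff exclusion threshold (default 5)
#' @return list with `means` (named numeric), `values` (list of numeric
#'   per group), `matrix` (gene x group mean omega), `wilcoxon`
#'   (pairwise one-sided rank-sum p-values, greater alternative by row)
#' @export
group_mean_dnds <- function(rates, group_map, cutoff = 5) {
  stopifnot(all(c("label", "omega") %in% names(rates)))
  unknown <- setdiff(unique(rates$label), names(group_map))
  if (length(unknown))
    stop("terminal branches not mapped to a group: ",
         paste(unknown, collapse = ", "))
  rates$group <- unname(group_map[rates$label])
  keep <- !is.na(rates$omega) & rates$omega <= cutoff
  kept <- rates[keep, , drop = FALSE]
  groups <- unique(unname(group_map))
  values <- lapply(groups, function(g) kept$omega[kept$group == g])
  names(values) <- groups
  means <- vapply(groups, function(g) {
    v <- values[[g]]
    if (!length(v)) {
      warning("group ", g, " has no surviving branches")
      return(NA_real_)
    }
    mean(v)
  }, numeric(1))
  gm <- NULL
  if ("gene" %in% names(kept)) {
    gm <- tapply(kept$omega, list(kept$gene, kept$group), mean)
  }
  W <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (a in groups) for (b in groups) if (a != b &&
      length(values[[a]]) && length(values[[b]]))
    W[a, b] <- stats::wilcox.test(values[[a]], values[[b]],
                                  alternative = "greater",
                                  exact = FALSE)$p.value
  list(means = means, values = values, matrix = gm, wilcoxon = W)
}

#' Per-branch substitution rates at 4-fold degenerate sites
#'
#' Extracts third positions of 4-fold degenerate codon columns (codon
#' family conserved across all taxa, third position free) and fits GTR
#' branch lengths on the fixed topology; the fitted branch lengths are the
#' per-branch neutral rates.
#'
#' @param aln codon alignment
#' @param tree `phylo`
#' @param min_sites minimum 4D sites for a confident fit (default 50)
#' @return list with `rates` (data.frame edge/parent/child/label/rate),
#'   `n_sites`, `low_confidence` flag, `tree`
#' @export
fourfold_rates <- function(aln, tree, min_sites = 50) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "CODON")
  m <- aln$mat
  keep <- vapply(seq_len(ncol(m)), function(j) is_fourfold_column(m[, j]),
                 logical(1))
  if (!any(keep)) stop("no 4-fold degenerate columns")
  third <- substr(m[, keep, drop = FALSE], 3, 3)
  dim(third) <- c(nrow(m), sum(keep))
  rownames(third) <- rownames(m)
  daln <- new_alignment(third, "DNA")
  fit <- fit_fixed_topology(daln, tree, gamma = FALSE, passes = 2)
  tp <- prep_phylo(tree, rownames(third))
  lab <- character(nrow(tp$edge))
  istip <- tp$edge[, 2] <= tp$ntip
  lab[istip] <- tp$tip.label[tp$edge[istip, 2]]
  list(rates = data.frame(edge = seq_along(fit$edge_len),
                          parent = tp$edge[, 1], child = tp$edge[, 2],
                          label = lab, rate = fit$edge_len),
       n_sites = sum(keep), low_confidence = sum(keep) < min_sites,
       tree = fit$tree)
}
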