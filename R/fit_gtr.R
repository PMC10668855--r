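# Nucleotide GTR+Gamma likelihood fit on a fixed topology.

NUC_STATES <- c("A", "C", "G", "T")

#' Fit GTR+Gamma on a fixed topology
#'
#' Optimizes branch lengths, the five free GTR exchangeabilities and the
#' gamma shape by coordinate-wise bounded scalar search (Brent), with base
#' frequencies taken from the data.  Returns the per-site log-likelihoods
#' at the optimum, as needed by the AU topology test.
#'
#' @param aln DNA alignment (`aln`)
#' @param topology `phylo` tree; leaf set must equal the alignment taxa.
#'   Branch lengths, if any, are discarded and re-optimized.
#' @param k number of discrete gamma categories (default 4); `gamma =
#'   FALSE` fits a rate-homogeneous model.
#' @param gamma logical, include gamma rate variation
#' @param passes number of full coordinate passes (default 2)
#' @param fix_params optional list with elements `rates`, `alpha`, `pi` to
#'   hold model parameters fixed (used by oracles/tests).
#' @return list with `loglik`, `site_loglik` (length = sites),
#'   `edge_len`, `rates`, `pi`, `alpha`, `tree` (topology with fitted
#'   branch lengths).
#' @export
fit_fixed_topology <- function(aln, topology, k = 4, gamma = TRUE,
                               passes = 2, fix_params = NULL) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "DNA")
  if (ncol(aln$mat) == 0) stop("empty alignment")
  tp <- prep_phylo(topology, aln_taxa(aln))
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  cp <- compress_patterns(m)
  tips <- tip_partials(new_alignment(m[, cp$cols, drop = FALSE], "DNA"),
                       NUC_STATES)
  obs <- m[!is.na(m)]
  pi <- if (!is.null(fix_params$pi)) fix_params$pi else {
    tb <- table(factor(obs, levels = NUC_STATES))
    as.numeric(tb + 1) / (sum(tb) + 4)
  }
  names(pi) <- NUC_STATES
  rates <- if (!is.null(fix_params$rates)) fix_params$rates else rep(1, 6)
  alpha <- if (!is.null(fix_params$alpha)) fix_params$alpha else 1
  edge_len <- init_branch_lengths(tp, m)
  ne <- nrow(tp$edge)

  mk <- function(rates, alpha) {
    eQ <- eigen_Q(build_gtr_Q(rates, pi), pi)
    r <- if (gamma) gamma_rates(alpha, k) else 1
    list(edge_eQ = rep(list(rep(list(eQ), ne)), length(r)),
         rates = r, rate_w = rep(1 / length(r), length(r)))
  }
  pi_by_cat <- function(ncat) rep(list(pi), ncat)

  ll_of <- function(rates, alpha, el) {
    md <- mk(rates, alpha)
    full_loglik(tp, tips, pi_by_cat(length(md$rates)), md$edge_eQ, el,
                md$rates, md$rate_w, cp$weight)$loglik
  }

  free <- is.null(fix_params)
  for (pass in seq_len(passes)) {
    md <- mk(rates, alpha)
    res <- optimize_edge_lengths(tp, tips, pi_by_cat(length(md$rates)),
                                 md$edge_eQ, edge_len, md$rates,
                                 md$rate_w, cp$weight)
    edge_len <- res$edge_len
    if (free) {
      for (j in 1:5) { # GT fixed at 1
        o <- brent_par(function(v) {
          rr <- rates; rr[j] <- v
          ll_of(rr, alpha, edge_len)
        }, 0.02, 50)
        rates[j] <- o$par
      }
      if (gamma) {
        o <- brent_par(function(a) ll_of(rates, a, edge_len), 0.05, 50)
        alpha <- o$par
      }
    }
  }
  md <- mk(rates, alpha)
  fin <- full_loglik(tp, tips, pi_by_cat(length(md$rates)), md$edge_eQ,
                     edge_len, md$rates, md$rate_w, cp$weight)
  if (!all(is.finite(fin$pattern_loglik))) {
    bad <- cp$cols[which(!is.finite(fin$pattern_loglik))[1]]
    stop("non-finite site likelihood at site ", bad)
  }
  tr <- tp$phy
  tr$edge.length <- edge_len
  list(loglik = fin$loglik,
       site_loglik = fin$pattern_loglik[cp$index],
       edge_len = edge_len, rates = rates, pi = pi,
       alpha = if (gamma) alpha else NA_real_, tree = tr)
}

#' Per-site log-likelihood matrix for a set of candidate topologies
#'
#' Fits GTR+Gamma independently on each fixed topology (branch lengths
#' re-optimized per topology) and stacks the per-site log-likelihood
#' vectors, the input expected by [au_test()].
#'
#' @param aln DNA alignment
#' @param topologies named list of `phylo` objects (e.g. H1..H5)
#' @param ... passed to [fit_fixed_topology()]
#' @return matrix (topologies x sites) of per-site log-likelihoods, with
#'   attribute `loglik` (per-topology totals).
#' @export
site_loglik_matrix <- function(aln, topologies, ...) {
  stopifnot(length(topologies) >= 1, !is.null(names(topologies)))
  fits <- lapply(topologies, function(tr) fit_fixed_topology(aln, tr, ...))
  m <- do.call(rbind, lapply(fits, `[[`, "site_loglik"))
  rownames(m) <- names(topologies)
  attr(m, "loglik") <- vapply(fits, `[[`, numeric(1), "loglik")
  m
}
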