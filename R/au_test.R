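# Approximately-unbiased (AU) topology test via multiscale RELL bootstrap:
# per-site log-likelihoods are resampled at several scale factors, the
# bootstrap proportion of each topology being best is mapped through the
# normal quantile, and signed distance / curvature are fitted by weighted
# least squares; p_AU = 1 - Phi(d - c).

#' AU test from a per-site log-likelihood matrix
#'
#' @param m matrix (topologies x sites) of per-site log-likelihoods, with
#'   rownames identifying the topologies
#' @param scales bootstrap scale factors (default 10 steps over 0.5-1.4)
#' @param n_boot bootstrap replicates per scale (default 10000)
#' @param seed RNG seed; resampling is keyed to a canonical site order so
#'   results are invariant to site permutation
#' @return named numeric vector of AU p-values, one per topology, with
#'   attribute `bp` (the per-scale bootstrap proportion matrix)
#' @export
au_test <- function(m, scales = seq(0.5, 1.4, length.out = 10),
                    n_boot = 10000, seed = 1) {
  stopifnot(is.matrix(m), nrow(m) >= 2, n_boot >= 100)
  if (is.null(rownames(m))) rownames(m) <- paste0("T", seq_len(nrow(m)))
  ntop <- nrow(m); n <- ncol(m)
  # canonical site order -> permutation invariance of the seed stream
  ord <- do.call(order, as.data.frame(t(m)))
  m <- m[, ord, drop = FALSE]
  dup <- duplicated(m, MARGIN = 1)
  if (any(dup))
    warning("topologies with identical per-site log-likelihoods: ",
            paste(rownames(m)[dup], collapse = ", "))
  set.seed(seed)
  bp <- matrix(0, ntop, length(scales),
               dimnames = list(rownames(m), NULL))
  for (j in seq_along(scales)) {
    nprime <- max(2L, round(n * scales[j]))
    counts <- stats::rmultinom(n_boot, nprime, rep(1 / n, n))
    ll <- m %*% counts # ntop x n_boot
    mx <- apply(ll, 2, max)
    ismax <- sweep(ll, 2, mx, ">=")
    share <- sweep(ismax, 2, colSums(ismax), "/")
    bp[, j] <- rowMeans(share)
  }
  eps <- 0.1 / n_boot
  p_au <- vapply(seq_len(ntop), function(i) {
    b <- pmin(pmax(bp[i, ], eps), 1 - eps)
    z <- stats::qnorm(1 - b)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    w <- n_boot * stats::dnorm(z)^2 / (b * (1 - b))
    fit <- stats::lm.wfit(X, z, w)
    dc <- fit$coefficients
    1 - stats::pnorm(dc[1] - dc[2])
  }, numeric(1))
  names(p_au) <- rownames(m)
  attr(p_au, "bp") <- bp
  p_au
}

#' Per-hypothesis support counts over genes
#'
#' Runs the AU test on each gene's per-site log-likelihood matrix and
#' counts, per topology, the genes whose AU p-value is >= `alpha`
#' (i.e. the genes that cannot reject that hypothesis).
#'
#' @param genes list of per-gene matrices (topologies x sites), all with
#'   the same topology labels
#' @param alpha rejection level (default 0.05)
#' @param ... passed to [au_test()]
#' @return list with `counts` (named integer per topology), `p`
#'   (gene x topology AU p-value matrix, heatmap-ready)
#' @export
hypothesis_support_counts <- function(genes, alpha = 0.05, ...) {
  stopifnot(length(genes) >= 1)
  labs <- rownames(genes[[1]])
  if (is.null(labs)) stop("topology labels (rownames) required")
  P <- t(vapply(seq_along(genes), function(i) {
    mi <- genes[[i]]
    if (!identical(rownames(mi), labs))
      stop("gene ", i, " is missing or reorders topologies")
    as.numeric(au_test(mi, ...)[labs])
  }, numeric(length(labs))))
  colnames(P) <- labs
  rownames(P) <- names(genes) %||% paste0("gene", seq_along(genes))
  list(counts = colSums(P >= alpha), p = P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
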