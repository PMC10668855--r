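# Supermatrix / gene quality-control statistics: completeness, RCFV
# compositional heterogeneity, per-taxon chi-square composition tests and
# pairwise Bowker matched-pairs symmetry (SRH) tests, plus the gene filter
# that applies the stated thresholds.

qc_states <- function(aln) {
  switch(aln$alphabet,
         DNA = c("A", "C", "G", "T"),
         AA = .AA,
         CODON = sense_codons())
}

#' Alignment completeness score
#'
#' Proportion of non-missing cells, per taxon and overall.
#'
#' @param aln alignment
#' @return list with `per_taxon` (named numeric in `[0, 1]`) and
#'   `overall` (mean over all cells)
#' @export
completeness_score <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  if (length(aln$mat) == 0) stop("empty alignment")
  ok <- !is.na(aln$mat)
  list(per_taxon = rowMeans(ok), overall = mean(ok))
}

#' Relative Composition Frequency Variability (RCFV)
#'
#' RCFV = sum over taxa and states of |f(taxon, state) - mean_f(state)| /
#' n_taxa, computed on non-missing cells.  Higher values mean stronger
#' compositional heterogeneity among taxa; identical compositions give 0.
#'
#' @param aln alignment
#' @return list of class `composition_report`: `freq` (taxon x state
#'   frequency matrix), `per_taxon` (RCFV contributions), `rcfv` (total)
#' @export
rcfv <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  states <- qc_states(aln)
  n0 <- rowSums(!is.na(aln$mat))
  if (any(n0 == 0)) {
    warning("taxa with no data excluded from RCFV: ",
            paste(aln_taxa(aln)[n0 == 0], collapse = ", "))
    aln <- new_alignment(aln$mat[n0 > 0, , drop = FALSE], aln$alphabet)
  }
  if (nrow(aln$mat) < 2) stop("need at least 2 taxa with data")
  f <- t(apply(aln$mat, 1, function(row) {
    tb <- table(factor(row[!is.na(row)], levels = states))
    as.numeric(tb) / sum(tb)
  }))
  colnames(f) <- states
  mu <- colMeans(f)
  dev <- abs(sweep(f, 2, mu))
  per_taxon <- rowSums(dev) / nrow(f)
  structure(list(freq = f, per_taxon = per_taxon,
                 rcfv = sum(per_taxon)),
            class = "composition_report")
}

#' Per-taxon chi-square composition test
#'
#' Tests each taxon's state counts against the pooled (all-taxa) state
#' frequencies.  States with zero expected count are dropped and the
#' degrees of freedom adjusted.
#'
#' @param aln alignment
#' @param alpha flag threshold (default 0.01)
#' @return data.frame: taxon, statistic, df, p, heterogeneous (p < alpha)
#' @export
chi2_composition_test <- function(aln, alpha = 0.01) {
  stopifnot(inherits(aln, "aln"), nrow(aln$mat) >= 2)
  states <- qc_states(aln)
  counts <- t(apply(aln$mat, 1, function(row)
    as.numeric(table(factor(row[!is.na(row)], levels = states)))))
  pooled <- colSums(counts)
  pfreq <- pooled / sum(pooled)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    n <- sum(counts[i, ])
    keep <- pfreq > 0
    exp_ct <- n * pfreq[keep]
    stat <- sum((counts[i, keep] - exp_ct)^2 / exp_ct)
    df <- sum(keep) - 1
    data.frame(taxon = aln_taxa(aln)[i], statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  res$heterogeneous <- res$p < alpha
  res
}

#' Pairwise Bowker matched-pairs symmetry tests
#'
#' For each taxon pair, builds the divergence matrix over sites
#' non-missing in both and computes Bowker's statistic
#' sum over unordered state pairs of (n_ij - n_ji)^2 / (n_ij + n_ji),
#' df = number of pairs with n_ij + n_ji > 0.  A significant value
#' indicates violation of the stationary/reversible/homogeneous (SRH)
#' assumptions for that pair.
#'
#' @param aln alignment
#' @return list of class `symmetry_matrix`: `statistic`, `df`, `p`
#'   (symmetric taxon x taxon matrices, diagonal NA); df = 0 (identical
#'   sequences) gives p = NA
#' @export
bowker_pairwise_matrix <- function(aln) {
  stopifnot(inherits(aln, "aln"), nrow(aln$mat) >= 2)
  states <- qc_states(aln)
  tx <- aln_taxa(aln)
  n <- length(tx)
  S <- DF <- P <- matrix(NA_real_, n, n, dimnames = list(tx, tx))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- bowker_stat(aln$mat[i, ], aln$mat[j, ], states)
    S[i, j] <- S[j, i] <- r$statistic
    DF[i, j] <- DF[j, i] <- r$df
    P[i, j] <- P[j, i] <- r$p
  }
  structure(list(statistic = S, df = DF, p = P),
            class = "symmetry_matrix")
}

bowker_stat <- function(x, y, states) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok))
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  tab <- table(factor(x[ok], levels = states),
               factor(y[ok], levels = states))
  num <- (tab - t(tab))^2
  den <- tab + t(tab)
  up <- upper.tri(tab)
  use <- up & den > 0
  df <- sum(use)
  if (df == 0)
    return(list(statistic = 0, df = 0, p = NA_real_))
  stat <- sum(num[use] / den[use])
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Proportion of parsimony-informative sites
#'
#' Proxy reported alongside the QC metrics (a stand-in for supermatrix
#' information content; distinct from quartet-geometry measures).
#'
#' @param aln alignment
#' @return fraction of columns with >= 2 states each observed >= 2 times
#' @export
parsimony_informative_fraction <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  mean(apply(aln$mat, 2, function(col) {
    tb <- table(col[!is.na(col)])
    sum(tb >= 2) >= 2
  }))
}

#' Filter genes by QC thresholds
#'
#' Applies, per gene: minimum completeness, maximum RCFV, chi-square
#' composition heterogeneity (gene flagged if any taxon is heterogeneous
#' at `chi2_alpha`), and a Bowker violation rule (gene flagged when more
#' than `bowker_max_frac` of taxon pairs have p < `bowker_alpha`).  Any
#' threshold can be disabled with NULL.
#'
#' @param genes named list of alignments
#' @param min_completeness e.g. 0.7 (NULL disables)
#' @param max_rcfv e.g. 0.025 (NULL disables)
#' @param chi2_alpha e.g. 0.01 (NULL disables)
#' @param bowker_alpha pair-level significance (default 0.05)
#' @param bowker_max_frac gene flagged if the violating-pair fraction
#'   exceeds this (default 0.5; NULL disables the Bowker rule)
#' @return list with `retained` (list of alignments) and `report`
#'   (data.frame gene, completeness, rcfv, chi2_het, bowker_frac,
#'   removed, reason)
#' @export
filter_genes <- function(genes, min_completeness = 0.7,
                         max_rcfv = 0.025, chi2_alpha = 0.01,
                         bowker_alpha = 0.05, bowker_max_frac = 0.5) {
  stopifnot(length(genes) >= 1)
  if (is.null(names(genes))) names(genes) <- paste0("g", seq_along(genes))
  rep_rows <- lapply(names(genes), function(g) {
    a <- genes[[g]]
    comp <- completeness_score(a)$overall
    rc <- rcfv(a)$rcfv
    chi_het <- if (is.null(chi2_alpha)) FALSE else
      any(chi2_composition_test(a, chi2_alpha)$heterogeneous)
    bfrac <- if (is.null(bowker_max_frac)) 0 else {
      p <- bowker_pairwise_matrix(a)$p
      pv <- p[upper.tri(p)]
      if (all(is.na(pv))) 0 else mean(pv < bowker_alpha, na.rm = TRUE)
    }
    reason <- character(0)
    if (!is.null(min_completeness) && comp < min_completeness)
      reason <- c(reason, "completeness")
    if (!is.null(max_rcfv) && rc >= max_rcfv)
      reason <- c(reason, "rcfv")
    if (chi_het) reason <- c(reason, "chi2_composition")
    if (!is.null(bowker_max_frac) && bfrac > bowker_max_frac)
      reason <- c(reason, "bowker")
    data.frame(gene = g, completeness = comp, rcfv = rc,
               chi2_het = chi_het, bowker_frac = bfrac,
               removed = length(reason) > 0,
               reason = paste(reason, collapse = "+"))
  })
  report <- do.call(rbind, rep_rows)
  retained <- genes[!report$removed]
  if (!length(retained))
    stop("all genes removed; relax the QC thresholds")
  list(retained = retained, report = report)
}

#' Write a p-value matrix as TSV (heatmap-ready)
#' @param sym `symmetry_matrix` from [bowker_pairwise_matrix()]
#' @param file output path
#' @export
write_symmetry_tsv <- function(sym, file) {
  utils::write.table(sym$p, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}
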