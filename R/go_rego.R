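# Rapidly evolving GO category (REGO) detection: per-term dN/dS
# distributions with ancestor propagation, one-sided Wilcoxon rank-sum
# scans against the gene background, and development-related proportions.

#' GO annotation object
#'
#' @param gene2term data.frame with columns `gene`, `term`
#' @param term_parents data.frame with columns `term`, `parent`
#'   (a slice of the GO DAG; must be acyclic)
#' @return list of class `go_annotation` with `gene2term` and `parents`
#'   (named list term -> character parents)
#' @export
go_annotation <- function(gene2term, term_parents = NULL) {
  stopifnot(all(c("gene", "term") %in% names(gene2term)))
  parents <- list()
  if (!is.null(term_parents) && nrow(term_parents)) {
    stopifnot(all(c("term", "parent") %in% names(term_parents)))
    parents <- split(as.character(term_parents$parent),
                     as.character(term_parents$term))
  }
  obj <- structure(list(gene2term = gene2term, parents = parents),
                   class = "go_annotation")
  # acyclicity check via full ancestor closure
  for (tm in names(parents)) go_ancestors(obj, tm)
  obj
}

#' Ancestor terms of a GO term (transitive closure, excluding itself)
#' @param ann `go_annotation`
#' @param term term ID
#' @return character vector of ancestor term IDs
#' @export
go_ancestors <- function(ann, term) {
  seen <- character(0)
  stack <- ann$parents[[term]]
  guard <- 0L
  while (length(stack)) {
    guard <- guard + 1L
    if (guard > 1e5) stop("cycle detected in GO DAG near ", term)
    t1 <- stack[[1]]; stack <- stack[-1]
    if (t1 %in% seen) next
    if (t1 == term) stop("cycle detected in GO DAG at ", term)
    seen <- c(seen, t1)
    stack <- c(stack, ann$parents[[t1]])
  }
  seen
}

go_descendants <- function(ann, root) {
  terms <- unique(c(names(ann$parents),
                    unlist(ann$parents, use.names = FALSE),
                    unique(ann$gene2term$term)))
  desc <- terms[vapply(terms, function(tm)
    root %in% go_ancestors(ann, tm), logical(1))]
  unique(c(root, desc))
}

#' Per-category dN/dS distributions
#'
#' Maps each gene's omega onto its annotated terms (propagated to
#' ancestor terms by default) and returns, per term with at least
#' `min_genes` genes, the vector of member-gene omegas.
#'
#' @param gene_omega named numeric vector: gene -> dN/dS
#' @param ann `go_annotation`
#' @param min_genes minimum genes per term (default 5)
#' @param propagate propagate annotations to ancestor terms
#'   (default TRUE)
#' @return named list: term -> named numeric vector of gene omegas
#' @export
category_dnds <- function(gene_omega, ann, min_genes = 5,
                          propagate = TRUE) {
  stopifnot(inherits(ann, "go_annotation"))
  g2t <- ann$gene2term
  if (!nrow(g2t)) stop("empty annotation")
  drop <- setdiff(unique(g2t$gene), names(gene_omega))
  if (length(drop)) {
    warning("annotated genes without omega dropped: ",
            paste(utils::head(drop, 5), collapse = ", "))
    g2t <- g2t[g2t$gene %in% names(gene_omega), , drop = FALSE]
  }
  pairs <- unique(g2t[c("gene", "term")])
  if (propagate) {
    extra <- lapply(seq_len(nrow(pairs)), function(i) {
      anc <- go_ancestors(ann, pairs$term[i])
      if (length(anc))
        data.frame(gene = pairs$gene[i], term = anc)
      else NULL
    })
    pairs <- unique(rbind(pairs, do.call(rbind, extra)))
  }
  byterm <- split(pairs$gene, pairs$term)
  byterm <- lapply(byterm, unique)
  byterm <- byterm[vapply(byterm, length, integer(1)) >= min_genes]
  lapply(byterm, function(gs) gene_omega[gs])
}

#' REGO scan: rank-sum test of each category against the background
#'
#' One-sided (greater) Wilcoxon rank-sum test of each term's member-gene
#' omegas against all genes not in the term; BH-FDR across terms; a term
#' is a REGO when adjusted p < `alpha`.
#'
#' @param cats output of [category_dnds()]
#' @param gene_omega full named gene -> omega vector (the background for
#'   a term is every gene not annotated to it)
#' @param alpha adjusted-p threshold (default 0.05)
#' @return data.frame (`rego_result`): term, n, median_omega, mean_omega,
#'   statistic, p, p_adj, rego
#' @export
rego_scan <- function(cats, gene_omega, alpha = 0.05) {
  stopifnot(length(cats) >= 1)
  rows <- lapply(names(cats), function(tm) {
    v <- cats[[tm]]
    bg <- gene_omega[setdiff(names(gene_omega), names(v))]
    wt <- stats::wilcox.test(v, bg, alternative = "greater",
                             exact = FALSE, correct = TRUE)
    data.frame(term = tm, n = length(v), median_omega = stats::median(v),
               mean_omega = mean(v), statistic = unname(wt$statistic),
               p = wt$p.value)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$rego <- res$p_adj < alpha
  class(res) <- c("rego_result", "data.frame")
  res
}

#' REGOs unique to one group
#'
#' A term is unique to a group when it is a REGO there and in no other
#' group (exclusive significance).
#'
#' @param rego_by_group named list of [rego_scan()] results
#' @return named list: group -> character vector of unique REGO terms
#' @export
rego_unique <- function(rego_by_group) {
  sig <- lapply(rego_by_group, function(r) r$term[r$rego])
  lapply(seq_along(sig), function(i) {
    setdiff(sig[[i]], unlist(sig[-i], use.names = FALSE))
  }) |> stats::setNames(names(rego_by_group))
}

#' Proportion of REGOs under the developmental-process root
#'
#' @param rego [rego_scan()] result (or character vector of REGO terms)
#' @param ann `go_annotation`
#' @param root developmental-process root term ID
#' @return fraction of REGO terms that are the root or its descendants;
#'   NA when there are no REGOs
#' @export
development_proportion <- function(rego, ann, root) {
  terms <- if (is.character(rego)) rego else rego$term[rego$rego]
  if (!length(terms)) return(NA_real_)
  dev <- go_descendants(ann, root)
  mean(terms %in% dev)
}
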