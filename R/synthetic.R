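# Synthetic-data generators: codon and protein alignments evolved along a
# tree, multispecies-coalescent gene trees, alignment corruption (missing
# data, GC bias), and qPCR Ct tables.  Every generator is a deterministic
# function of its inputs and seed; multi-gene simulations derive one seed
# per gene from the root seed by counter.

derive_seed <- function(seed, i) {
  (as.integer(seed) * 1009L + as.integer(i)) %% 2147483587L
}

#' Simulation configuration
#'
#' @param seed integer root seed
#' @param n_genes number of genes for multi-gene simulations
#' @param n_sites sites per gene (codons for the codon generator,
#'   residues for the protein generator)
#' @param kappa transition/transversion ratio
#' @param pi codon frequencies (61, default uniform)
#' @param omega named vector of dN/dS per branch class
#'   (default `c(bg = 0.2)`)
#' @param alpha gamma shape for among-site rate variation
#' @param k gamma categories
#' @param missing_frac fraction of cells knocked out by
#'   [corrupt_alignment()]
#' @param planted list of planted-substitution specs for the protein
#'   generator: each `list(site =, clades = list(<tip label vectors>),
#'   anc =, derived =)`
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1, n_genes = 10, n_sites = 500, kappa = 2,
                       pi = rep(1 / 61, 61), omega = c(bg = 0.2),
                       alpha = 1, k = 4, missing_frac = 0,
                       planted = list()) {
  stopifnot(kappa > 0, alpha > 0, abs(sum(pi) - 1) < 1e-12,
            missing_frac >= 0, missing_frac < 1, all(omega >= 0))
  structure(list(seed = seed, n_genes = n_genes, n_sites = n_sites,
                 kappa = kappa, pi = pi, omega = omega, alpha = alpha,
                 k = k, missing_frac = missing_frac, planted = planted),
            class = "sim_config")
}

# per-edge class labels: tree$edge.class (postorder character vector) or
# "bg" everywhere
edge_classes_of <- function(tp, omega) {
  cls <- tp$phy$edge.class
  if (is.null(cls)) cls <- rep(names(omega)[1], nrow(tp$edge))
  bad <- setdiff(unique(cls), names(omega))
  if (length(bad)) {
    k <- which(cls == bad[1])[1]
    stop("no omega defined for branch class '", bad[1], "' (edge ", k,
         ", child node ", tp$edge[k, 2], ")")
  }
  cls
}

# vectorized endpoint sampling of child states given parent states
evolve_states <- function(parent, P) {
  child <- integer(length(parent))
  for (s in unique(parent)) {
    idx <- which(parent == s)
    child[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  child
}

#' Mark foreground branches on a tree
#'
#' Attaches an `edge.class` vector (postorder) to the tree: the clade
#' spanned by `fg_tips` gets class `"fg"`, everything else `"bg"`.
#'
#' @param phy `phylo`
#' @param fg_tips tips of the foreground clade
#' @param within label edges inside the clade too (default TRUE)
#' @return `phylo` with `edge.class`
#' @export
mark_foreground <- function(phy, fg_tips, within = TRUE) {
  tp <- prep_phylo(phy)
  cls <- foreground_edge_classes(tp$phy, fg_tips, within = within)
  out <- tp$phy
  out$edge.class <- c("bg", "fg")[cls + 1L]
  out
}

#' Simulate a codon alignment along a tree
#'
#' Root codons are drawn from `cfg$pi`; each branch evolves them under the
#' GY94-type model with the branch class's omega (via `tree$edge.class`
#' and `cfg$omega`), using transition matrices exp(Qt).
#'
#' @param tree `phylo` with branch lengths in expected
#'   substitutions/codon; optional `edge.class`
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed` when given
#' @return codon alignment (`aln`) with attribute `node_states`
#'   (internal-node codon indices) for oracle checks
#' @export
simulate_codon_alignment <- function(tree, cfg, seed = cfg$seed) {
  tp <- prep_phylo(tree)
  cls <- edge_classes_of(tp, cfg$omega)
  set.seed(seed)
  codons <- sense_codons()
  eQs <- lapply(cfg$omega, function(w)
    eigen_Q(build_codon_Q(cfg$kappa, w, cfg$pi), cfg$pi))
  L <- cfg$n_sites
  nn <- tp$ntip + tp$nnode
  states <- matrix(NA_integer_, nn, L)
  states[tp$root, ] <- sample.int(61, L, replace = TRUE, prob = cfg$pi)
  E <- tp$edge
  for (k in rev(seq_len(nrow(E)))) { # preorder
    P <- prob_matrix(eQs[[cls[k]]], tp$edge.length[k])
    states[E[k, 2], ] <- evolve_states(states[E[k, 1], ], P)
  }
  m <- matrix(codons[states[seq_len(tp$ntip), ]], tp$ntip, L,
              dimnames = list(tp$tip.label, NULL))
  out <- new_alignment(m, "CODON")
  attr(out, "node_states") <- states
  attr(out, "tree") <- tp$phy
  out
}

#' Simulate a protein alignment along a tree
#'
#' Amino acids evolve under a bundled empirical model (JTT by default)
#' with discrete-gamma site rates; planted substitutions from
#' `cfg$planted` are then applied deterministically (column set to the
#' ancestral residue everywhere, the derived residue in the named clades).
#'
#' @inheritParams simulate_codon_alignment
#' @param model empirical amino-acid model name (see [aa_model()])
#' @param track_events if TRUE, simulate by Gillespie sampling and attach
#'   an `events` matrix (per edge x site substitution counts)
#' @return AA alignment with attributes `node_states`, `site_rates` and
#'   optionally `events`
#' @export
simulate_protein_alignment <- function(tree, cfg, seed = cfg$seed,
                                       model = "JTT",
                                       track_events = FALSE) {
  tp <- prep_phylo(tree)
  mod <- aa_model(model)
  set.seed(seed)
  L <- cfg$n_sites
  rates <- gamma_rates(cfg$alpha, cfg$k)
  site_rate <- rates[sample.int(cfg$k, L, replace = TRUE)]
  nn <- tp$ntip + tp$nnode
  states <- matrix(NA_integer_, nn, L)
  states[tp$root, ] <- sample.int(20, L, replace = TRUE, prob = mod$pi)
  E <- tp$edge
  eQ <- eigen_Q(mod$Q, mod$pi)
  events <- if (track_events) matrix(0, nrow(E), L) else NULL
  for (k in rev(seq_len(nrow(E)))) {
    t_e <- tp$edge.length[k]
    par <- states[E[k, 1], ]
    if (!track_events) {
      for (r in unique(site_rate)) {
        idx <- which(site_rate == r)
        P <- prob_matrix(eQ, t_e * r)
        states[E[k, 2], idx] <- evolve_states(par[idx], P)
      }
    } else {
      ch <- par
      for (i in seq_len(L)) {
        s <- par[i]; tt <- t_e * site_rate[i]
        repeat {
          rate <- -mod$Q[s, s]
          wt <- stats::rexp(1, rate)
          if (wt > tt) break
          tt <- tt - wt
          pr <- mod$Q[s, ]; pr[s] <- 0
          s <- sample.int(20, 1, prob = pr)
          events[k, i] <- events[k, i] + 1
        }
        ch[i] <- s
      }
      states[E[k, 2], ] <- ch
    }
  }
  m <- matrix(mod$states[states[seq_len(tp$ntip), ]], tp$ntip, L,
              dimnames = list(tp$tip.label, NULL))
  for (pl in cfg$planted) {
    stopifnot(pl$site >= 1, pl$site <= L)
    if (pl$anc == pl$derived)
      stop("planted derived residue equals ancestral residue at site ",
           pl$site)
    m[, pl$site] <- pl$anc
    for (cl in pl$clades) {
      miss <- setdiff(cl, tp$tip.label)
      if (length(miss)) stop("unknown planted tips: ",
                             paste(miss, collapse = ", "))
      m[cl, pl$site] <- pl$derived
    }
  }
  out <- new_alignment(m, "AA")
  attr(out, "node_states") <- states
  attr(out, "site_rates") <- site_rate
  attr(out, "tree") <- tp$phy
  if (track_events) attr(out, "events") <- events
  out
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per species; within each species-tree
#' branch (lengths in coalescent units) lineages coalesce at rate
#' choose(k, 2); remaining lineages coalesce freely above the root.
#'
#' @param species_tree rooted `phylo`, branch lengths in coalescent units
#' @param n_genes number of gene trees
#' @param seed root seed; gene `i` uses a derived seed
#' @return list of rooted `phylo` gene trees (branch lengths in
#'   coalescent units)
#' @export
simulate_gene_trees <- function(species_tree, n_genes, seed = 1) {
  stopifnot(inherits(species_tree, "phylo"))
  if (any(species_tree$edge.length < 0)) stop("negative branch lengths")
  tp <- prep_phylo(species_tree)
  E <- tp$edge
  ntip <- tp$ntip
  # node depths (time above root measured downward); heights above tips not
  # needed: we track time within each branch only, and absolute times via
  # node age = distance below root
  lapply(seq_len(n_genes), function(g) {
    set.seed(derive_seed(seed, g))
    msc_one_tree(tp)
  })
}

# single MSC draw; lineages are (gene-tree node id, time), times measured
# as age before present accumulated bottom-up along the species tree
msc_one_tree <- function(tp) {
  E <- tp$edge
  ntip <- tp$ntip
  nn <- ntip + tp$nnode
  # species-node ages (tips at their depth; works for non-ultrametric too:
  # age = root-to-node path length, converted to "time before root")
  depth <- numeric(nn)
  for (k in rev(seq_len(nrow(E))))
    depth[E[k, 2]] <- depth[E[k, 1]] + tp$edge.length[k]
  maxd <- max(depth)
  age <- maxd - depth # time axis increasing toward the root
  # active lineages entering each species node from below
  pend <- vector("list", nn)
  nextid <- ntip + 1L
  merges <- list() # (child1, child2, parent_id, age)
  for (i in seq_len(ntip)) pend[[i]] <- list(list(id = i, age = age[i]))
  coalesce_in <- function(lins, t_from, t_to) {
    # t_to = Inf above the root
    t <- t_from
    while (length(lins) > 1) {
      k <- length(lins)
      wt <- stats::rexp(1, k * (k - 1) / 2)
      if (t + wt > t_to) break
      t <- t + wt
      pick <- sample.int(k, 2)
      a <- lins[[pick[1]]]; b <- lins[[pick[2]]]
      nid <- nextid; nextid <<- nextid + 1L
      merges[[length(merges) + 1L]] <<- list(a = a$id, b = b$id,
                                             p = nid, age = t)
      lins <- c(lins[-pick], list(list(id = nid, age = t)))
    }
    lins
  }
  for (k in seq_len(nrow(E))) { # postorder: child before parent
    ch <- E[k, 2]; par <- E[k, 1]
    out <- coalesce_in(pend[[ch]], age[ch], age[par])
    pend[[par]] <- c(pend[[par]], out)
  }
  coalesce_in(pend[[tp$root]], age[tp$root], Inf)
  # build phylo
  nm <- length(merges)
  edge <- matrix(0L, 2 * nm, 2)
  elen <- numeric(2 * nm)
  node_age <- c(stats::setNames(age[seq_len(ntip)], seq_len(ntip)))
  # gene-tree internal ids run ntip+1 .. ntip+nm; phylo wants root = ntip+1
  ids <- vapply(merges, `[[`, numeric(1), "p")
  ages <- vapply(merges, `[[`, numeric(1), "age")
  remap <- stats::setNames(seq_len(ntip), seq_len(ntip))
  # root is the last merge; order internal nodes by decreasing age so the
  # root gets number ntip+1
  ord <- order(-ages)
  remap[as.character(ids[ord])] <- ntip + seq_len(nm)
  aa <- c(stats::setNames(age[seq_len(ntip)], seq_len(ntip)),
          stats::setNames(ages, ids))
  r <- 0L
  for (mg in merges) {
    for (side in c("a", "b")) {
      r <- r + 1L
      edge[r, 1] <- remap[as.character(mg$p)]
      edge[r, 2] <- remap[as.character(mg[[side]])]
      elen[r] <- mg$age - aa[as.character(mg[[side]])]
    }
  }
  phy <- list(edge = edge, edge.length = elen, Nnode = nm,
              tip.label = tp$tip.label)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "postorder")
}

#' Corrupt an alignment with missing data and GC bias
#'
#' Knocks out an exact fraction of cells (so the realized missing
#' proportion matches the target to rounding) and, for the bias taxa,
#' resamples synonymous third positions toward G/C.
#'
#' @param aln alignment (any alphabet; GC shift needs codon)
#' @param missing_frac fraction of cells set to missing
#' @param bias_taxa taxa receiving the GC shift
#' @param gc_shift nonnegative bias weight: third positions are resampled
#'   within the synonymous codon family with weight `1 + gc_shift` on G/C
#'   endings (0 = no change)
#' @param seed RNG seed
#' @return corrupted alignment
#' @export
corrupt_alignment <- function(aln, missing_frac = 0, bias_taxa = NULL,
                              gc_shift = 0, seed = 1) {
  stopifnot(inherits(aln, "aln"), missing_frac >= 0, missing_frac < 1)
  miss <- setdiff(bias_taxa, aln_taxa(aln))
  if (length(miss)) stop("bias taxa not in alignment: ",
                         paste(miss, collapse = ", "))
  if (missing_frac == 0 && (gc_shift == 0 || is.null(bias_taxa)))
    return(aln)
  set.seed(seed)
  m <- aln$mat
  if (gc_shift > 0 && length(bias_taxa)) {
    if (aln$alphabet != "CODON") stop("GC shift needs a codon alignment")
    code <- .GENETIC_CODE
    for (tx in bias_taxa) {
      row <- m[tx, ]
      for (j in which(!is.na(row))) {
        cod <- row[j]
        fam <- paste0(substr(cod, 1, 2), c("T", "C", "A", "G"))
        fam <- fam[!is.na(code[fam]) & code[fam] == code[cod]]
        if (length(fam) < 2) next
        wgt <- ifelse(substr(fam, 3, 3) %in% c("G", "C"),
                      1 + gc_shift, 1)
        row[j] <- sample(fam, 1, prob = wgt)
      }
      m[tx, ] <- row
    }
  }
  if (missing_frac > 0) {
    ncell <- length(m)
    k <- round(missing_frac * ncell)
    m[sample.int(ncell, k)] <- NA
  }
  new_alignment(m, aln$alphabet)
}

#' Simulate a qPCR Ct table
#'
#' Generates technical-replicate Ct values for target genes and a
#' reference gene so that the target's delta-Ct relative to the reference
#' encodes log2(1 / fold-change) plus Gaussian noise.
#'
#' @param truth data.frame with columns `gene`, `time`, `fold`
#'   (fold-change relative to the baseline time; the baseline rows must
#'   have fold 1)
#' @param reference name of the reference gene (fold 1 at all times);
#'   added automatically
#' @param bio_reps biological replicates per time point (default 3)
#' @param tech_reps technical replicates per biological replicate
#' @param noise_sd Gaussian Ct noise (cycles)
#' @param fail_rate probability a well fails (recorded as NA)
#' @param base_ct reference-gene baseline Ct
#' @param offset target-vs-reference baseline delta-Ct
#' @param seed RNG seed
#' @return data.frame (`ct_table`): gene, time, bio_rep, tech_rep, ct
#' @export
make_qpcr_table <- function(truth, reference = "ACTIN", bio_reps = 3,
                            tech_reps = 3, noise_sd = 0.2,
                            fail_rate = 0, base_ct = 15, offset = 5,
                            seed = 1) {
  stopifnot(all(c("gene", "time", "fold") %in% names(truth)),
            all(truth$fold > 0))
  if (bio_reps < 2)
    warning("fewer than 2 biological replicates: significance untestable")
  set.seed(seed)
  times <- sort(unique(truth$time))
  genes <- unique(truth$gene)
  rows <- list()
  emit <- function(gene, time, mu) {
    for (b in seq_len(bio_reps)) {
      bshift <- stats::rnorm(1, 0, noise_sd)
      for (tr in seq_len(tech_reps)) {
        ct <- mu + bshift + stats::rnorm(1, 0, noise_sd / 2)
        if (fail_rate > 0 && stats::runif(1) < fail_rate) ct <- NA
        rows[[length(rows) + 1L]] <<- data.frame(
          gene = gene, time = time, bio_rep = b, tech_rep = tr, ct = ct)
      }
    }
  }
  for (tm in times) {
    emit(reference, tm, base_ct)
    for (g in genes) {
      fold <- truth$fold[truth$gene == g & truth$time == tm]
      if (!length(fold)) stop("no fold for ", g, " at time ", tm)
      emit(g, tm, base_ct + offset + log2(1 / fold))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ct_table", "data.frame")
  out
}
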