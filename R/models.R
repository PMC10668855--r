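# Substitution-model machinery: rate-matrix construction for nucleotide GTR,
# GY94-type codon models, and empirical amino-acid models; reversible-matrix
# eigendecomposition and transition probabilities; discrete-gamma rates.

#' GTR rate matrix
#'
#' @param rates numeric(6): exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT (the last is conventionally fixed to 1).
#' @param pi base frequencies, order A C G T, summing to 1.
#' @return 4x4 rate matrix (rows sum to 0) scaled to one expected
#'   substitution per site per unit time.
#' @export
build_gtr_Q <- function(rates = rep(1, 6), pi = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(pi) == 4, abs(sum(pi) - 1) < 1e-9)
  R <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  R[1, 2] <- rates[1]; R[1, 3] <- rates[2]; R[1, 4] <- rates[3]
  R[2, 3] <- rates[4]; R[2, 4] <- rates[5]; R[3, 4] <- rates[6]
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale_Q(Q, pi)
}

#' GY94-type codon rate matrix
#'
#' Single-nucleotide changes only; rate to codon j proportional to its
#' frequency `pi[j]`, multiplied by `kappa` for transitions and by `omega`
#' for nonsynonymous changes.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0)
#' @param pi 61-vector of sense-codon frequencies summing to 1
#' @param scale if `TRUE` (default) scale to one expected substitution per
#'   codon per unit time; pass `FALSE` to keep the raw parameterization
#'   (used when several branch classes must share a common time scale).
#' @return 61x61 rate matrix with codon dimnames.
#' @export
build_codon_Q <- function(kappa, omega, pi = rep(1 / 61, 61), scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61,
            abs(sum(pi) - 1) < 1e-9)
  tab <- std_codon_table()
  n <- length(tab$codons)
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  Q[tab$single] <- 1
  Q[tab$single & tab$transition] <- kappa
  Q[tab$single & !tab$synonymous] <-
    Q[tab$single & !tab$synonymous] * omega
  Q <- Q * rep(pi, each = n)
  diag(Q) <- -rowSums(Q)
  if (scale) scale_Q(Q, pi) else Q
}

#' Empirical amino-acid model
#'
#' Returns the exchangeability-based rate matrix and equilibrium
#' frequencies of a bundled empirical model (taken at run time from the
#' phangorn package's model data).
#'
#' @param model model name, currently `"JTT"` (default) or `"WAG"`.
#' @param pi optional replacement equilibrium frequencies (length 20, +F
#'   style); defaults to the model's own frequencies.
#' @return list with `Q` (20x20 rate matrix, scaled to 1 expected
#'   substitution/site/unit time), `pi`, and `states` (one-letter codes in
#'   the order used by `Q`).
#' @export
aa_model <- function(model = c("JTT", "WAG"), pi = NULL) {
  model <- match.arg(model)
  obj <- get(paste0(".", model), envir = asNamespace("phangorn"))
  bf <- obj$bf
  states <- toupper(names(bf))
  if (is.null(pi)) pi <- as.numeric(bf) else stopifnot(length(pi) == 20)
  pi <- pi / sum(pi)
  n <- 20
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(states, states)
  list(Q = scale_Q(Q, pi), pi = stats::setNames(pi, states),
       states = states)
}

# scale a rate matrix so the expected substitution rate at stationarity is 1
scale_Q <- function(Q, pi) {
  mu <- -sum(pi * diag(Q))
  Q / mu
}

#' Eigendecomposition of a reversible rate matrix
#'
#' Decomposes via the symmetrized form so that transition matrices
#' P(t) = exp(Qt) can be computed cheaply for many t.
#'
#' @param Q reversible rate matrix
#' @param pi its stationary distribution
#' @return list usable by [prob_matrix()]
#' @export
eigen_Q <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d)) # diag(d) %*% Q %*% diag(1/d), but B_ij = d_i q_ij / d_j
  B <- (B + t(B)) / 2 # symmetrize against round-off
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       right = e$vectors / d, # diag(1/d) %*% U
       left = t(e$vectors * d), # t(U) %*% diag(d)
       pi = pi)
}

#' Transition probability matrix from a cached eigendecomposition
#' @param eQ result of [eigen_Q()]
#' @param t branch length (expected substitutions per site), t >= 0
#' @return stochastic matrix P(t)
#' @export
prob_matrix <- function(eQ, t) {
  P <- eQ$right %*% (exp(eQ$vals * t) * eQ$left)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate categories (median method)
#'
#' @param alpha gamma shape (> 0); the scale is 1/alpha so the mean is 1.
#' @param k number of equal-probability categories
#' @return numeric(k) category rates, normalized to mean exactly 1.
#' @export
gamma_rates <- function(alpha, k = 4) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha,
                     rate = alpha)
  r / mean(r)
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies multiplied across the three
#' codon positions, restricted to sense codons and renormalized.
#'
#' @param aln codon alignment
#' @return 61-vector of codon frequencies
#' @export
f3x4_frequencies <- function(aln) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "CODON")
  obs <- aln$mat[!is.na(aln$mat)]
  if (!length(obs)) stop("empty alignment")
  nuc <- c("T", "C", "A", "G")
  f <- sapply(1:3, function(p) {
    tab <- table(factor(substr(obs, p, p), levels = nuc))
    as.numeric(tab) / sum(tab)
  })
  # guard against unobserved states
  f <- apply(f, 2, function(v) (v + 1e-6) / sum(v + 1e-6))
  codons <- sense_codons()
  pi <- vapply(codons, function(cd) {
    prod(f[cbind(match(strsplit(cd, "")[[1]], nuc), 1:3)])
  }, numeric(1))
  pi / sum(pi)
}
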