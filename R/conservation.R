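# Per-site conservation scoring (Rate4Site-style empirical Bayes under
# discrete-gamma rates) and cubic smoothing-spline profile smoothing.

#' Per-site conservation scores
#'
#' For each site, the posterior-mean substitution rate over `k` gamma
#' categories at the fixed tree is computed by empirical Bayes:
#' rbar_i = sum_c r_c P(data_i | r_c) P(r_c) / P(data_i).  Raw rates are
#' z-normalized across sites and multiplied by -1 so that higher scores
#' mean higher conservation.
#'
#' @param aln AA alignment
#' @param tree `phylo` with branch lengths, leaf set = alignment taxa
#' @param model empirical amino-acid model (see [aa_model()])
#' @param alpha gamma shape (default 1)
#' @param k gamma categories for scoring (default 16; finer than the
#'   4 used in likelihood fitting)
#' @return list of class `conservation_profile`: `rate` (posterior-mean
#'   rate), `normalized` (mean 0, sd 1), `conservation` (sign-flipped
#'   normalized score), all length = sites; all-gap sites are NA.
#' @export
site_conservation_scores <- function(aln, tree, model = "JTT",
                                     alpha = 1, k = 16) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "AA")
  tp <- prep_phylo(tree, aln_taxa(aln))
  mod <- aa_model(model)
  m <- aln$mat[tp$tip.label, , drop = FALSE]
  allgap <- colSums(!is.na(m)) == 0
  cp <- compress_patterns(m)
  tips <- tip_partials(new_alignment(m[, cp$cols, drop = FALSE], "AA"),
                       mod$states)
  rates <- gamma_rates(alpha, k)
  eQ <- eigen_Q(mod$Q, mod$pi)
  ne <- nrow(tp$edge)
  ll <- vapply(rates, function(r) {
    P <- lapply(seq_len(ne), function(e)
      prob_matrix(eQ, tp$edge.length[e] * r))
    engine_down(tp, tips, P, mod$pi)$pattern_loglik
  }, numeric(length(cp$cols)))
  if (length(cp$cols) == 1) ll <- matrix(ll, 1, k)
  mx <- apply(ll, 1, max)
  lik <- exp(ll - mx)
  w <- rep(1 / k, k)
  postw <- lik * rep(w, each = nrow(lik))
  postw <- postw / rowSums(postw)
  rbar <- as.vector(postw %*% rates)[cp$index]
  rbar[allgap] <- NA
  mu <- mean(rbar, na.rm = TRUE)
  sg <- stats::sd(rbar, na.rm = TRUE)
  normalized <- if (isTRUE(sg > 0)) (rbar - mu) / sg else rbar * 0
  structure(list(rate = rbar, normalized = normalized,
                 conservation = -normalized),
            class = "conservation_profile")
}

#' Natural cubic smoothing spline (direct penalized solve)
#'
#' Minimizes sum (y_i - f(x_i))^2 + lambda int f''(t)^2 dt over natural
#' cubic splines with knots at the data points, via the banded
#' Green-Silverman system fhat = (I + lambda K)^-1 y with
#' K = t(D) W^-1 D.  Smoothing is chosen by generalized cross-validation
#' unless `lambda` or `df` is given.
#'
#' @param x ordered distinct abscissae
#' @param y responses
#' @param lambda fixed penalty (optional)
#' @param df target effective degrees of freedom (optional; solved by
#'   root-finding on the hat-matrix trace)
#' @return list: `fitted`, `lambda`, `df` (trace of the hat matrix)
#' @export
smoothing_spline <- function(x, y, lambda = NULL, df = NULL) {
  stopifnot(length(x) == length(y), !is.unsorted(x),
            !anyDuplicated(x), length(x) >= 4)
  n <- length(x)
  h <- diff(x)
  D <- matrix(0, n - 2, n)
  W <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -(1 / h[i] + 1 / h[i + 1])
    D[i, i + 2] <- 1 / h[i + 1]
    W[i, i] <- (h[i] + h[i + 1]) / 3
    if (i > 1) {
      W[i, i - 1] <- W[i - 1, i] <- h[i] / 6
    }
  }
  K <- crossprod(D, solve(W, D))
  solve_l <- function(l) {
    A <- diag(n) + l * K
    Ainv <- solve(A)
    list(fitted = as.vector(Ainv %*% y), trace = sum(diag(Ainv)))
  }
  if (is.null(lambda) && !is.null(df)) {
    f <- function(loglam) solve_l(exp(loglam))$trace - df
    lambda <- exp(stats::uniroot(f, c(-20, 25))$root)
  }
  if (is.null(lambda)) {
    gcv <- function(loglam) {
      s <- solve_l(exp(loglam))
      rss <- sum((y - s$fitted)^2)
      n * rss / (n - s$trace)^2
    }
    o <- stats::optimize(gcv, c(-10, 20))
    lambda <- exp(o$minimum)
  }
  s <- solve_l(lambda)
  list(fitted = s$fitted, lambda = lambda, df = s$trace)
}

#' Smooth a conservation profile
#'
#' Fits a cubic smoothing spline to the per-site scores; NA sites are
#' linearly interpolated before fitting and flagged in the output.
#'
#' @param scores numeric vector (e.g. the `conservation` component of
#'   [site_conservation_scores()])
#' @param df fixed effective degrees of freedom; NULL (default) selects
#'   smoothing by GCV
#' @return list: `smoothed` (same length as input), `interpolated`
#'   (logical), `lambda`, `df`
#' @export
smooth_profile <- function(scores, df = NULL) {
  ok <- !is.na(scores)
  if (sum(ok) < 10) stop("need at least 10 non-NA sites")
  x <- seq_along(scores)
  y <- scores
  if (any(!ok))
    y[!ok] <- stats::approx(x[ok], scores[ok], xout = x[!ok],
                            rule = 2)$y
  if (stats::sd(y) < 1e-12) {
    return(list(smoothed = y, interpolated = !ok, lambda = Inf,
                df = 1))
  }
  s <- smoothing_spline(x, y, df = df)
  list(smoothed = s$fitted, interpolated = !ok, lambda = s$lambda,
       df = s$df)
}
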