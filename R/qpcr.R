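# qPCR relative quantification: the delta-delta-Ct (2^-ddCt) method with
# reference-gene normalization, and per-time-point significance vs the
# baseline on delta-Ct values.

#' Relative quantification by the delta-delta-Ct method
#'
#' Technical replicates are averaged within (gene, time, biological
#' replicate); delta-Ct = Ct_target - Ct_reference per biological
#' replicate; delta-delta-Ct = mean delta-Ct(t) - mean delta-Ct(baseline);
#' RQ = 2^-ddCt.  Failed wells (NA Ct) are dropped before averaging.
#'
#' @param ct data.frame with columns gene, time, bio_rep, tech_rep, ct
#'   (NA = failed well), e.g. from [make_qpcr_table()]
#' @param reference reference gene name (default "ACTIN")
#' @param baseline_time baseline time point (default the smallest)
#' @return data.frame (`rq_result`): gene, time, n_reps, delta_ct,
#'   ddct, rq, sd_delta_ct; attribute `delta_ct` keeps the per-bio-rep
#'   delta-Ct table for significance testing
#' @export
relative_quantification <- function(ct, reference = "ACTIN",
                                    baseline_time = NULL) {
  stopifnot(all(c("gene", "time", "bio_rep", "tech_rep", "ct")
                %in% names(ct)))
  if (!reference %in% ct$gene)
    stop("reference gene '", reference, "' absent from the table")
  if (is.null(baseline_time)) baseline_time <- min(ct$time)
  if (!baseline_time %in% ct$time) stop("baseline time not present")
  ok <- !is.na(ct$ct)
  tech <- stats::aggregate(ct ~ gene + time + bio_rep,
                           data = ct[ok, , drop = FALSE], FUN = mean)
  refs <- tech[tech$gene == reference, c("time", "bio_rep", "ct")]
  names(refs)[3] <- "ct_ref"
  targ <- tech[tech$gene != reference, , drop = FALSE]
  dct <- merge(targ, refs, by = c("time", "bio_rep"))
  dct$delta_ct <- dct$ct - dct$ct_ref
  rows <- list()
  for (g in unique(targ$gene)) {
    dg <- dct[dct$gene == g, , drop = FALSE]
    base <- dg$delta_ct[dg$time == baseline_time]
    if (!length(base)) {
      warning("no baseline reference pairs for gene ", g)
      next
    }
    for (tm in sort(unique(targ$time[targ$gene == g]))) {
      v <- dg$delta_ct[dg$time == tm]
      if (!length(v)) {
        warning("no usable wells for ", g, " at time ", tm)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, time = tm, n_reps = 0L, delta_ct = NA_real_,
          ddct = NA_real_, rq = NA_real_, sd_delta_ct = NA_real_)
        next
      }
      dd <- mean(v) - mean(base)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, time = tm, n_reps = length(v), delta_ct = mean(v),
        ddct = dd, rq = 2^(-dd),
        sd_delta_ct = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rq_result", "data.frame")
  attr(out, "delta_ct") <- dct
  attr(out, "baseline_time") <- baseline_time
  out
}

#' Per-time-point significance vs the baseline
#'
#' Welch two-sided t-test on per-biological-replicate delta-Ct values of
#' each time point against the baseline, BH-adjusted across time points
#' within each gene.
#'
#' @param rq [relative_quantification()] result
#' @return data.frame: gene, time, p, p_adj (baseline rows NA)
#' @export
timecourse_significance <- function(rq) {
  dct <- attr(rq, "delta_ct")
  baseline <- attr(rq, "baseline_time")
  stopifnot(!is.null(dct), !is.null(baseline))
  rows <- list()
  for (g in unique(dct$gene)) {
    dg <- dct[dct$gene == g, , drop = FALSE]
    base <- dg$delta_ct[dg$time == baseline]
    for (tm in setdiff(sort(unique(dg$time)), baseline)) {
      v <- dg$delta_ct[dg$time == tm]
      p <- if (length(v) < 2 || length(base) < 2) {
        warning("fewer than 2 replicates for ", g, " at time ", tm)
        NA_real_
      } else if (stats::sd(v) == 0 && stats::sd(base) == 0) {
        if (isTRUE(all.equal(mean(v), mean(base)))) 1 else 0
      } else {
        stats::t.test(v, base)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(gene = g, time = tm,
                                              p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (g in unique(out$gene)) {
    sel <- out$gene == g
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], "BH")
  }
  out
}
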