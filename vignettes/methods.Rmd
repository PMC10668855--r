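---
title: "Models and methods behind amphievo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amphievo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`amphievo` re-implements, as a tested desk-scale pipeline, the comparative
molecular-evolution workflow used to contrast amphibian lineages (and, by
extension, any set of one-to-one vertebrate orthologs): supermatrix quality
filtration, support testing of fixed species-tree hypotheses, lineage-specific
dN/dS selection scans, rapidly evolving GO-category detection,
parallel-substitution analysis, per-site conservation profiling, and qPCR
relative quantification.  This vignette records the models, the numerical
choices, and the limits of what a green test establishes.

## Likelihood machinery

All likelihood computations share one Felsenstein pruning engine operating on
`ape` trees, with per-pattern log-scaling and alignment-pattern compression.
Three substitution processes are built on it:

* **Nucleotide GTR+Γ** — exchangeabilities relative to GT = 1, empirical base
  frequencies, discrete gamma with `k = 4` equal-probability categories
  discretized by category medians and renormalized to mean 1.
* **Codon GY94-type** — single-nucleotide changes only, rate to codon *j*
  proportional to π<sub>j</sub>, × κ for transitions, × ω for nonsynonymous
  changes; frequencies are F3x4 computed from the alignment (the common
  CODEML default; the source analyses do not state their choice).
* **Amino acid** — JTT exchangeabilities with model frequencies and
  discrete-gamma rates.  The JTT numbers are read at run time from the
  installed `phangorn` package rather than shipped as a data file; the
  numerical content is identical.

Branch lengths are optimized coordinate-wise by Brent line search using the
up–down ("two-pass") decomposition, so each branch's conditional likelihood
curve costs one edge, not one full pruning.  A sweep proposes all updates
jointly and is accepted only if the total log-likelihood improves, falling
back to sequential refits otherwise.  Model parameters (κ, ω per class, the
gamma shape, GTR rates) are optimized by bounded Brent passes, two to three
full passes by default, with a line-search tolerance of about 3 × 10⁻³ on the
transformed parameter — loose enough to be fast, tight enough that
likelihood-ratio statistics move by well under 0.05 log-units.

**Rate-matrix gauges.**  For branch models each class's rate matrix is scaled
to one expected substitution per codon, so branch lengths are in
substitutions/codon (the PAML convention).  The branch-site mixture instead
scales every class by the ω = 1 substitution rate (a "neutral gauge"): with
per-class scaling an elevated ω would only reshuffle relative rates, while in
the neutral gauge it genuinely accelerates foreground evolution, and the null
(ω₂ = 1) remains exactly nested in the alternative.

**dN/dS decomposition.**  Per branch, dS = t·ρ<sub>S</sub>/(3p<sub>S</sub>)
and dN = t·ρ<sub>N</sub>/(3p<sub>N</sub>), where ρ are the synonymous and
nonsynonymous fractions of substitution flow at the MLEs and p the same
fractions computed at ω = 1 (the mutational-opportunity proportions).  This
reproduces the standard PAML-style definitions and gives dN/dS = ω exactly.

## Selection scans

* **FEG scan** — one-ratio null vs multi-ratio alternative (separate
  foreground ω), χ² LRT with df = extra ω parameters, Benjamini–Hochberg FDR
  across genes; a gene is called fast-evolving only when additionally
  ω_fg > ω_bg.  BH was chosen because the source describes only "the FDR
  method".
* **PSG scan** — branch-site Model A with four site classes
  (ω₀, 1, ω₀/ω₂, 1/ω₂ on background/foreground) and the proportion
  parameterization p₀ = wq, p₁ = w(1−q).  The null fixes ω₂ = 1; the LRT uses
  χ²(1), the conservative applied choice rather than the 50:50 boundary
  mixture.  The null is fitted first and the alternative is warm-started from
  it, which guarantees a non-negative LRT up to line-search tolerance and
  equalizes optimization effort between the two hypotheses — fitting the
  models independently in either order can otherwise produce spurious
  negative or inflated statistics.  Per-site posteriors for the selected
  class are **naive empirical Bayes** values at the MLEs; they are not BEB
  probabilities and are never labelled as such.
* **Group means** — terminal-branch ω averaged within groups after excluding
  values above 5 (the stated abnormal-value rule), with per-group
  distributions exported for one-sided rank-sum contrasts.
* **4D rates** — third positions of codon columns whose family is 4-fold
  degenerate and whose first two positions are conserved across taxa; GTR
  branch lengths on these sites estimate per-branch neutral rates.

## Topology testing and supertrees

Five (or any number of) candidate hypotheses are evaluated as **fixed, fully
resolved topologies**: GTR+Γ is re-fitted per topology (branch lengths
re-optimized — the more conservative reading of the per-gene workflow) and
per-site log-likelihoods are compared by the approximately-unbiased test:
multiscale RELL resampling over ten scale factors 0.5–1.4, normal-quantile
transform of the bootstrap proportions, weighted least-squares fit of signed
distance and curvature, p = 1 − Φ(d − c).  Resampling is keyed to a canonical
site order so p-values are invariant to column permutation.  Note that
hypotheses identical as *unrooted* topologies are indistinguishable to a
reversible model and receive equal support by construction.

Two supertree methods consume gene trees: **GAC parsimony**, where each gene
is one multistate character whose step matrix is the nodal (edge-count)
distance between tips in that gene's tree, scored by Sankoff dynamic
programming (the cited method does not restate its step metric; nodal
distance is this package's documented choice), searched exhaustively up to 7
taxa and by NNI hill-climbing beyond, ties broken by lexicographic Newick
order; and **MP-EST-style pseudo-likelihood**, scoring rooted-triplet counts
with P(concordant) = 1 − (2/3)e^(−t), internal branch lengths bounded at 10
coalescent units (full concordance drives t̂ to the cap, which is reported,
not hidden).

## Synthetic data: the stated world

The generators default to 10 taxa and 500 codons per gene — conventions for a
transcriptome-derived amphibian ortholog set, not values stated by the source
study — with κ = 2, background ω = 0.2, gamma shape α = 1, and uniform codon
frequencies.  Gene trees are drawn under the standard multispecies
coalescent.  Missing data are knocked out cell-wise to an exact fraction;
compositional bias is injected by resampling synonymous third positions
toward G/C in selected taxa, which perturbs composition without touching the
protein.  Planted parallel substitutions are applied deterministically after
simulation (column forced to the ancestral residue, derived residue in the
named clades), so downstream recovery tests have exact ground truth.  Every
generator is a pure function of (inputs, seed); multi-gene runs derive one
seed per gene by counter.

What the generators do **not** emulate: indels and alignment error, assembly
artifacts, paralogy leakage, codon-usage selection, and site-heterogeneous
amino-acid profiles.  A green calibration test therefore establishes
correctness of the statistics under the assumed models, not robustness to
real-data pathologies.

## QC statistics

Completeness is the non-missing cell fraction; RCFV is the mean absolute
deviation of per-taxon state frequencies from the across-taxa mean; the
chi-square test compares each taxon's counts to pooled expectations (states
with zero expectation dropped, df adjusted, flag at p < 0.01); SRH violations
are detected by Bowker's matched-pairs test on pairwise divergence matrices
(df = number of off-diagonal state pairs observed).  The gene filter applies
the retained-range thresholds (completeness ≥ 0.7, RCFV < 0.025 by default)
plus a configurable per-gene Bowker rule — a gene is flagged when more than
half its taxon pairs violate at p < 0.05; the source does not state how
pairwise results translated into gene removal, so this rule is explicitly a
package convention.  The quartet-geometry information content of the original
filtering tool is *not* reimplemented; the package reports the fraction of
parsimony-informative sites under a distinct name instead.

## Parallel evolution

Ancestral states are marginal posteriors from the up–down algorithm under
JTT+Γ.  Group-shared changes require every group member to carry the same
residue and the group-MRCA's parent to reconstruct a different residue with
posterior ≥ 0.7 (threshold unstated in the source; 0.7 is the package
default, configurable).  Two-lineage coincidences are classified by the
stated rule — same derived and same ancestral residue ⇒ parallel, different
derived residues ⇒ common; same derived residue from different ancestors is
excluded with a logged reason.  The chance expectation of parallel
coincidences places nA and nB substitutions uniformly over L sites and uses
the empirical model's one-step distribution for the derived residue
(uniform-over-19 available as a sensitivity option); the p-value is the
Poisson upper tail.  Equivalence with the historical CONVERG2 program is not
claimed.

## Conservation profiles and smoothing

Per-site rates are empirical-Bayes posterior means over k = 16 discrete-gamma
categories at fixed branch lengths (finer than the k = 4 used in fitting —
a precision/speed trade-off), z-normalized and multiplied by −1 so larger
means more conserved.  Smoothing uses a natural cubic smoothing spline solved
directly from the Green–Silverman penalized system, with λ selected by
generalized cross-validation by default (the original workflow's smoothing
parameter is unstated); missing sites are linearly interpolated and flagged.

## qPCR quantification

Technical replicates are averaged first, then ΔCt is computed per biological
replicate against the reference gene, ΔΔCt against the baseline time, and
RQ = 2^−ΔΔCt.  Significance uses Welch t-tests on per-replicate ΔCt values
(approximately normal; the ratio scale is not), BH-adjusted across time
points within each gene.  The source describes three replicates per time
point in its methods and two biological × three technical in its figure
caption; the table format supports both layouts.

## Known limitations

* No indel handling; alignments are assumed site-homologous.
* Branch-site power at desk scale is modest (short foreground branches,
  ≤ a few hundred codons); the calibration tests bound the false-positive
  rate, not the discovery rate.
* The AU test inherits RELL's fixed-parameter approximation; per-gene model
  re-fitting is per topology but not per bootstrap replicate.
* MP-EST branch lengths at the concordance boundary are reported at the cap.
* Naive empirical-Bayes site posteriors understate uncertainty relative to
  BEB when parameter estimates are poor.
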