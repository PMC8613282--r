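---
title: "Models and methods behind replistress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replistress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replistress)
```

# Scope

`replistress` implements the computational side of a common experimental
design in replication-stress pharmacology: a tumour cell line (here,
ALK/MYCN-driven neuroblastoma) is treated with an ATR kinase inhibitor, and
the response is read out by RNA-seq, total proteomics, TMT phosphoproteomics,
viability dose-response assays, and tumour growth in mice. The package covers
everything downstream of quantification: differential testing with a
hyperbolic significance surface, S/TQ (PIKK substrate) motif enrichment,
gene-set and network enrichment, and pharmacodynamic summaries (IC50,
combination index, tumour growth inhibition). Raw spectrum identification,
read alignment and identifier mapping are out of scope; inputs are plain
quantified tables (TSV), gene sets (GMT), protein sequences (FASTA) and
STRING-style edge lists.

Because the real inputs are large external downloads, the package ships a
synthetic-data module that generates every input type with planted ground
truth. All statements below about recovery and calibration are properties the
test suite actually computes on those synthetic inputs.

# Differential testing

## The per-feature test

`fit_differential()` uses a deliberately transparent estimator: a per-feature
Welch (unequal-variance) two-sample *t*-test on log2 values, with
Benjamini-Hochberg correction (`bh_adjust()`, a validating wrapper around
`stats::p.adjust`). For phosphosite or protein intensities the input is the
total-signal-normalised matrix on the log2 scale; for counts the matrix is
first transformed as follows.

Library sizes are estimated by **median-of-ratios size factors** (the
estimator popularised by count-based differential-expression packages):
each sample's factor is the median across features of its ratio to the
per-feature geometric mean, and counts are divided by the factor before a
`log2(x + 0.5)` transform. We use this rather than plain total-count
scaling because total counts are not robust to strong asymmetric effects:
when planted up-effects (e.g. 4-fold) add more library mass than the
down-effects remove, total-count scaling shifts every null feature by about
-0.5 log2 units and the observed false-discovery rate roughly triples. With
median-of-ratios factors the synthetic-null p-values are uniform
(Kolmogorov-Smirnov check in the suite) and the observed FDR stays below
1.5x the nominal level while sensitivity for planted |log2FC| >= 2 effects
at five replicates per arm exceeds 0.99.

The estimator is intentionally simpler than moderated frameworks
(no dispersion shrinkage, no empirical-Bayes pooling — those are explicit
non-goals): downstream stages only consume `(log2fc, padj)`, and the
simpler test makes every number in the output reproducible by hand.
Zero-variance features get p = 1 (never NaN) so BH stays well defined; the
signed statistic keeps the sign of the fold change.

## The hyperbolic significance surface

Rectangular volcano-plot cuts (|log2FC| above a threshold *and* adjusted p
below a threshold) admit features that barely clear both. The hyperbolic
surface instead requires, at fold change magnitude $x$,

$$-\log_{10} p_{adj} \;\ge\; -\log_{10} p_{TH} \;+\;
\frac{c}{\sqrt{x^2 - x_{TH}^2}}, \qquad x > x_{TH},$$

so the significance requirement grows without bound as $x \to x_{TH}^+$ and
relaxes to the plain $p_{TH}$ cut as $x \to \infty$. The labelled set is
therefore always a subset of the rectangular set (a property test in the
suite). Two presets match the study conventions: genes
$(p_{TH}, x_{TH}, c) = (0.01, 1.5, 0.5)$ and phosphosites/proteins
$(0.05, 0.3, 0.5)$; $c = 0.5$ is shared because the source analysis states
the curve parameter once.

Two sign/edge conventions are fixed here deliberately. First, the equation
is applied on the $-\log_{10}$ scale as written above; applied literally on
the $\log_{10}$ scale a positive added term would *loosen* the cut near the
asymptote, which contradicts the purpose of the curve. Second, comparisons
are strict (`>`) on |log2FC| and inclusive (`>=`) on the boundary, so a
feature exactly at the fold-change threshold is never significant (the
boundary diverges there). Convergence of the boundary to $p_{TH}$ is
checked on the adjusted-p scale, where the residual $c/x$ term is
negligible by |log2FC| = 50; on the $-\log_{10}$ scale the residual is
exactly $c/\sqrt{x^2 - x_{TH}^2} \approx 0.01$ at $x = 50$, which is worth
knowing when reading volcano plots near the tail.

# S/TQ motif analysis

Phosphosites are represented by 11-residue windows (positions -5..+5,
`'-'`-padded at protein termini, so window construction never fails). The
S/TQ call is: centre residue S or T **and** Q at position +1 — the canonical
ATM/ATR (PIKK) substrate signature; tyrosine sites are never S/TQ. The
motif definition is read as "Q at +1" because that is the universal PIKK
substrate motif; the call is invariant to how much flanking context exists
beyond +1.

Enrichment between response classes (hypo-/hyperphosphorylated vs
non-responding background) uses Fisher's exact test with the p-value
computed by direct hypergeometric enumeration: the two-sided p is the sum of
all table probabilities at the observed margins not exceeding the observed
table's probability (the classical convention; sidedness is not stated in
the source analysis, and the classical two-sided sum is what
`stats::fisher.test` reports, which the suite uses as an independent
oracle). The odds ratio is the sample cross-product $(ad)/(bc)$ with the
convention 0 when $a = 0$ and $\infty$ when $bc = 0, ad > 0$ — not the
conditional MLE. The per-position residue enrichment (sequence-logo style)
uses one-sided overrepresentation tests across the 10 flanking positions
x 20 residues grid with BH correction across all 200 cells; the phosphosite
position itself is excluded, and pad characters never enter the counts.

The exhaustive correctness check enumerates **all** 316,251 contingency
tables with total count <= 50 against an independent `lchoose`-based
enumeration (agreement to 1e-12), plus a spot-check against
`stats::fisher.test`.

# Gene-set enrichment

`preranked_gsea()` implements the weighted Kolmogorov-Smirnov running-sum
statistic with weight exponent 1: walking down the ranking, member features
increment the sum by |metric|/NR (NR = sum of member |metric|) and
non-members decrement by 1/(N - m); the enrichment score is the extremum.
The null is classical **gene-label permutation** with a configurable
permutation count (default 10,000; at least 100 enforced) — not the
adaptive multilevel scheme of production GSEA tools, which trades
transparency for speed on extreme p-values. P-values are sign-stratified
(an observed ES is compared only to permuted scores of the same sign) with
add-one smoothing, so they saturate at 1/(n+1) and are reported as bounds;
NES divides ES by the mean same-sign |permuted ES|, the classical
normalisation. The suite checks the hand-computable worked example
(metrics 5..1, set at ranks {1,3}, ES = 2/3), sign antisymmetry under
ranking complementation, bitwise reproducibility under a fixed seed,
agreement of the ES with `fgsea::calcGseaStat`, and uniformity of the
permutation p under a null set (KS test over 500 repetitions).

`fisher_gsea()` is the unranked mode: one-sided overrepresentation of a
selected feature list in each set, against a stated universe (defaulting to
all quantified features — the appropriate universe for phosphoproteomics,
where only ~4,000 proteins are observed), BH-corrected across sets. Sets
are intersected with the universe; preranked sets outside a configurable
size range (default at least 2 members present) are skipped with a warning.

# Interaction subnetworks

Edges come in on either the unit or the STRING-download thousand scale —
the dialect is an explicit flag, never auto-detected, because 0.7 on the
wrong scale silently empties the network. `filter_high_confidence()` keeps
combined scores **strictly** above 0.7. `first_degree_subnetwork()` returns
the subgraph **induced** on seeds plus direct neighbours: edges among
non-seed neighbours are retained when both endpoints are in the node set.
The figure convention in the source analysis is ambiguous between this and
a star around seeds; the induced subgraph is chosen because it is what the
upstream resource's own viewers draw. Properties tested: idempotence,
monotonicity in the score cutoff, and seed-adjacency of every node against
a brute-force neighbour scan.

# Pharmacodynamics

Caliper volume is $V = (\pi/6) L W^2$ (sphere volume when $L = W$);
dimensions are swapped with a warning if width exceeds length. Tumour
growth inhibition is two-branched: with treated growth,
$TGI = 100(1 - (TV_t - TV_0)/(CV_t - CV_0))$ (requires control growth);
with regression, $TGI = 100(2 - TV_t/TV_0)$, so stasis is 100% and complete
regression 200%. The boundary $TV_t = TV_0$ is assigned 100% explicitly —
the two strict inequalities in the printed formulas leave it undefined, but
both formulas agree there, and the suite checks continuity and monotonicity
across the branch point. Group-level TGI uses group mean volumes (matching
how such studies report), with the per-animal table available.

IC50s come from a four-parameter logistic fit by Levenberg-Marquardt
least squares with multi-start initialisation (IC50 starts on a log grid
across the dose range, hill starts in both directions); the best-RSS
converged start wins, and the fit is reported in the canonical orientation
(bottom < top, hill sign flipped as needed — an exact reparameterisation).
Noise-free curves are recovered to machine precision. The synergy module
implements the Chou-Talalay median-effect method: the log-logit regression
$\log(f_a/(1-f_a)) = m \log d - m \log D_m$ gives $(D_m, m)$ per agent, and
the **mutually exclusive** (two-term) combination index
$CI = d_1/D_{x,1} + d_2/D_{x,2}$ is used — the field default, as the source
analysis cites the method without specifying the variant. Affected
fractions from viability are clipped away from {0, 1} by 1e-6 with a
warning before the logit.

# The synthetic-data generators

The generators define the study conditions the tests run under:

* **Counts**: negative binomial with mean `depth * 2^N(0,1)` per feature
  (default depth 500, dispersion 0.05; dispersion 0 falls back to Poisson),
  3 replicates per arm by default, matching the triplicate cell-line
  design. Planted effects are `sign * (effect_min + Exp(rate))`, half up and
  half down.
* **Phosphosite intensities**: Gaussian on the log2 scale (default SD 0.25)
  around a log-normal base, matching normalised TMT reporter signals, with
  one sequence window per site. Responder windows carry Q at +1 with
  probability `stq_frac_responders` (default 0.17) and null windows with
  `stq_frac_null` (default 0.033) — the frequencies implied by the
  motivating study at its scale of 674 differential and 13,854
  non-responding sites. Counts of motif-positive sites are deterministic
  (rounded) with random placement, so extreme proportions are hit exactly.
* **Dose-response**: 4PL curves on the 8-dose grid 25-1000 nM; the
  reference condition is (bottom 0, top 1, IC50 50 nM, hill 2) measured in
  triplicate — a full-range sigmoid with IC50 near 50 nM as in the
  motivating viability data, which reported IC50s of ~47-51 nM from three
  biological replicates. With hill 1 on a single-replicate grid the upper
  plateau is never observed above the lowest dose and top/IC50 become
  confounded; that identifiability limit of the design (not of the fitter)
  is why the steeper, replicated reference condition is the default.
* **Tumour growth**: exponential per-animal trajectories with group rates
  and multiplicative log-normal noise, measured every 2 days over 14 days
  (the treatment window in the motivating study); negative rates model
  regression.
* **Edges**: uniform random graphs with uniform scores by default.

Every generator takes a single seed and produces bitwise-identical output
when re-run; the pipeline derives all sub-streams from one config seed.

What the generators do **not** emulate: TMT ratio compression, batch
effects, peptide-level multiplicity (each localised site is independent),
mean-dispersion trends, count-length biases, or realistic protein sequence
composition (windows are i.i.d. residues outside the controlled positions).
A passing suite therefore demonstrates correctness of the machinery and
calibration under the stated models — not robustness to every artefact of
real MS or RNA-seq data.

# Numerical choices and degenerate inputs

* p-values are clamped into (0, 1]; BH inputs outside that range are errors.
* Fisher two-sided sums use a `1 + 1e-7` relative tolerance when comparing
  table probabilities, the same guard `fisher.test` uses against
  floating-point ties.
* Ranking ties break lexicographically by feature id, so rankings are
  deterministic.
* Constant rows z-score to zeros with a warning rather than NaN.
* Empty foregrounds/backgrounds, singleton dose grids, non-positive doses,
  zero-sum sample columns, and out-of-range scores are all rejected with
  errors naming the offending field; the pipeline aborts before computing
  anything if a configured input path does not exist.

# Problem sizes in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: differential recovery uses 1,000
features x 20 seeds; the motif-scale recovery uses the study-scale 14,528
sites; the exhaustive Fisher check enumerates all 316,251 tables with total
count <= 50; GSEA null calibration uses 500 repetitions of 200
permutations on a 100-feature ranking; IC50 recovery uses 50 seeds on the
triplicate 8-dose grid.

# Known limitations

The per-feature Welch test is less powerful than moderated estimators at
2-3 replicates and makes no variance pooling; it is calibrated, not
optimal. Permutation GSEA cannot resolve p-values below 1/(n_perm+1).
The DDR/TF-target analyses require user-supplied gene sets (GMT) — no
database fetching. Identifier namespaces are opaque strings throughout;
joining RNA, protein and site tables across namespaces is the caller's
responsibility.
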