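---
title: "Models and methods: dissecting glucocorticoid-driven regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dissecting glucocorticoid-driven regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grffl)
```

## The scientific problem

Glucocorticoids resolve inflammation by signalling through the
glucocorticoid receptor (GR), a ligand-activated transcription factor.
Within an hour of stimulation, macrophages rewire hundreds of genes, and a
striking share of the earliest GR targets are themselves transcription
factors — so the response is not a flat list of induced genes but a
network in which GR acts as a hub and propagates the hormonal signal
through intermediate regulators. Several early targets (Klf2 being the
canonical case) show pulse-like kinetics under *constant* hormone: fast
induction, a peak at 1–3 h, then a return to baseline. That shape cannot
be produced by simple one-factor activation; it is the signature of an
incoherent type-1 feed-forward loop (I1-FFL), in which the master
activator (GR) simultaneously induces the target and a repressor of the
target.

`grffl` implements the computational chain needed to dissect such a
system from condition-wise expression tables, association networks,
fold-change time courses and binding-site intervals:

1. **Expression clustering** — Z-score transform, ANOVA filtering,
   k-means with elbow selection, within-cluster rank tests.
2. **Network modules** — Girvan–Newman community detection with
   edge-betweenness recalculation, topology statistics, hub statistics
   and module-composition chi-squared tests.
3. **FFL dynamics** — simulation, analytic solution, global least-squares
   fitting, repressor prediction and knockout (uncoupling) analysis.
4. **Binding and enrichment** — flanking-window peak-to-gene association,
   frequency comparisons against expression-tier backgrounds,
   hypergeometric gene-set enrichment with FDR control, gene-set
   similarity networks, TF co-occurrence, and degenerate consensus
   scanning for glucocorticoid response elements (GREs).

Because the underlying experiments are not redistributable, the package
carries seeded generators that emulate the statistical structure each
stage assumes; every pipeline stage is therefore testable end-to-end with
no external data.

## Stage 1: expression clustering

Expression values arrive as a genes × conditions matrix on a linear
RPKM-like scale, with conditions U (untreated), D (dexamethasone),
L (LPS) and LD (both). Clustering should group genes by the *shape* of
their response, not by magnitude, so each row is log2-transformed and
standardized:

$$z_{gc} = \frac{x_{gc} - \bar{x}_g}{s_g},$$

with $\bar x_g$ and $s_g$ the mean and standard deviation of the
log2 values across conditions. Two small decisions are deliberately
pinned down because they change numbers downstream:

* **The divisor of $s_g$** is the sample (n−1) standard deviation, for
  consistency with the ANOVA variance estimator used in filtering.
* **Constant rows** ($s_g = 0$) carry no shape information; they are
  flagged and excluded rather than imputed.
* **Replicates** are averaged on the log2 scale *before* standardizing,
  so that clustering sees one value per condition; a one-way ANOVA
  across the four condition groups (on log2 values, requiring at least
  two replicates per group) is the differential-expression filter. A
  richer factorial design would be defensible; the one-way layout is the
  minimal model consistent with four treatment groups and is stated here
  as an assumption.

k-means uses Lloyd's algorithm with Euclidean distance and the best of
`n_init` seeded random starts. The number of clusters is chosen by the
elbow method, which we make reproducible by maximizing the discrete
second difference $w_{k-1} - 2w_k + w_{k+1}$ of the within-cluster sum
of squares over the interior of the scanned range (classically 8–14 for
this data type). Each scan step is warm-started from the previous
solution plus its worst-fitted point, which guarantees the scanned curve
is non-increasing in k. A curve whose maximal second difference is below
5% of the first scanned value is flagged as having no distinct elbow
rather than silently returning an arbitrary k.

Within-cluster condition contrasts use the Mann–Whitney test with
midrank ties: exact enumeration when the pooled sample is at most 20
without ties, otherwise the normal approximation with tie and continuity
corrections. Clusters below 3 genes are reported but flagged
underpowered, never dropped.

## Stage 2: network modules

Association networks arrive as edge lists. Weights, when present, are
retained as annotations only: partitioning and all topology statistics
use connectivity alone. Girvan–Newman community detection iteratively
removes the edge with the largest betweenness — the summed fraction of
all-pairs shortest paths crossing the edge, recomputed after every
removal (Brandes-style accumulation over BFS trees). Ties are broken by
lexicographic edge id so the removal history is exactly reproducible.
Stopping is either at a fixed module count (the classical three-module
decomposition is the default) or, with `"auto"`, at the
modularity-optimal partition along the removal sequence.

The topology report follows the NetworkAnalyzer conventions: density
$2E/(N(N-1))$; per-node clustering coefficient
$2\,\mathrm{tri}(v)/(d_v(d_v-1))$, zero when $d_v < 2$; *network
heterogeneity* as the coefficient of variation of the degree
distribution (population standard deviation over mean — the published
module values come without a formula, and this is the convention of the
tool ecosystem they were produced with); *neighborhood connectivity* of
a node as the mean degree of its neighbours, averaged over nodes with at
least one neighbour; and the histogram of shared-neighbour counts over
all node pairs. Hub influence is summarized as the fraction of edges
incident to the `top_n` highest-degree nodes; because "percent of all
edges" is ambiguous, the alternative degree-sum reading is exposed as an
option rather than silently chosen.

Module composition is tested per module with the Yates-corrected 2×2
chi-squared statistic

$$\chi^2 = \frac{n\,(|ad - bc| - n/2)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with the continuity correction floored at zero. The same statistic
serves the binding-frequency comparisons of stage 4, keeping all 2×2
testing in the package on one footing.

## Stage 3: I1-FFL dynamics

The model is the fold-sensor formulation of the I1-FFL. The raw system —
repressor $dR/dt = \beta_R X - \alpha_R R$, target
$dZ/dt = \beta_Z X / R - \alpha_Z Z$ under strong repression — is
nondimensionalized by the basal steady states, which matches the data:
RT-qPCR fold changes with basal set to 1. Three parameters remain: the
input fold change $F \ge 1$ and the two relaxation rates (per hour):

$$\frac{dr}{dt} = \alpha_R (F - r), \qquad
  \frac{dz}{dt} = \alpha_Z \left(\frac{F}{r} - z\right),
  \qquad r(0) = z(0) = 1.$$

The basal input is treated as small but nonzero (GR is largely inactive
without ligand, but a literal zero basal would make the fold change
undefined), so $F$ is a step fold change. Strong repression is the
default because it admits the analytic solution below and carries the
exact-adaptation property; a Hill-repression variant
($F(1+(1/K)^h)/(1+(r/K)^h)$, normalized to keep the basal state
stationary) is provided for the case of a finite repressor.

With equal rates $\alpha_R = \alpha_Z = \alpha$ the system solves in
closed form:

$$r(t) = F + (1-F)e^{-\alpha t}, \qquad
  z(t) = 1 + \frac{F-1}{F}\, e^{-\alpha t}
         \ln\!\left(1 - F + F e^{\alpha t}\right).$$

The solution was verified by substitution into the governing equations
before use, and is evaluated in the numerically stable form
$\ln(1-F+Fe^{\alpha t}) = \alpha t + \ln F + \mathrm{log1p}((1-F)e^{-\alpha t}/F)$
so large $\alpha t$ does not overflow. Numerical integration (lsoda,
relative tolerance $10^{-10}$) agrees with the closed form to better
than $10^{-6}$ across $F \in \{2, 10, 100\}$, $\alpha \in \{0.5, 1, 2\}$
on $t \in [0, 12]$ — one of the package's acceptance checks.

Three qualitative properties anchor the biology and are asserted as
tests:

* **Pulse with exact adaptation.** For any $F > 1$ under strong
  repression, $z$ rises from 1, peaks once, and returns to baseline
  ($|z-1| < 10^{-3}$ by $\alpha t = 12$) — the fold-change-detection
  behaviour that distinguishes the Klf2-like profile from simple
  induction.
* **Knockout uncoupling.** Clamping $r \equiv 1$ (the repressor-null
  genotype) collapses the pulse to monotone saturation
  $z = F + (1-F)e^{-\alpha_Z t}$, within 5% of the plateau by
  $t = 3/\alpha_Z$.
* **Coherent delay.** An AND-gated coherent FFL instead *delays*
  activation by $T = \ln((F-1)/(F-K))/\alpha_Y$ — the Fkbp5-like
  profile; both basal conventions (basal 1 and basal 0 intermediate)
  are implemented.

### Fitting and identifiability

`fit_i1ffl()` is a two-stage global least squares. Stage 1 fits the
analytic equal-rates solution over $(F, \alpha)$; stage 2 fits the full
numerical model over $(F, \alpha_R, \alpha_Z)$, initialized from
stage 1. Both stages use derivative-free Nelder–Mead search in
log-parameter space (relative tolerance $10^{-14}$, two polish passes)
from multiple seeded starts, with bounds $F \in [1, 10^3]$ and rates in
$[10^{-2}, 10^2]$ h⁻¹ enforced by penalty. On noiseless trajectories
over the standard 0–9 h grid, stage 2 recovers all three parameters to
well under 0.1% with $R^2 \ge 1 - 10^{-8}$.

One genuine property of this model deserves emphasis: with all three
parameters free, $F$ is only weakly identifiable from a noisy pulse.
The output amplitude grows roughly logarithmically in $F$, and the
likelihood surface has a flat ridge along which a smaller $F$ with
retuned rates fits almost as well (we measured, at 5% noise, SSE 0.0105
at $F = 6$ against 0.0129 at the true $F = 10$). The equal-rates
stage-1 fit does not suffer from this: its $F$ estimate recovers the
truth with a median relative error around 5% at a 5% coefficient of
variation. Parameter-recovery claims about $F$ under noise are therefore
made for the stage-1 estimator; stage 2 is the right tool for curve
shape, repressor prediction and the knockout comparison. A related
consequence: least-squares fitting of the pulse model to a *monotone*
saturating time course (the knockout phenotype) drives the fit into a
near-degenerate corner of parameter space whose curve overshoots its
end-of-window value by only a few percent (about 4% at the verified
global optimum of our standard fixture) — the pulse is gone, which is
the diagnostic point.

`predict_repressor()` exposes the fitted repressor trajectory
$r(t) = F + (1-F)e^{-\alpha_R t}$ for overlay against measured
candidate repressors, with a comparison $R^2$ when a candidate time
course is supplied.

## Stage 4: binding-site association and enrichment

Internal genomic coordinates are 1-based closed (the annotation
convention); BED input/output converts at the boundary, and the
conversion is an exact bijection. A gene is *associated* with a peak set
when at least one interval overlaps, by at least one nucleotide, the
gene body extended by a symmetric `window_bp` flank (default 15 kb;
strand is stored but ignored because the flank is symmetric). The
overlap engine is an interval-tree query; an acceptance check verifies
exact set equality with the quadratic all-pairs rule on a 500-gene /
2000-peak synthetic fixture, plus the two boundary cases (an 11-nt
overlap at the window edge associates; a 1-nt miss does not).

Association frequencies of gene groups (e.g. co-regulation clusters)
are compared against expression-tier backgrounds — non-expressors
(RPKM < 1), low expressors (1 < RPKM < 10) and all expressed genes
(RPKM > 1) — with the same Yates chi-squared statistic as stage 2. A
gene counts once per TF regardless of peak multiplicity.

Gene-set overrepresentation uses the one-sided upper-tail
hypergeometric probability $P(X \ge k)$ with Benjamini–Hochberg
q-values; the population defaults to all annotated genes and is
overridable to an expressed-gene background. Gene-set similarity
networks connect categories by the *overlap coefficient*
$|A \cap B| / \min(|A|, |B|)$ (the fraction of shared genes relative to
the smaller set, as in Enrichment Map practice); Jaccard similarity is
an option.

The GRE scanner slides an IUPAC consensus (default the canonical
pseudo-palindromic 15-mer `AGAACANNNTGTTCT`, which is its own reverse
complement) across a sequence and reports, per window and strand, the
number of matched defined positions. Published GRE-like genomic sites
are degenerate — typically 7–9 of 12 defined positions — so the default
reporting threshold is a permissive 7; raise `min_report_matches`
toward 12 for strict hits, or supply a different consensus. A
position-weight-matrix model is deliberately out of scope: the
capitalization-style match count is what the scanning-ChIP analyses it
supports actually use.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed once and the tests inherit them.

* **Expression** (`gen_expression()`): per gene, log2 value =
  between-gene baseline offset (Normal, `gene_sd`) + template condition
  mean + residual (Normal, `noise_sd`), exponentiated to the linear
  scale. Noise Normal on the log2 scale — i.e. multiplicative on the
  linear scale — matches RNA-seq dispersion at typical RPKM magnitudes.
  `macrophage_cluster_templates()` provides twelve templates over
  U/D/L/LD emulating the canonical early-response patterns (independent
  LPS or Dex induction, additive and synergistic co-activation, Dex
  antagonism of LPS induction, Dex repression, LPS downregulation), with
  40–15 genes per cluster, `gene_sd` 0.4 and `noise_sd` 0.25 log2 units.
  `separation_templates()` is the four-template recovery fixture: the
  four major co-regulation shapes (Dex-up, LPS-up, Dex-down, LPS-down),
  mutually distant in Z-score space (minimum pairwise squared distance 6
  against a per-coordinate noise of ~0.11), chosen so that "well
  separated" is actually true of the fixture and cluster-number recovery
  is a property of the method, not luck.
* **Time courses** (`gen_ffl_timecourse()`): model curve times mean-1
  lognormal noise at a fixed coefficient of variation (fold-change error
  is multiplicative), replicated; means and standard errors are
  reported. Defaults: the 0–9 h sampling grid, CV 5%, 3 replicates.
* **Networks** (`gen_planted_network()`): planted-partition (stochastic
  block model) graphs; within-community edges Bernoulli(`p_in`), between
  Bernoulli(`p_out`).
* **Intervals** (`gen_interval_plant()`): uniform background peaks plus
  peaks planted inside gene ± window of randomly chosen target genes, on
  a deliberately small synthetic genome (2 × 10 Mb) so exhaustive
  overlap oracles stay cheap; default peak width 200 bp, ChIP-peak
  scale.
* **Annotations** (`gen_annotations()`): random categories of 5–40 genes
  plus planted overrepresented categories, GMT-writable.

What the generators do *not* emulate — and what passing tests therefore
do not show about real data: read-level sequencing noise and coverage
biases; correlated gene-gene noise within pathways; realistic gene
length, spacing and chromatin context; weighted multi-channel
association evidence; and motif-containing sequence composition. The
tests demonstrate that each algorithm does what it claims under its own
statistical assumptions, not that those assumptions hold in any given
experiment.

## Numerical choices and degenerate inputs

* Integration: lsoda with rtol $10^{-10}$, atol $10^{-12}$; non-finite
  states abort with a parameter echo.
* k-means: random starts that collapse a cluster are discarded; nearest
  centroid ties resolve to the first (lowest-index) centroid, the
  convention of the underlying implementation.
* Girvan–Newman: betweenness ties broken lexicographically by sorted
  endpoint names; an already-disconnected graph at the target count
  returns the identity partition with an empty removal history.
* Chi-squared: any zero marginal is an error (the statistic is
  undefined), except in the frequency report where an exactly equal
  group/background pair short-circuits to p = 1.
* Mann–Whitney: two identical constant samples return U = nm/2, p = 1.
* Z-scores: non-positive values under log2 are an error unless a
  pseudocount is configured.
* All generator randomness flows through a single integer seed per call;
  identical seeds give byte-identical outputs.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on: 200-gene × 4
condition expression fixtures (10 seeds); 60-node planted graphs for
community recovery (10 seeds) and ≤ 8-node graphs (100 of them) for the
exhaustive topology comparison; the 0–9 h / 8-point grid for all fits
(1 noiseless + 10 noisy); a 500-gene / 2000-peak fixture for the
association sweep; and full enumeration up to n = m = 7 (rank test) and
N = 12 (hypergeometric). These sizes make every oracle exhaustive or
near-exhaustive while keeping the whole validation suite in the
low minutes.

## Known limitations

* The equal-rates analytic solution exists only for strong repression;
  Hill-repression fits always go through the integrator.
* $F$ from a single noisy pulse is weakly identified with free rates
  (see above); report stage-1 $F$ or fix a rate when that number
  matters.
* Girvan–Newman at a fixed module count can strand borderline nodes in
  the wrong module; on 3 × 20-node planted graphs at `p_in` 0.3 /
  `p_out` 0.02 the adjusted Rand index against truth is ≥ 0.9 for about
  90% of seeds (our implementation returns partitions identical to two
  independent implementations on such graphs, so this is the
  algorithm's ceiling, not an implementation artifact).
* The elbow statistic needs an interior point: a scan narrower than
  three values is an error, and a flat curve is a flag, not a k.
* The GRE scanner counts consensus matches; it is not a thermodynamic
  or PWM affinity model.
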