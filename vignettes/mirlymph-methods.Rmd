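---
title: "Methods: models, parameters and design choices in mirlymph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirlymph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlymph)
```

mirlymph implements an array-based miRNA profiling workflow for non-Hodgkin
B-cell lymphomas (NHBCL): five tumor types — Burkitt's lymphoma (BL),
diffuse large B-cell lymphoma (DLBCL), primary mediastinal B-cell lymphoma
(PMBL), mantle cell lymphoma (MCL), follicular lymphoma (FL) — profiled
against reactive lymph nodes (LN). The scientific thread running through
the pipeline is MYC: the transcription factor activates the miR-17-92
polycistron and its paralog clusters and represses a characteristic set of
miRNA families, so a sample's miRNA profile carries a readout of its MYC
activity that can be compared with the MYC protein level measured by
immunohistochemistry (IHC).

This vignette documents the models each stage assumes, the tunable
parameters with their defaults and units, the synthetic-data generators the
test suite relies on, and the design decisions taken where more than one
reasonable implementation existed.

## Normalization: affine calibration + glog2

Raw probe intensities are non-negative fluorescence values with a
per-array multiplicative scale and an additive background. `glog_normalize()`
fits, per array $i$:

* a background $b_i$ — the `bg_quantile` (default 5%) quantile of the
  array's intensities;
* a scale $a_i$ — the trimmed mean (`trim`, default 0.25) of the ratio
  between the background-corrected array and a per-feature median
  pseudo-reference across arrays.

Calibrated values $z = (x - b_i)/a_i$ are transformed with a generalized
log,

$$y = \log_2\!\left(z + \sqrt{z^2 + c^2}\right) - 1,$$

with the pseudo-count $c$ set to the 1% quantile of the positive calibrated
values pooled over arrays. For $z \gg c$ this converges to $\log_2 z$ (the
error is bounded by $c^2 / (2 z^2 \ln 2)$), so fold-change thresholds
downstream translate into differences of means on the transformed scale;
near zero the transform stays defined and flattens the variance of
low-intensity features. The transform is strictly increasing in $x$, so
within-array ranks are preserved exactly. This is a deliberately simple,
testable calibration: it provides the two properties the rest of the
pipeline needs (variance flattening and rank preservation) without a full
maximum-likelihood variance-stabilization fit, and it is not intended to
reproduce any particular reference implementation's estimates.

A practical caveat the test suite surfaced: the background quantile is only
a good estimator of $b_i$ when part of the feature distribution actually
sits at background. Arrays on which *every* feature is strongly expressed
lead to over-subtraction and a distorted low end. Real miRNA arrays always
contain a substantial unexpressed mass, and the synthetic cohort reproduces
this (see below).

## Probe summarization: Tukey median polish

Probes interrogating the same mature miRNA sequence are summarized with
Tukey's median polish (`median_polish()`): alternating row/column median
sweeps decompose the probes-by-samples block into
overall + probe effect + sample effect + residual. The target's profile is
overall + sample effect, so fixed per-probe offsets (affinity differences)
are absorbed by the probe effects and drop out of the summary. Defaults:
`max_iter = 20`, `tol = 1e-6` on the change in the sum of absolute
residuals. Missing cells are ignored by the medians.

Two numerical facts worth knowing:

* **Even-by-even stalls.** On matrices with an even number of rows *and*
  columns the alternating sweep can enter a two-cycle in which the residual
  sum is stationary but no fixed point is reached (about 40% of random
  even-by-even matrices do this; any odd dimension guarantees a finite
  fixed point). The stopping rule fires either way, but the `converged`
  flag additionally requires the residual row/column medians to vanish, so
  a stalled cycle is reported as not converged rather than silently
  accepted. Fitted effects in the stalled state still agree with the
  reference `stats::medpolish` to ~1e-11 because both implementations run
  the identical sweep sequence.
* **Constant probe offsets.** Adding a constant to one probe's whole row
  moves that probe's row effect, but the median-recentering step can shift
  the target's summarized profile by a per-target *constant* (when the
  offset crosses the median of row effects). The profile shape across
  samples — which is all that differential expression, clustering and the
  correlation screen consume — is exactly invariant.

## Differential expression and FDR

`test_multigroup()` runs a fixed-effects one-way ANOVA per target across
the sample classes; `test_twogroup()` a two-sided Welch t-test (unequal
variances — the class sizes here are unbalanced, and nothing justifies a
pooled-variance assumption). Both are vectorized over targets and verified
against `stats::aov`/`stats::t.test` in the suite.

`estimate_qvalues()` implements the Storey q-value with a fixed tuning
parameter $\lambda = 0.5$:
$\hat\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))$, then for sorted
p-values $q_{(m)} = \hat\pi_0\, p_{(m)}$ and
$q_{(i)} = \min(q_{(i+1)}, \hat\pi_0\, p_{(i)}\, m / i)$. The fixed
$\lambda$ is robust at the few-hundred-target scale of miRNA panels, where
spline smoothing of $\pi_0(\lambda)$ is poorly determined. One guard: the
exceedance count is floored at 1, otherwise an input with no p-value above
$\lambda$ (e.g. a single small p) would force $\hat\pi_0 = 0$ and zero out
every q-value.

Fold change between classes is $2^{\Delta}$ where $\Delta$ is the
difference of class means on the glog2 scale; with more than two classes
the reported value is the maximum pairwise ratio (the criterion pairs a
multi-class ANOVA with a single fold-change filter, and the max-pairwise
definition is the least surprising one). Signatures are selected at
`q <= fdr_threshold` and `fc > fc_threshold`; the pipeline's operating
points are FDR 0.5% for the five-class comparison and FDR 2% for
tumor-vs-LN, both with FC > 1.5.

`hierarchical_cluster()` uses $d = 1 - r$ (Pearson) with complete linkage
— the classic transcriptomics choice — over features or samples; items are
pre-sorted by id so leaf order is deterministic under permutations of the
input. Anti-correlated profiles sit at distance 2; zero-variance items are
rejected by name rather than silently producing NaN distances.

## The M parameter and the correlation screen

`m_parameter()` scores each sample as

$$M = \overline{\mathrm{up}} - \overline{\mathrm{down}},$$

the unweighted mean glog2 level of the MYC-upregulated signature miRNAs
found in the matrix minus the unweighted mean of the downregulated ones
(unweighted because the score is defined as a plain average of levels; no
defensible weighting exists without external calibration data). M is
invariant to adding a constant to a sample's column, so residual array
effects cancel. The default signature (`default_myc_signature()`) lists the
miR-17-92 cluster members as up (plus the miR-106a/miR-106b paralog-cluster
members when `include_paralogs = TRUE`, the pipeline default — the paralog
arms behave as one co-regulated block in practice) and the let-7 family,
miR-30 family, miR-29a/b/c, miR-26a/b, miR-34a, miR-146a, miR-150 and
miR-195 as down. Both lists are overridable from a two-column TSV or a
GMT-like file. Identifier matching lowercases and strips the species
prefix but keeps `*`/`-5p`/`-3p` suffixes significant, since distinct
mature arms are distinct molecules. At least `min_found = 3` members per
list must be present or the function aborts listing what matched.

`correlate_with_myc()` correlates every feature with the per-sample IHC
MYC-positive fraction by Spearman's rho on average ranks. Two-sided
p-values use the t approximation for $n \ge 8$ pairs and exact permutation
enumeration below ($n \le 7$ is cheap to enumerate and the t approximation
is poor there); q-values reuse `estimate_qvalues()`, and both raw-p and
q-based calls are reported. Because rho depends only on ranks, the screen
is invariant under any strictly monotone transform of the fractions — the
IHC readout need only be monotone in the underlying biology, not linear.
`volcano_table()` splits the significant features (default raw p < 0.001)
into positive and negative arms by the sign of rho and labels features not
in the known signature as novel candidates. The screen defaults to whatever
level the supplied matrix has; the pipeline hands it probe-level data (the
per-probe view is the more sensitive discovery screen) with the collapsed
target-level matrix as an option, and includes the LN samples by default
(`include_ln = TRUE`) since the reference nodes anchor the low end of the
MYC range.

## IHC quantification

`set_threshold()` pools the reference slides (reactive LNs with
low-frequency nuclear stain) and takes the nearest-rank quantile at
`negative_fraction` (default 0.95) of their nucleus intensities; a nucleus
is positive iff strictly above the threshold. On rank data this reproduces
"negative for 95% of reference cells, at least weakly positive for the
rest" exactly: reference intensities 1..100 give threshold 95 and exactly
5 positives. `positive_fraction()` reports the positive percentage per
slide — the paper-scale readout, nominally per 10,000 counted nuclei,
though any count works.

The rank threshold *by construction* calls a share $1 - \mathrm{nf}$ of
truly negative nuclei positive, so the raw percentage over-estimates small
true fractions by about $(1-f)(1-\mathrm{nf})$ — at a true 5% positivity
the raw readout sits near 9.7%. The result therefore also carries
`percent_positive_adjusted`,
$\hat f = (\hat p - (1-\mathrm{nf}))/\mathrm{nf}$ clipped to $[0, 100]$,
which divides out this known operating characteristic and is the better
estimator of the underlying positive fraction; recovery tests use it. The
raw percentage remains the headline value because it is what the
thresholding rule actually measures. No cross-slide intensity
normalization is applied beyond the shared threshold, matching the
single-background-threshold design; the expert-pathologist override step
of the original protocol is not algorithmic and is out of scope.

## Network inference

`filter_targets()` reduces a MirTarBase-style miRNA-target table to seed
genes: targeted by at least one differentially expressed miRNA with
*strong* (low-throughput validated) evidence and annotated with the filter
GO term (default GO:0030098, lymphocyte differentiation).
`shortest_path_union()` enumerates **all** unweighted shortest paths
between every pair of retained seeds and takes the union of their nodes
and edges — all paths rather than one arbitrary path, both to match the
all-pairs shortest-path tool this style of analysis uses and to make the
output deterministic and independent of seed/edge enumeration order. Seeds
missing from the graph are dropped with a warning; seed pairs in different
components are skipped (real interactomes have isolated components, and a
fatal error there would be wrong). Edges are unweighted hop counts — no
confidence weighting is attempted.

`rank_hubs()` ranks proteins by degree *within* the subnetwork (the
analysis asks which proteins are most connected among the perturbed
circuitry, not globally; the full-interactome degree is available as an
optional column), ties broken lexicographically, `k = 7` by default
(matching the number of hub proteins such an analysis typically reports,
exposed as an option since no principled k exists). `overlay_mirnas()`
adds bipartite miRNA-protein edges for strong-evidence pairs whose protein
is in the subnetwork and whose miRNA is differentially expressed, each
carrying the miRNA's regulation direction, and counts the distinct miRNAs
connected to the hubs.

## The synthetic cohort generator

`simulate_cohort()` generates the data structure the analysis assumes,
with recovery truth recorded:

* **Classes and sizes.** BL 12, DLBCL 13, PMBL 8, MCL 17, FL 26 (76
  lymphomas) plus LN 11.
* **Latent MYC activity.** Per sample, $a_s \in [0,1]$ from a truncated
  normal with class means 0.90 (BL), 0.60 (DLBCL), 0.52 (PMBL), 0.30 (LN),
  0.25 (FL), 0.17 (MCL) and sds 0.06/0.18/0.15/0.10/0.14/0.12 — BL highest
  and tight, DLBCL wide (it shows the largest observed MYC range), the
  indolent classes low with enough within-class spread that their samples
  are not rank-degenerate.
* **Expression model.** Target-level truth
  $t_{gs} = \mathrm{baseline}_g + \mathrm{DE\ offset} + \beta\, d_g\, a_s
  + \varepsilon$, with $d_g \in \{+1, -1, 0\}$ for up-/down-signature/other
  targets, $\beta = 1$ glog2 unit per unit activity, and
  $\varepsilon \sim N(0, 0.5)$. Baselines are $N(8, 1.5)$ glog2 for
  expressed targets; 30% of null targets are unexpressed
  ($N(2, 0.3)$) — the near-background mass real arrays always carry,
  without which the calibration's background quantile is misestimated.
  Signature member ids are used verbatim as target ids so the scoring
  stage finds them.
* **Probe layer.** Each target gets $1 + \mathrm{Poisson}(3.3)$ probes
  (mean 4.3); fixed per-probe offsets $N(0, 0.3)$ give median polish real
  work; raw values are
  $(2^{t + \mathrm{offset}} + 50)\cdot\mathrm{array\ factor} + N(0, 10)$,
  clipped at 0, with log-normal array factors (sd 0.15).
* **MYC fraction.** $\mathrm{logistic}(6(a_s - 0.5))$ plus $N(0, 0.05)$
  noise, clipped to $[0, 1]$ — bounded, monotone, noisy; the weakest
  structure the M-vs-IHC relationship needs.
* **Planted structure.** Optional class-discriminating targets (default
  offset 1.25 glog2 on a configurable class set), planted MYC-correlated
  "novel" targets (default 1.8 glog2 per unit activity, giving a true
  Spearman near 0.7 under the default noise), and the per-sample $a_s$
  itself.

`simulate_nuclei()` draws reference nuclei from a log-normal background
(meanlog 4, sdlog 0.25) and sample nuclei from a mixture of background and
an upward log-shift of `separation` with probability $f$.
`simulate_interactome()` grows a preferential-attachment graph (150 nodes,
$m = 2$), builds a 15-miRNA target table with strong/weak evidence labels
and a GO table, and wires each planted hub to every seed-eligible gene so
it sits on a length-2 path between every seed pair.

Everything is seeded and byte-reproducible; the pipeline fans a single
seed out to per-stage child seeds by a stable hash of the stage name
(`stage_seed()`), so toggling one stage never shifts another stage's
randomness.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: array chemistry and spatial artifacts, batch
effects (the original design handles batches by randomization only),
cross-hybridization between related mature sequences, the heavy-tailed
intensity distributions of scanner data, biological correlation between
miRNAs beyond the single MYC axis, and tissue heterogeneity in the IHC
model (one mixture component, no staining gradients). Recovery results on
the synthetic cohort demonstrate that the implementation correctly
extracts the structure it models, not that the biology of any given
dataset satisfies the model.

## Problem sizes used by the checks

The packaged checks run the default 87-sample cohort at 300 targets
(~1,300 probes), ten-seed replicates for the discovery and DE recovery
properties, 10,000-nucleus slides for IHC calibration, 50 random graphs up
to 30 nodes for the shortest-path oracle, and a reduced 24-sample cohort
for the end-to-end determinism check — sizes chosen so the full suite
exercises every stage at meaningful scale while remaining quick to run on
a laptop.

## Known limitations

* The calibration is a documented simplification, not a reproduction of
  any published normalization's estimates; only its contract (rank
  preservation, variance flattening, scale/offset removal) is guaranteed.
* $\hat\pi_0$ uses a single fixed $\lambda$; with very few targets the
  q-values inherit its variance.
* The multi-class fold change (max pairwise ratio) is one of several
  defensible definitions; signatures at a given threshold depend on it.
* The IHC adjustment assumes the reference slides share the sample slides'
  staining background; a systematic stain shift between them biases both
  estimators.
* `shortest_path_union()` enumerates all shortest paths, whose count can
  grow quickly on dense graphs; the intended inputs (sparse interactomes)
  keep this tractable, but pathological dense graphs will be slow.
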