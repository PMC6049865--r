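# mirlymph

An R package implementing an array-based miRNA profiling workflow for
non-Hodgkin B-cell lymphomas (NHBCL), for computational biologists who want
the full analysis chain — from raw probe intensities to a miRNA–protein hub
network — as tested, reusable functions rather than a one-off script.

The workflow targets a recurring question in lymphoma transcriptomics: how
much of the miRNA heterogeneity across Burkitt's lymphoma (BL), diffuse
large B-cell (DLBCL), primary mediastinal (PMBL), mantle cell (MCL) and
follicular lymphoma (FL) is attributable to MYC activity, and which
proteins sit downstream of the MYC-responsive miRNAs.

## What it computes

- **Normalization** — per-array affine calibration (background quantile
  `b_i`, trimmed-mean scale `a_i` against a median pseudo-reference)
  followed by a generalized log,
  `y = log2(z + sqrt(z^2 + c^2)) − 1`, `z = (x − b_i)/a_i`, which is
  rank-preserving and tends to `log2(z)` for bright features.
- **Probe summarization** — Tukey median polish per multi-probe target;
  the target profile is `overall + sample effect`, so per-probe affinity
  offsets drop out.
- **Differential expression** — per-target one-way ANOVA (multi-class) or
  Welch t (two-class), Storey q-values
  (`π0 = min(1, #{p>λ}/((1−λ)m))`, λ = 0.5) and max-pairwise fold change;
  signatures at FDR 0.5% (five-class) / FDR 2% (BL vs reactive lymph
  node), both with FC > 1.5. Hierarchical clustering with the
  1 − Pearson distance and complete linkage.
- **M parameter** — per-sample MYC-activity score: mean glog2 level of
  MYC-upregulated miRNAs (miR-17-92 cluster, optionally its paralogs)
  minus mean level of MYC-downregulated miRNAs (let-7 and miR-30
  families, miR-29a/b/c, miR-26a/b, miR-34a, miR-146a, miR-150, miR-195).
- **Correlation screen** — Spearman rho of every feature against the
  immunohistochemical MYC-positive fraction, volcano partition at
  p < 0.001, novel candidates flagged against the known signature.
- **IHC quantification** — nearest-rank 95th-percentile threshold on
  pooled reference slides; per-slide percent of nuclei strictly above it,
  plus a background-corrected estimate of the true positive fraction.
- **Network inference** — strong-evidence targets of the DE miRNAs
  filtered to a GO category (default GO:0030098, lymphocyte
  differentiation) seed a union-of-all-shortest-paths subnetwork of a
  protein interactome; proteins are ranked by subnetwork degree (top 7 =
  hubs) and DE miRNAs are overlaid as bipartite edges.
- **Synthetic cohort** — seeded generators for the expression cohort (87
  samples, latent MYC activity per class, ~4.3 probes/target), nucleus
  intensity tables and planted-hub interactomes, with ground truth for
  recovery testing.

## Worked example

```r
library(mirlymph)

sim     <- simulate_cohort(cohort_config(n_planted_corr = 5, seed = 1))
norm    <- glog_normalize(sim$raw)
targets <- collapse_probes(norm$normalized, sim$annotation)
targets
#> <expr_matrix> 300 target(s) x 87 sample(s), glog2 scale
#> value range: -6.27 .. 13.05

mp  <- m_parameter(targets)
cls <- sim$metadata$class[match(mp$sample_id, sim$metadata$sample_id)]
round(sort(tapply(mp$m, cls, median), decreasing = TRUE), 2)
#>    BL DLBCL  PMBL    FL    LN   MCL
#>  2.03  1.55  1.20  0.63  0.60  0.42
cor(mp$m, sim$truth$a_s[mp$sample_id], method = "spearman")
#> [1] 0.936
```

The class medians of M reproduce the planted MYC-activity ordering (BL
highest, the indolent classes lowest), and the per-sample score tracks the
latent activity at Spearman 0.94. Differential expression across the five
lymphoma classes then recovers a compact signature:

```r
labels <- sim$metadata$class[match(colnames(targets$values),
                                   sim$metadata$sample_id)]
keep <- labels != "LN"
de  <- differential_expression(
  expr_matrix(targets$values[, keep], "target", "glog2"), labels[keep])
sig <- select_signature(de, fdr_threshold = 0.005, fc_threshold = 1.5)
nrow(sig)
#> [1] 26
head(sig[, c("target", "statistic", "q", "fc")], 3)
#>         target statistic            q       fc
#> 37 mir-syn-004  25.71609 9.042396e-11 3.424866
#> 36 mir-syn-003  16.89954 1.176645e-07 2.639999
#> 34 mir-syn-001  15.63269 2.832216e-07 2.415342
```

and the network stage turns a DE miRNA list into ranked hub proteins:

```r
si  <- simulate_interactome(seed = 1)
sub <- shortest_path_union(si$graph, si$truth$seed_genes)
overlay_mirnas(sub, si$targets, data.frame(target = si$de_mirnas), k = 7)
#> <hub_network> 28 nodes (8 miRNAs), 52 edges; 7 hub(s); 4 miRNA(s) hitting hubs
#>  protein degree rank
#>    G0030     12    1
#>    G0145     12    2
#>    ...
```

`run_pipeline(pipeline_config(outdir = "out", seed = 1))` chains all
stages and writes every table (TSV), the dendrogram (newick), the network
(SIF/GraphML) and a JSON summary; a thin CLI wrapper lives at
`inst/scripts/mirlymph` (`mirlymph run --outdir out --seed 1`). Identical
config and seed reproduce byte-identical outputs.

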