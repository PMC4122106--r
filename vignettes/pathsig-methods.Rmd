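---
title: "Pathway-guided gene signatures for cancer prognosis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided gene signatures for cancer prognosis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsig)
```

## The problem

Differential-expression screens on clinical microarray cohorts produce long
gene lists in which many entries are false positives: expression shifts driven
by sample heterogeneity or technical variation rather than by the phenotype
being predicted. Classifiers built on such lists tend to be fragile — they
perform well on the split they were selected on and degrade when training and
validation roles are exchanged. `pathsig` implements a network-based
re-scoring strategy: after the usual statistical DEG selection, each DEG is
scored by how well it is embedded in a bipartite network connecting the DEGs
to a fixed panel of cancer-related KEGG signaling pathways, and only the
well-embedded genes are kept as classifier features.

## The scoring model

Let $N(G, P, E)$ be the bipartite network whose gene side $G$
($g_1,\dots,g_n$, the DEG list) and pathway side $P$ ($p_1,\dots,p_m$) are
connected by an edge whenever gene $g_j$ is a member of pathway $p_l$
(adjacency $a_{jl} \in \{0,1\}$; no edges within a side). Each gene starts
with an initial score $s_0 = 1$ and the score mass is propagated in two
steps:

1. every gene spreads its $s_0$ equally over its pathways, giving pathway
   weights
   $w_l = \sum_j a_{jl}\, s_0 / k(g_j)$;
2. every pathway returns its accumulated weight equally to its member genes,
   giving final scores
   $s_i = \sum_l a_{il}\, w_l / k(p_l)$,

where $k(\cdot)$ are node degrees. Composing the two steps gives the
one-mode weighted projection $s = C s_0 \mathbf{1}$ with
$c_{ij} = \frac{1}{k(g_j)} \sum_l \frac{a_{il} a_{jl}}{k(p_l)}$.
The package implements both routes (`gene_scores()` and
`score_via_projection()`) and they must agree to $10^{-12}$; the test suite
uses this agreement, together with two exact identities — column sums of $C$
equal 1 over connected genes, and $\sum_i s_i = s_0 \cdot \#\{\text{connected
genes}\}$ — as its main numerical guards.

A gene that receives back at least the unit it spread ($s \ge 1$, inclusive)
is considered well-embedded among the cancer pathways and enters the
signature (`filter_signature()`). Degree-zero genes and pathways are excluded
from every division: they contribute and receive exactly 0. This is the
natural boundary of the resource-allocation interpretation and avoids
division by zero, which the propagation formulas leave undefined.

### Degree convention

Pathway degrees are, by default, counted inside the induced subnetwork: only
DEGs contribute to $k(p_l)$. This matches the workflow in which the scored
network is built over the DEG list alone, and it keeps the conservation
identity exact. The alternative — dividing by a pathway's full membership
size — is available via
`build_bipartite_network(..., pathway_degree = "full")`; it down-weights
large pathways and breaks conservation, which is why it is not the default.

## DEG selection

`two_sample_t()` is the classical pooled-variance Student test (two-sided,
$n_1 + n_2 - 2$ df, no multiplicity correction), vectorized over rows and
cross-checked against `stats::t.test(var.equal = TRUE)` in the tests; a
`welch = TRUE` flag switches to the unequal-variance form. Degenerate rows
follow fixed conventions: zero pooled variance with equal means gives
$t = 0, p = 1$; with unequal means, $p = 0$ plus a warning.

Fold changes assume log2-scale input (the standard for series-matrix
intensities): $\log_2 FC$ is the difference of group means and
$FC = 2^{\log_2 FC}$. A `linear` scale flag switches to the ratio of group
means, with non-positive means rejected. Filters are strict on both sides
($p < 0.05$; $FC > 1.5$ or $FC < 1/1.5$) while the score threshold is
inclusive ($s \ge 1$) — the boundary semantics follow the inequality symbols
as written in the field's convention for these filters.

Probeset collapsing keeps, per gene symbol, the probeset with the largest
$|\log_2 FC|$ between the two groups, with ties resolved toward the
lexicographically smallest probeset id for determinism. Collapsing is
computed on the training split only, so feature selection never sees the
validation samples.

Survival endpoints are dichotomized at a milestone (default 365 days):
death before the milestone is high-risk (positive), survival to the
milestone is low-risk regardless of later censoring, and patients censored
before the milestone are excluded — they carry no usable milestone
information.

## Classification and the swap analysis

The classifier is an RBF-kernel SVM (via `e1071`, a libsvm binding),
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$. The kernel-width parameter
often printed as $\sigma$ in this literature is interpreted as this
$\gamma$: the canonical reported optima (0.03125, 0.00195, 0.00781, 0.125)
are all powers of two, exactly the values a power-of-two $\gamma$ grid
produces. The default grids are the libsvm-style
$c \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ and
$\gamma \in \{2^{-15}, 2^{-13}, \dots, 2^{3}\}$; `grid_search()` maximizes
leave-one-out cross-validation accuracy, with ties broken by higher LOOCV
MCC, then smaller $c$, then smaller $\gamma$, so model selection is fully
deterministic.

Features are z-scored using statistics learned on each training part
(recomputed inside every LOOCV fold); constant features are dropped with a
warning. Raw-intensity RBF kernels are scale-pathological, which is why
scaling is the default; `scale = FALSE` preserves the literal unscaled
reading. Evaluation reports specificity, sensitivity, accuracy and MCC from
the confusion counts, with MCC defined as 0 whenever a denominator factor
vanishes, plus a rank-based AUC (ties credited one half, equal to the
trapezoidal ROC area; cross-checked against `pROC` in the tests).

`run_original_and_swap()` is the robustness harness: the original arm trains
on set A and validates on set B, the swap arm exchanges the roles, and both
arms use the identical, pre-fixed signature — the signature is never
re-selected. Hyperparameters are re-optimized per arm by default
(`reuse_spec = TRUE` carries the original pair over, for the design in which
both arms report the same optimum). Similar performance across arms is the
evidence that the signature, not a fortunate split, carries the signal.

## The synthetic-data generator

`sim_config()` fixes the simulated study: genes receive log2 baselines
$\mathcal{N}(7, 1.5)$; a fraction `frac_de` (default 0.1) of genes is shifted
by $\pm$`effect_size` (default 2) in the positive class; each of the
`n_probes_per_gene` (default 2) probesets adds a fixed affinity offset
$\mathcal{N}(0, 0.3)$ and per-sample noise $\mathcal{N}(0,$ `noise_sd`
$= 0.5)$. Default cohort size is 60 samples per class; the end-to-end fixture
splits each class half/half into training and test. Pathways (default 20)
draw `frac_de_in_pathways` (default 1) of their members from the planted DE
genes; sizes default to 29–150 members — the lower bound matches the
smallest pathway in the reference KEGG cancer panel, while the upper bound is
capped by the planted-gene pool (200 genes at the defaults) rather than the
largest real pathway (327), since a set cannot exceed the pool it samples
from. Survival is exponential with mean 600 days in the low-risk class, a
6-fold hazard in the high-risk class, and independent exponential censoring
at rate 1/2000 per day — the minimal model that exercises all three branches
of the milestone rule (high-risk, low-risk, excluded).

These choices emulate what the pipeline assumes about real cohorts — and no
more. The generator has no array/batch effects, no probe saturation, no
correlated gene modules, and class-balanced cohorts; passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not performance on any particular clinical series.

All simulation is seeded and deterministic per config; pathway and survival
draws use fixed offsets from the main seed so the three generators can be
invoked in any order. Determinism holds at the value level on a given
platform; across BLAS/libm builds the usual last-ulp floating-point caveats
apply.

## Problem sizes and runtime

The shipped reference checks use: 100 random networks up to 200 genes x 30
pathways for the scoring identities; a 2000-gene, 30 + 30-sample null
simulation for t-test calibration; the default 2000-gene, 60 + 60-sample
fixture for recovery and the original/swap harness (with a reduced
3 x 3 power-of-two grid, a subset of the default grids, so the 50
random-signature baseline re-fits stay within minutes on one CPU); and a
300-gene fixture for end-to-end pipeline determinism. The full suite runs in
a few minutes on a single core.

## Known limitations

- At the reference calibration (per-gene shift 2 with noise 0.5, i.e.
  signal-to-noise 4), classification of the synthetic cohort saturates:
  the pathway-filtered signature attains validation MCC 1.0, but so does
  the majority of random same-size gene sets, because a random draw of
  ~90 genes from a pool containing 10% planted DE genes almost surely
  includes several of them. The signature-versus-random comparison can
  therefore only tie at the ceiling under these conditions; the comparison
  becomes informative only at lower signal-to-noise or sparser planted
  signal. The signature's defining advantage at the reference calibration
  is its precision (its members are planted pathway-member DE genes),
  not a higher MCC.
- The score is a single two-step propagation, not an iterated random walk;
  schemes with more propagation rounds are out of scope.
- KEGG memberships are not shipped (the packaged table lists the 20 pathway
  ids/names only); users supply memberships as GMT.
- The t-test is used without multiple-testing correction by design, matching
  the workflow the package implements; the DEG counts it produces are
  expected to contain false positives — that is precisely what the network
  re-scoring is for.

## Command-line interface

The workflow is function-first; a thin `Rscript` wrapper
(`inst/scripts/pathsig`) exposes the three entry points users run from a
shell — `simulate` (write a synthetic study), `score` (score a gene list
against a GMT), and `run-all` (the full pipeline). Intermediate stages
(collapsing, DEG selection, training, evaluation, swap) are deliberately not
duplicated as subcommands: they are reachable as package functions and are
chained by `run-all`, which writes every intermediate table the subcommands
would have produced.
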