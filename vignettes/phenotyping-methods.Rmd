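---
title: "Data-driven cognitive phenotyping with phenosom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven cognitive phenotyping with phenosom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosom)
```

## The problem

Children who struggle at school form a heterogeneous population: diagnostic
labels (ADHD, dyslexia, language impairment) overlap heavily, and most
struggling learners carry no diagnosis at all. Rather than grouping children
by label, `phenosom` phenotypes them from data: each child is described by a
vector of cognitive test z-scores (fluid reasoning, vocabulary, phonological
awareness, verbal and spatial short-term memory, verbal and spatial working
memory — all age-normed), and the package learns the structure of that
seven-dimensional space with an unsupervised neural network, then carves it
into profile groups, and finally asks which external measures (learning
outcomes, behavior ratings, diagnostic labels, white-matter connectomes)
track those groups.

## The self-organizing map

A self-organizing map (SOM) is a grid of nodes, each carrying a weight
vector $m_i$ in measure space. Training pulls the weights toward the data
while keeping neighboring nodes similar, so the trained grid is a 2-D
topographic model of the cohort: children with similar profiles map to
nearby nodes.

We use the *batch* formulation. Each cycle maps every child $x^{(t)}$ to its
best matching unit (BMU) — the node minimizing Euclidean distance — and then
replaces every node's weights concurrently by the mean of all children whose
BMU falls within grid distance $ND$ of that node (a "bubble" neighborhood).
Nodes whose neighborhood captures no children keep their previous weights;
retention avoids an undefined 0/0 mean and is the only behavior that leaves
a fixed point intact on constant data. During an ordering phase of $n$
cycles the neighborhood shrinks linearly,

$$ND(t) = 1 + INS\left(1 - \frac{t}{n}\right), \qquad t = 1, \dots, n,$$

from just under $1 + INS$ down to exactly 1; a fine-tuning phase then holds
$ND < 1$, so each node is updated only from its own BMU set. With $ND = 0$
the batch cycle is *exactly* one Lloyd (k-means) step with nodes as
centroids — the test suite verifies this equivalence against an independent
Lloyd implementation to machine precision.

Defaults: a $10 \times 10$ grid (about five times the square root of a
~500-child cohort), hexagonal topology with link (hop-count) distance,
$INS = 3$, five ordering cycles, one fine-tuning cycle at $ND = 0$. All are
configurable through `som_config()`. Grid geometry matters only through the
node-to-node distance matrix, so rectangular topology and Euclidean or
Chebyshev metrics are drop-in alternatives.

**Initialization.** Weights start on the plane spanned by the first two
principal components of the data through its mean: rows of the grid vary
along PC1 and columns along PC2, with spans proportional to the square
roots of the two leading eigenvalues. This makes training deterministic —
useful for reproducibility, but it removes the run-to-run variability that
consensus clustering (below) needs. We therefore add seeded Gaussian jitter
(`init_jitter_sd`, default 0.05 z-units) to the initial weights. The
jitter scale is small relative to the data (z-scores with cluster
separations of order 1) and acts only as a symmetry breaker; it is a
declared design choice, since nothing in the batch algorithm itself is
stochastic. BMU ties are broken toward the lowest node index, again for
reproducibility.

**Quantization error** (mean child-to-BMU distance) is recorded after every
cycle; on all seeded test cohorts it is non-increasing across the ordering
phase, a useful training sanity check though not a theorem.

## Topographic tests of categorical structure

If a category (a referral reason, a diagnosis) predicts cognitive profile,
its members' BMUs should concentrate somewhere on the map. We test this
with the two-sample two-dimensional Kolmogorov–Smirnov statistic: over
candidate origins and all four quadrant orientations, $D$ is the largest
absolute difference between the two samples' quadrant fractions. Candidate
origins are all combinations of observed $x$ and observed $y$ coordinates.
On an integer grid this attains exactly the same maximum as scanning every
grid point (the step function of quadrant counts only changes at observed
coordinate values), which the test suite confirms against an exhaustive
enumeration oracle; restricting origins to observed *points* (rather than
coordinate combinations) can miss the maximum on adversarial
configurations, which is why we use the full coordinate product. Children
sharing a node count with multiplicity.

Significance comes from a permutation test: membership labels are shuffled,
$D$ recomputed, and $p = (1 + \#\{D_{perm} \ge D_{obs}\})/(1 + B)$ with
$B$ permutations (default 9,999). The permutation route is exact up to
Monte-Carlo error and valid for small member groups, at the cost of a
discrete, conservative null — calibration runs show a type-I error of about
0.05 at the 0.05 level for a 530-child map. No correction is applied across
categories by default; `topography_tests(..., correction = "bonferroni")`
enables one.

## Consensus clustering into profile groups

The map is continuous; groups are imposed by k-means on the node weights
(k-means++ seeding, Lloyd iterations, best of 10 restarts). Each child
inherits its BMU's cluster. Because both the jittered initialization and
k-means are stochastic, the whole procedure is repeated (default 1,000
iterations; analyses in this package's validation use 200), retraining the
map each time. Cluster labels from each iteration are aligned to the first
iteration's centroids by the bijection minimizing summed centroid
distances (exhaustive over $k!$ assignments; $k \le 8$). Each child then
receives:

* a **modal cluster** — the most frequent aligned label;
* a **consistency** — modal count / iterations, in $[1/k, 1]$, which shades
  how close to a cluster boundary the child sits;
* a **clarity p-value** — a $\chi^2$ goodness-of-fit of the child's
  assignment counts against uniform $n/k$ expectation on $k-1$ df. A small
  p-value means the child has a clear home cluster.

$k$ defaults to 4 and is configurable; the package does not automate the
stopping rule of adding clusters until held-out measures stop
discriminating.

## Group statistics

Profiles are compared across modal clusters with classical one-way ANOVA
per measure and Tukey HSD post hocs (Tukey–Kramer standard errors for
unequal $n$). P-values are Bonferroni-corrected *within measure family*
(cognitive, learning, behavior), matching the number of comparisons per
data type. Categorical membership is tested with a one-way Pearson
goodness-of-fit of member counts across clusters against expectations
proportional to cluster sizes; this is the reading under which the
package's worked examples reproduce their reference statistics (e.g.
$\chi^2 = 14.93$ for the speech-and-language-therapy category) exactly from
the printed counts. Gender balance per cluster is a 1-df goodness-of-fit
against the whole-sample male proportion without continuity correction —
again the unique reading reproducing the reference values 6.12 and 6.80.

Behavior questionnaires (e.g. 8 BRIEF and 10 CCC-2 subscales) are reduced
before comparison: PCA on the subscale correlation matrix, two retained
components, varimax rotation, and regression-method factor scores
standardized to mean 0, sd 1. Two numerical choices matter here. First,
the rotation is run from ten orthonormal starting rotations and the
solution with the highest varimax criterion is kept — the standard
iteration can stall in a local optimum or, for perfectly balanced loading
blocks, start at a saddle point. Second, factor-score coefficients use a
generalized inverse of the correlation matrix, so noise-free (rank-
deficient) data remain scorable.

## Connectome comparison

Per-child structural connectomes arrive as symmetric streamline-count
matrices over 85 regions (34 cortical per hemisphere + 17 subcortical,
Desikan–Killiany style). Counts are symmetrized by averaging with the
transpose and weighted as $\log_{10}(1 + \text{count})$ — the offset keeps
the transform defined at zero streamlines and preserves "weight 0 = no
connection", whereas a bare $\log_{10}$ is undefined there. Regional
strength is the row sum of weights.

Group differences use a two-stage procedure: stage 1 screens each region
with an uncorrected Welch $t$ (deficit group vs the within-sample
age-appropriate group, $p < 0.05$); stage 2 retests only screened regions
against an external typically-developing group with Benjamini–Hochberg FDR
at $q = 0.05$ within the screened set. Welch rather than pooled-variance
$t$ because the group sizes are unequal by design. One property of this
design deserves emphasis: both stages share the deficit group's sampling
noise, so stage-2 p-values are not uniform *conditional on screening*.
Under a global null the expected number of selected regions is therefore
small (about 0.3 of 85 regions in our simulations) but exceeds
$q \times$ (mean screened count); the procedure's false-selection rate per
region is about 0.5%, not $q \times \alpha_1$. Users should read "selected"
as "survived a selection-biased confirmation", which is also how the
two-stage design behaves on real data.

Lobe-level summaries average strengths over each lobe's member regions —
the averaging (rather than summing over ~84 connections) keeps scores on
an O(1) scale — and compare groups with a two-sided Mann–Whitney U
(reported as $\min(U_1, U_2)$; exact below a combined $n$ of 20, normal
approximation with tie correction otherwise), BH-corrected across the five
lobes within each contrast.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the study conditions the
pipeline assumes: four generating clusters of sizes 146/121/132/131 whose
mean z-score profiles follow the reference cluster table (seven cognitive
plus three learning measures), multivariate-normal within-cluster noise,
and per-cluster categorical rates (gender, referral reason, five diagnosis
flags) set to printed count / cluster size. Within-cluster dispersion and
inter-measure correlation are not identified by group-level summaries, so
the defaults — per-measure sd 0.5 and exchangeable correlation 0.3 — were
chosen once as values a cohort analyst would call realistic: clusters
overlap at their boundaries (as the consistency shading assumes) yet remain
recoverable. Ages are uniform on 65–215 months and play no role downstream.
`generate_connectomes()` produces symmetric nonnegative edge-weight
matrices with optional planted regional deficits (mean reduction on all
edges incident to chosen regions) for power studies.

What the generator does *not* emulate: non-normal and skewed score
distributions, missing-data mechanisms, floor effects in clinical samples,
age-related covariance, and the spatial covariance structure of real
tractography (edge weights are independent given the group mean). Passing
tests on synthetic data therefore validate the machinery — they do not
certify performance on any real cohort.

## Validation scale and known limitations

The validation suite runs the consensus at 200 iterations over 10 master
seeds (the methodological default is 1,000 iterations; 200 is the scale at
which the modal assignment and clarity statistics are already stable, and
it keeps the suite fast). Two honest limitations surfaced by that
validation are worth stating plainly:

* **Boundary bias in recovered profiles.** With sd-0.5 clusters, ~15% of
  children sit close enough to a cluster boundary to be modally assigned
  across it. Any clustering method does this; the consequence is that
  recovered cluster means are pulled toward their neighbors by roughly
  0.05–0.2 z — several standard errors at $n \approx 130$. Agreement with
  the generating partition is far above chance (≈ 85% vs 25%,
  label-permutation $p < 0.001$), but per-cell cluster means should not be
  expected to match generating means to within sampling error alone.
* **Selection bias in the two-stage regional test**, described above.

Both are properties of the procedures themselves, reproduced faithfully;
neither is removable without changing the method.

## A worked example

```{r example, eval = FALSE}
gen <- generate_cohort(cohort_config(seed = 7))
som <- train_som(gen$cohort, som_config(seed = 3))
cons <- consensus(gen$cohort, som_config(), k = 4, n_iterations = 200,
                  seed = 11)
cons
topo <- topography_tests(som, gen$labels, c("slt", "adhd", "dyslexia"),
                         n_permutations = 999, seed = 5)
prof <- compare_cluster_profiles(gen$cohort, cons$modal_cluster)
```

`run_pipeline()` chains all stages from a single config (list or YAML) and
writes every table as delimited text with a config echo and the master
seed, so a full run is reproducible byte for byte.
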