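---
title: "Supervised manifold embedding for protein-DNA hot-spot prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised manifold embedding for protein-DNA hot-spot prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdhotspot)
```

## The model

Hot spots are the minority of interface residues whose alanine mutation
shifts protein-DNA binding free energy past a threshold. The package
predicts them from precomputed residue feature tables (in the benchmark
setting: 114 descriptors spanning solvent-accessible surface area,
sequence, structure and network properties; 150 training residues). The
pipeline is: supervised nonlinear dimensionality reduction to d = 3,
then gradient-boosted tree classification, then threshold at 0.5.

### Label-aware dissimilarity

For residues $x_i, x_j$ with Euclidean distance $d = d(x_i, x_j)$:

$$D(x_i,x_j) = \begin{cases}
\sqrt{1 - e^{-d^2/\beta}} & y_i = y_j \text{ (or labels absent)}\\
e^{d^2/(2\beta)} - \alpha & y_i \ne y_j
\end{cases}$$

The same-class branch is a bounded, strictly increasing transform of
$d$ (limit 1); the different-class branch grows unboundedly and is at
least $1-\alpha$ at $d = 0$. Consequences we rely on:

* with $\alpha \le 0$, *every* between-class dissimilarity exceeds
  *every* within-class one, whatever $d$;
* with the default $\alpha = 0.5$ the branches can interleave for small
  $d$, which keeps genuinely overlapping classes overlapping — the
  supervision is a soft prior, not a relabeling;
* since both branches are monotone in $d$, uniform labels give exactly
  the k-NN edge set of unsupervised ISOMAP (asserted by test).

The different-class branch is computed as $e^{d^2/(2\beta)} - \alpha$,
the algebraic rewrite of $\sqrt{e^{d^2/\beta}} - \alpha$ that halves the
exponent; inputs that would still overflow are rejected with a pointer
at $\beta$ rather than saturated, because an `Inf` edge weight silently
poisons every shortest path through it.

### Parameters

| parameter | default | units / scale | why |
|---|---|---|---|
| $\alpha$ | 0.5 | dissimilarity offset, $\alpha \le 1$ | soft between-class inflation; $\alpha \le 1$ keeps $D \ge 0$ at $d=0$ |
| $\beta$ | `"auto"` | scale of $d^2$ | mean squared pairwise distance of the fit data keeps exponents $O(1)$ |
| $k$ | 7 | neighbours | pure k-NN graph, the dominant ISOMAP convention at $n \approx 150$ |
| $\varepsilon$ | 0 (off) | Euclidean distance | the auxiliary $\varepsilon$-rule is defined on raw Euclidean distance and kept available but disabled — no principled default exists |
| $d$ | 3 | embedding dims | the dimension of the hot-spot model |
| `n_trees`, `learning_rate`, `max_depth` | 500, 0.1, 30 | boosting | the tuned values of the hot-spot model |

The source the defaults for $\alpha$, $\beta$, $k$ derive from never
reports the values used for the benchmark results, so these are
conventions, not reproductions.

### Graph, geodesics, embedding

The neighbourhood graph connects $i$ and $j$ iff either is among the
other's $k$ nearest by dissimilarity (union symmetrisation — required
for a symmetric shortest-path problem), or $d(x_i,x_j) < \varepsilon$;
edge weights are always dissimilarities. Nearest-neighbour ties break to
the smaller index, for determinism.

Supervised dissimilarities inflate between-class edges, so the graph of
a well-separated problem is often disconnected (the classes become
separate islands). Rather than dropping samples, connectivity is
repaired by iteratively adding the minimum-dissimilarity edge between
the two closest components, with a warning. This is the minimum
perturbation that makes Floyd-Warshall's finiteness precondition hold;
it adds exactly the minimum-spanning bridges (asserted by test).

Geodesics are exact all-pairs shortest paths (Floyd-Warshall, compiled;
$O(N^3)$ is irrelevant at $N \le 800$). Classical MDS then embeds
$\tau(D_G) = -HSH/2$ via its top-$d$ eigenpairs,
$Y = \mathrm{diag}(\lambda^{1/2})\,[u_1 \dots u_d]^T$. Numerical
choices:

* eigenvalues are "positive" above a relative tolerance
  $\max|\lambda| \cdot \sqrt{\epsilon_{mach}}$; if fewer than $d$
  qualify, $d$ is reduced with a warning — negative eigenvalues of
  $\tau$ carry no metric information and are never retained or padded;
* eigenvector signs are fixed by making each vector's largest-magnitude
  entry positive (first such entry on exact ties), so output is
  reproducible across platforms and row permutations of the input
  permute the embedding rows identically;
* the centring statistics of $\tau$ (row means and grand mean of the
  squared geodesic matrix) are stored on the model for the out-of-sample
  extension.

### Out-of-sample extension

Test labels are unknown, so a new point's dissimilarities to the
training set use the label-free (same-class) branch. The point is
connected to its $k$ nearest training points; its geodesic to every
training point is the minimum over entry points of (entry weight +
training geodesic). Because eigenvectors of the doubly centred $\tau$
with $\lambda \ne 0$ sum to zero, the Nyström projection reduces to

$$y_a = \frac{1}{2\sqrt{\lambda_a}} \sum_i u_a[i]\,(\mu_i - s[i]),$$

with $\mu$ the stored row means and $s$ the new point's squared
geodesics.

One rule is added beyond the basic construction: a new point whose
squared Euclidean distance to some training point is below a
data-scaled tolerance ($10^{-9}(1 + \overline{\lVert x \rVert^2})$,
comfortably above floating-point cancellation residue and far below
real neighbour distances) inherits that node's geodesic column. Without
it, a label-free entry edge to a nearby opposite-class training point
can undercut the supervised geodesic, and training rows would not map
back onto their fitted coordinates; with it, the round trip is exact to
machine precision (asserted at $10^{-6}$). A transductive alternative —
re-embedding train + test jointly with label-free distances for test
rows — is provided (`sisomap_fit_transductive`, `transductive = TRUE`
in `evaluate_holdout`) since the original evaluation protocol for
held-out residues is not fully specified; the inductive Nyström route is
the default because it keeps train/test separation clean.

Features are used as-is by default (`standardize = FALSE`); an optional
z-score flag fits the scaling on the training data and applies it at
test time.

### Classifier

No gradient-boosting library exists in the supported dependency set, so
the ensemble is implemented in compiled code: second-order boosting on
the logistic loss, exact greedy split search maximising the usual gain
with L2 leaf penalty $\lambda = 1$ and minimum child hessian 1, leaf
weights $-G/(H+\lambda)$ shrunk by the learning rate, base score 0.5.
There is no row or column subsampling: fitting is fully deterministic,
which the reproducibility contracts (identical predictions across
processes) require anyway. Split ties break to the lowest feature index
and threshold; thresholds sit at midpoints of consecutive distinct
values. The optional grid search ranks candidates by stratified-CV mean
AUC with ties broken towards fewer trees, then shallower depth.

Class imbalance (62:88) is left unweighted by default; the decision
threshold (0.5) is configurable.

### Evaluation harness

Confusion-count metrics follow the standard formulas literally; any
zero denominator (PRE with no predicted positives, MCC with a zero
factor) returns 0 with a warning, keeping aggregation over folds total.
AUC uses the Mann-Whitney rank formulation with average ranks (ties
count ½), and a trapezoidal ROC integration is provided as a
cross-check; the two agree to numerical precision by construction.

Cross-validation is stratified (62 positives among 150 samples make
unstratified 10-fold splits unstable), with per-repeat seed
`base_seed + repeat - 1`. Within every fold the embedding is refit on
the training portion only and held-out samples enter through the
Nyström extension — the embedding never sees evaluation labels or
coordinates. The per-repeat metric pools fold predictions rather than
averaging per-fold metrics (stable with ~6-sample positive folds);
repeats are then averaged with standard deviations.

## The synthetic generators

`make_benchmark_mimic` emulates the benchmark's *shape*: train 62/88,
test 26/38, 114 features in four correlated blocks (within-block
equicorrelation 0.6 via a shared factor, independent across blocks —
mimicking grouped feature families without claiming their true
covariance). The class signal is a mean shift of length `separation`
(in within-class SD units) along a random direction spread over
`n_informative = 10` randomly placed dimensions. Default
`separation = 2`: moderately overlapping classes, chosen once as the
regime a real residue benchmark lives in. What a green test on this
fixture establishes is that the pipeline recovers a low-dimensional
class signal buried in correlated noise at benchmark-like sample sizes
— not that it reproduces real protein-DNA energetics, real feature
marginals, or the published benchmark numbers (whose data are only
available through an external repository).

`make_swiss_roll` is the standard geodesic validation surface
$(t\cos t,\ h,\ t\sin t)$, $t \in [1.5\pi, 4.5\pi]$, $h \in [0, 21]$,
returning the intrinsic coordinates (arc length
$s(t) = (t\sqrt{1+t^2} + \mathrm{asinh}\,t)/2$, height) for oracle
checks. Points are sampled uniformly **on the manifold** (uniform in
arc length): sampling $t$ uniformly thins the outer coil roughly
14-fold, and at $n = 800$ the $k = 10$ NN graph then short-circuits
between coils — a pathology of the sampling law, not of the embedding
under test. Both generators are pure functions of their seed and leave
the caller's RNG stream untouched.

## Known limitations

* The repair of disconnected graphs, while minimal, fabricates
  geodesics between components; strongly separated classes therefore
  have between-class embedding distances governed by a single bridge.
* The Nyström extension is only as good as the training graph near the
  new point; extrapolation beyond the training manifold is undefined
  behaviour for any ISOMAP variant.
* The boosted ensemble at depth 30 on ~150 samples interpolates the
  training data; generalisation rests on the embedding, which is why
  the cross-validation harness refits the embedding per fold rather
  than once.
* Probabilities are not calibrated; only their ranking (AUC) and the
  0.5-thresholded labels are validated.
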