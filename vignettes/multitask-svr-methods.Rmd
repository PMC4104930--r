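---
title: "Multi-task support vector regression for multi-target QSAR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task support vector regression for multi-target QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtqsar)
```

## The models

### Single-task SVR

A QSAR task is a set of pairs $(x_i, y_i)$ with $x_i \in \mathbb{R}^n$ a
molecular fingerprint and $y_i$ a pIC50. `mtqsar` fits the linear
$\varepsilon$-insensitive SVR primal

$$\min_w \tfrac12\|w\|^2 + C \sum_i l_\varepsilon(w^\top x_i, y_i),
\qquad l_\varepsilon(\xi, y) = \max(|\xi - y| - \varepsilon, 0)^k,$$

with $k = 2$ (L2 loss) by default: the L2 loss models the mean squared
error, which is also the evaluation metric, so train-time and test-time
objectives agree. $k = 1$ is available. Residuals inside the tube of
half-width $\varepsilon$ are free; training points with nonzero dual
coefficient (the support vectors) lie on or outside the tube, so larger
$\varepsilon$ gives sparser models.

No bias term is regularized. Instead the labels are centered before
optimization and the training mean is kept as the prediction offset
($\hat y = w^\top x + \text{offset}$). Regularizing a bias (appending a
constant feature) can make the coupling terms below spend their budget on
matching biases rather than feature weights, which is exactly wrong when
two similar tasks have different average potencies.

Fingerprints should be normalized to unit Euclidean norm
(`normalize_features()`): with the linear kernel this equals the cosine
kernel, whose values lie in $[0, 1]$ for non-negative fingerprints and do
not grow with compound size.

### Graph-regularized multi-task SVR (GRMT)

Task relatedness is encoded in a symmetric non-negative adjacency matrix
$A$ ($A_{st}$ = similarity of tasks $s$ and $t$). The joint primal adds
the similarity-weighted disagreement penalty

$$J(w_1,\dots,w_T) = \tfrac14 \sum_{s,t} A_{st}\,\|w_s - w_t\|^2
 = \tfrac12 \sum_{s,t} L_{st}\, w_s^\top w_t,
\qquad L = D - A,\; D_{st} = \delta_{st}\textstyle\sum_k A_{kt},$$

to the sum of per-task SVR objectives. Because only off-diagonal entries
of $A$ enter $L$, the convention $\operatorname{diag}(A) = 1$ is harmless.
The dual is the standard SVR dual with inner products reweighted by
$M = (I_T + L)^{-1}$; the solver maintains the per-task weights
$w_t = \sum_s M_{ts} u_s$ incrementally, where $u_t$ collects
$\sum_{i: t_i = t}\beta_i x_i$. $M$ is computed once per fit by a
symmetric positive-definite solve (never an explicit inverse). Labels are
centered on the global mean over all tasks, which becomes the shared
offset — with the caveat that a task whose average potency differs
strongly from the panel mean is systematically harder for GRMT; for such
panels the TDMT variants (which re-center per node) are the better choice.

$A = I_T$ (or any diagonal $A$) decouples the problem into independent
SVRs sharing one $C$; a very large uniform $A$ forces all task weights
together. The similarity input therefore interpolates between the tSVM
and 1SVM baselines.

For a task with no training instances (prospective prediction for a new
target), `train_grmt(..., unseen_tasks = )` removes that task's ridge
term $\|w_t\|^2$ so its weight is determined purely by the disagreement
penalties tying it to trained tasks. The modified system must stay
positive definite — a task with zero similarity to every trained task is
rejected rather than silently given the zero weight vector.

### Top-down multi-task SVR (TDMT)

Given a rooted task taxonomy with tasks at the leaves, one model is
trained per node, breadth-first from the root. A node with subtree
instance set $S$ and parent weight $w_p$ (fixed) solves

$$\min_w \tfrac{1-B}{2}\|w\|^2 + \tfrac{B}{2}\|w - w_p\|^2
  + C\sum_{i \in S} l_\varepsilon(w^\top x_i, y_i),$$

with pull strength $B \in [0,1]$: $B = 0$ is an independent model,
$B = 1$ maximal dependence on the ancestor, and with the loss term
removed ($C = 0$) the minimizer is exactly $B\,w_p$. Substituting
$v = w - B w_p$ shows this is a standard SVR on labels shifted by the
parent's contribution — implemented as custom linear terms in the dual —
so each node costs one ordinary SVR fit and training is linear in the
number of nodes.

Two published conventions around this node problem are mutually
inconsistent, and we had to choose:

* **Prediction rule.** A "sum" convention predicts with
  $(w + w_p)^\top x$; but the node loss above is computed on
  $w^\top x_i$, and the $B = 0$ case is explicitly an *independent*
  model, which the sum convention would break. We predict with the node
  weight alone (plus the node offset). The sum rule is available as
  `predict(..., rule = "literal_sum")` for comparison only.
* **Sign of the linear term.** The dual linear term must shift the
  effective labels by $-B\,w_p^\top x_i$ (with $w = B w_p + \sum_i
  \beta_i x_i$); the opposite sign contradicts the $C \to 0$ limit. Our
  choice is pinned down by the primal-oracle equivalence tests.

Labels are re-centered at every node (each node keeps its own offset), so
subtrees with different potency ranges do not fight over one global bias.
An internal node or leaf with no instances — which occurs under
leave-one-sequence-out — inherits its parent's model verbatim, and
predictions for an unseen task are its parent's predictions.

**TDMTtax** takes $B$ for each node from the taxonomy edge weights,
scaled to $[0,1]$ by the maximum weight (`scale_weights()`; a no-op when
the weights already lie in $[0,1]$), and grid-searches only $C$ per node.
**TDMTgs** searches $(B, C)$ jointly per node by inner cross-validation
(`local_grid_search()`); a joint search over all nodes at once would be
exponentially expensive, so the local search is a taxonomy-guided
heuristic. Ties are broken towards smaller $B$, then smaller $C$ — less
transfer and less fitting capacity on equal evidence; the convention is
ours, chosen for conservatism. `prevent_negative_transfer = TRUE` adds
$B = 0$ to leaf grids so a leaf may opt out of transfer; it is off by
default because on the simulated benchmark unconditional transfer is
usually the better setting for TDMTtax (and TDMTgs's grid contains 0
anyway).

### Baselines

tSVM trains $T$ independent SVRs (per-task centering, per-task $C$);
1SVM pools everything into one model. Both are exact special cases:
GRMT with $A = I_T$ equals tSVM at shared $C$ and offset, a TDMT star
taxonomy with $B = 0$ at all leaves equals tSVM, and the TDMT root model
is the 1SVM. These identities are enforced by tests at $10^{-5}$
weight-vector $\infty$-norm and anchor the implementation.

## The solver

All duals are minimized by coordinate descent in the style of large-scale
linear SVM libraries: one epoch visits every dual coordinate in a fresh
random permutation; each update is a one-dimensional Newton step with the
exact handling of the $\varepsilon|\beta_i|$ kink; the per-epoch maximal
projected-gradient violation is the convergence measure. The permutation
is driven by an explicit integer seed, so fits are exactly reproducible —
coordinate order is the only stochastic element in training.

Numerical choices:

* **Stopping.** The violation threshold is *relative* to the first
  epoch's violation (floored at 1), default $10^{-3}$. An absolute
  threshold is misleading here because gradient scales grow with $C$ and
  with the label spread.
* **Epoch cap** default 30000. Epochs cost microseconds at desk scale;
  ill-conditioned fits (pooled data from heterogeneous tasks at
  $C = 2^7$) genuinely need $\sim 2 \times 10^4$ epochs. Hitting the cap
  flags the result and warns — never silently.
* **Shrinking heuristics** are deliberately omitted: correctness and
  auditability over speed at the problem sizes this package targets.
* **Degenerate inputs.** Identical feature vectors with conflicting
  labels are legal (the dual is still strictly convex in the L2 case);
  an all-zero instance simply keeps $\beta_i = 0$.
* **Duality.** At convergence the primal objective equals the negated
  dual objective; the test suite checks the gap and cross-checks every
  solver path against an independent dense BFGS minimization of the
  corresponding primal on ~100 random small problems.

## The synthetic benchmark

`simulate_mt_tasks()` generates the controlled multi-task regression
problem used throughout the tests: each instance has $D$ attributes, each
attribute takes one of 6 values (one-hot, so instances are binary vectors
of length $6D$ with exactly $D$ ones); each task is a linear model whose
6 sub-weights per attribute are drawn from Gaussians with means
$(-\beta, -\tfrac23\beta, -\tfrac13\beta, \tfrac13\beta, \tfrac23\beta,
\beta)$ and variance $\sigma^2$; targets are exact, $y = w_t^\top x$,
with no label noise. $\beta$ sets the signal scale (default 3, a
low-noise regime); $\sigma^2$ sets how far tasks scatter around the
shared mean pattern and hence the task similarity: $\sigma^2 = 0.5\beta$
gives highly similar tasks (mean pairwise weight cosine $\approx 0.75$,
target Pearson correlation $\approx 0.8$ on common instances),
$\sigma^2 = 3\beta$ dissimilar ones (cosine $\approx 0.34$). The
attribute value is drawn uniformly over the 6 choices — the natural
reading of "six possible values" — and training instances are sampled
separately per task (a `shared_instances` switch exists to study the
input-space-coverage effect). One global seed fans out to fixed
substreams for weights, per-task training instances and test instances,
so every component is individually reproducible.

The reference similarity inputs for the multi-task methods come from the
generating weights themselves: GRMT gets the pairwise cosine matrix
(negative cosines, possible at low similarity, are clipped to 0 because
the graph regularizer requires non-negative entries; the raw values are
kept as an attribute), and TDMT gets a star taxonomy — root = the mean
model, edge weight = cosine of task weights to the mean-model weights.
The `"anti"` variant ($1 - \cos$) and `"random"` variant exist to study
robustness against wrong similarities.

For the target-correlation summary statistic the tasks must be evaluated
on a *common* instance set (correlations of targets on disjoint
per-task instance sets are undefined); we use 100 common instances.
This is our reading — sampling designs that correlate on other instance
sets are possible but not obviously meaningful.

What the generator does **not** emulate about real QSAR data: sparse
high-dimensional hashed fingerprints (it uses dense low-dimensional
one-hot blocks), label noise and assay heterogeneity, non-uniform
chemistry coverage per target, and potency-range differences between
tasks (all tasks share the mean pattern, so offsets are comparable).
Passing benchmark tests therefore demonstrates correctness of the
optimization and the expected transfer behaviour under controlled
similarity — not predictive performance on chemical data.

## Evaluation harness

All protocols (`run_protocol()`, `leave_one_sequence_out()`) share one
structural guarantee: every algorithm sees *identical* train/test splits,
so per-(task, split) MSEs pair exactly — the pairing is enforced by
construction, and `paired_tests()` refuses tables where it does not hold.
Model selection is an inner cross-validation (default 3-fold, stratified
by task so every task appears in every fold where possible) over the
standard grids: $\log_2 C \in \{-5, -3, \dots, 7\}$,
$B \in \{0, 0.1, 0.25, 0.5, 0.75, 0.9, 1\}$, with a coarser large-$C$
grid (`make_grids("kinome_grmt")`) for graph-regularized training over
many tasks, where the loss term faces many more weight parameters and
larger $C$ is routinely selected.

$\varepsilon$ is fixed at 0.1 pIC50 units rather than searched: a
typical $\sim$25% relative IC50 assay error maps to
$\log_{10}(1.25) \approx 0.1$ on the pIC50 scale
(`epsilon_from_relative_error(0.25)`). Reported mean errors for
heterogeneous public bioactivity data are substantially larger
($\approx$ 0.4–0.55 log units), so 0.1 should be read as a lower bound
appropriate for single-lab data.

Leave-one-sequence-out removes *all* training data of one task and
redistributes that task's training budget uniformly over the remaining
tasks (remainder to the tasks with the most available instances), keeping
the total training size fixed; the held-out task is predicted by the
parent node (TDMT) or by the ridge-free similarity-tied weight (GRMT),
and GRMT is skipped with a message when the held-out task has zero
similarity to every trained task.

Significance: per-task two-sided Wilcoxon signed-rank tests on paired
MSEs — exact for $\le 25$ pairs, normal approximation with continuity
correction above (the split counts in practice straddle that boundary) —
with Holm's correction when several algorithms are compared on one
target (family-wise error) or Benjamini–Hochberg when one comparison
spans many targets (FDR). Significant results are labelled Better/Worse
by the sign of the median paired difference; all-zero difference vectors
get $p = 1$ by convention and are flagged. Under the null the rejection
rate at $\alpha = 0.05$ is calibrated to $0.05 \pm 0.02$ in the test
suite.

## Chemistry-facing utilities

The curation cascade (`curate_activities()`) applies, in order:
assay-confidence $\ge 8$, binding assays only, wild-type targets only,
exactly determined values only, IC50 $\to$ pIC50 conversion, activity
floor pIC50 $\ge 5$, per-(compound, target) replicate resolution
(range $> 1$ log unit $\Rightarrow$ reject, else geometric mean of the
pIC50 values — note this is the geometric mean *of the log quantity*,
kept deliberately as the conventional rule), a physicochemical window
(90 < MW $\le$ 900, $-7 \le$ AlogP $\le 9$, HBA/HBD/rotatable bonds
$\le$ 18), organic structures only, and a per-target minimum of 15
compounds (last, since it depends on everything before it). Every
exclusion is logged with its rule id. The record-level filters commute,
so their order only affects which rule a doubly-bad record is charged to.

Fingerprints: `fold_fingerprint()` maps raw circular-fingerprint ids into
$2^{bits}$ bins by modulo (bins accumulate, then binarize — presence
semantics) and reports the collision fraction; at subset scale
($\sim$5000 distinct ids into $2^{20}$ bins) collisions stay below 0.5%.
Generating the raw ids from structures is delegated to an external
chemistry toolkit; only folding, normalization and filtering are this
package's concern. `filter_frequent_features()` removes features in
strictly more than 90% of compounds (by default) and stores the kept-set
for application to held-out data. Chemotype clustering uses Tanimoto
distances and a seeded Lloyd-style k-medians with 10 restarts;
`choose_k()` picks the elbow of the within-cluster sum of squares as the
largest second difference over the candidate range — "the elbow" needs
*some* operational definition and this is ours.

## Problem sizes used in the checks

The test-suite experiments run at deliberate desk scale: similarity
statistics with $T = 10$, $D = 10$ over 20–50 seeds; the
similarity-robustness experiment at $N = 45$, $T = 5$, $D = 14$ with 10
splits; learning curves at $N \in \{15, 45, 75\}$ over 10 seeds (nested
training prefixes per seed, fixed test sets — the cleanest way to isolate
the effect of added instances); oracle equivalences on $\sim$100 random
problems with $T \le 3$, $l \le 12$, $n \le 6$. These sizes are the
package's own trade-off between statistical stability and quick, fully
reproducible runs.

## Known limitations

* Linear models only — the solver exploits the linear kernel throughout;
  nonlinear kernels are out of scope.
* GRMT requires a non-negative similarity matrix; learning $A$ from data
  is not attempted (cosine/Spearman estimates are computed elsewhere and
  supplied).
* The grid-search tie-breaks, the leave-one-sequence-out redistribution
  rule, and the elbow rule are reasonable conventions, not canonical
  choices; all are documented above and easy to override.
* pIC50 curation reproduces a specific published cascade; other
  databases or endpoints (Ki, EC50) need adapted rules
  (`curation_rules()` exposes every threshold).
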