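# mtqsar

Multi-task support vector regression for multi-target QSAR modelling.

## The problem

A QSAR (quantitative structure–activity relationship) model predicts the
potency of a compound against one protein target — typically the pIC50,
the negative decadic logarithm of the molar IC50 — from a molecular
fingerprint. When a panel of related targets (e.g. protein kinases) is
modelled, the targets rarely have equally rich training data, yet their
binding pockets — and therefore their structure–activity relationships —
are often similar. Multi-task learning exploits this: instead of training
one SVR per target (*tSVM*) or pretending all targets are the same and
pooling everything (*1SVM*), it couples the per-target models so that
knowledge flows between similar tasks.

`mtqsar` implements two such couplings for linear ε-insensitive support
vector regression, for users who model panels of related protein targets
(medicinal/computational chemists, cheminformaticians) and for
methodological work on transfer learning in QSAR:

* **GRMT** (graph-regularized multi-task SVR). Task similarities are
  encoded in a non-negative symmetric adjacency matrix *A*; the penalty
  ¼ Σₛₜ A*ₛₜ* ‖**w**ₛ − **w**ₜ‖² = ½ Σₛₜ L*ₛₜ* **w**ₛᵀ**w**ₜ, with
  L = D − A the graph Laplacian, pulls the task weight vectors of similar
  tasks together. All tasks are trained jointly; the dual is solved by
  seeded coordinate descent where the effective inner products are
  weighted by M = (I_T + L)⁻¹.
* **TDMT** (top-down multi-task SVR). Tasks are leaves of a taxonomy
  (e.g. the human kinome tree). One model is trained per node, from the
  root down, each solving
  min_w (1−B)/2 ‖**w**‖² + B/2 ‖**w** − **w**_p‖² + C Σ_{i∈S} l_ε(**w**ᵀxᵢ, yᵢ),
  i.e. fitting its subtree's instances while staying close to the parent
  model with pull strength B ∈ [0, 1]. B comes either from the scaled
  taxonomy edge weights (*TDMTtax*) or from a per-node grid search with
  inner cross-validation (*TDMTgs*). The node problem reduces to a
  standard SVR dual with custom linear terms, so every node costs one
  SVR fit.

Both baselines (tSVM, 1SVM) are included, as are the supporting pieces:
a seeded dual coordinate-descent solver (L2 and L1 ε-insensitive loss),
taxonomy utilities (Newick I/O via ape, patristic distances, the
d → 1 − d/max similarity transform, UPGMA from correlation matrices), a
synthetic multi-task benchmark generator, activity-record curation and
fingerprint preprocessing (folding, frequent-feature removal, Tanimoto
k-medians chemotype clustering), and an evaluation harness (random
splits, nested CV, leave-one-sequence-out, paired Wilcoxon tests with
Holm or Benjamini–Hochberg correction).

## A worked example

Simulate five related tasks (each task's weights scatter around a shared
pattern; σ² = 0.5 β gives high task similarity), then compare independent,
pooled and multi-task training on ten train/test splits:

```r
library(mtqsar)
library(dplyr)

sim <- simulate_mt_tasks(n_per_task = 30, n_tasks = 5, n_attributes = 10,
                         sigma2 = 0.5 * 3, seed = 42)
sim
#> <mt_simulation> T = 5 tasks, N = 30/task, D = 10 (dim 60), beta = 3, sigma2 = 1.5

round(sim$similarity[1:3, 1:3], 2)   # cosine similarities of the task models
#>      [,1] [,2] [,3]
#> [1,] 1.00 0.75 0.74
#> [2,] 0.75 1.00 0.76
#> [3,] 0.74 0.76 1.00

perf <- benchmark_simulated(c("tSVM", "1SVM", "GRMT", "TDMTtax"),
                            n_per_task = 30, n_tasks = 5, n_attributes = 10,
                            n_splits = 5, seed = 42)
perf |> group_by(algorithm) |> summarise(mean_mse = mean(mse))
#>   algorithm mean_mse
#> 1 1SVM         18.0
#> 2 GRMT          9.78
#> 3 TDMTtax      10.4
#> 4 tSVM         30.4
```

With 30 instances per task and similar tasks, both multi-task methods
roughly halve the test MSE of independent per-task models (tSVM, 30.4),
while the pooled 1SVM (18.0) is limited by its assumption that all tasks
are identical. A single GRMT fit and its broom-style summary:

```r
fit <- train_grmt(sim$train, sim$similarity, C = 2, epsilon = 0.1)
glance(fit)
#>   n_tasks     C epsilon offset n_support_vectors regularizer dual_objective ...
#> 1       5     2     0.1  -1.18               150        224.          -901.
tidy(fit)          # per-task weight vectors, one row per nonzero term
autoplot(perf)     # MSE boxplots by algorithm
```

Per-task paired comparisons with multiplicity control
(`paired_tests(perf, "GRMT", "tSVM", correction = "holm")`) report
Better/NoChange/Worse labels per target.

For real data, `read_mt_dataset()` reads a sparse delimited format
(`instance_id`, `task_id`, `label`, `index:value` features),
`parse_newick()` reads a task taxonomy, and `distances_to_similarity()`
turns tree distances into a GRMT adjacency matrix. A thin command-line
wrapper with verbs `simulate`, `train`, `evaluate`, `loso` and `stats`
is installed at `inst/cli/mtqsar.R`.

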