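#' Sample task model weights for the synthetic multi-task benchmark
#'
#' Each task model is a weight vector over `6 * n_attributes` dimensions:
#' every attribute contributes a block of 6 sub-weights drawn independently
#' from Gaussians with means
#' \eqn{(-\beta, -\tfrac23\beta, -\tfrac13\beta, \tfrac13\beta,
#' \tfrac23\beta, \beta)} and common variance \eqn{\sigma^2}. `beta` sets
#' the signal scale (the lower, the noisier the learning problem);
#' \eqn{\sigma^2} controls how far tasks scatter around the shared mean
#' pattern and hence the task similarity — \eqn{\sigma^2 = 0.5\beta} gives
#' highly similar tasks, \eqn{\sigma^2 = 3\beta} dissimilar ones.
#'
#' @param n_tasks number of tasks T.
#' @param n_attributes number of attributes D (feature dimension is `6 * D`).
#' @param beta positive signal scale (default 3, the low-noise setting).
#' @param sigma2 non-negative Gaussian variance (default `0.5 * beta`).
#' @param seed integer seed.
#' @return A `T x 6D` matrix of task weight vectors (one per row).
#' @export
sample_task_weights <- function(n_tasks, n_attributes, beta = 3,
                                sigma2 = 0.5 * beta, seed = 1L) {
  stopifnot(n_tasks >= 1, n_attributes >= 1, beta > 0, sigma2 >= 0)
  mu <- attribute_means(n_attributes, beta)
  .with_seed(seed, {
    W <- matrix(stats::rnorm(n_tasks * 6 * n_attributes,
                             mean = rep(mu, each = n_tasks),
                             sd = sqrt(sigma2)),
                nrow = n_tasks)
    W
  })
}

#' @param n_attributes,beta as above.
#' @return `attribute_means()` returns the tiled mean pattern of length
#'   `6 * n_attributes` — the weight vector of the "mean model" that serves
#'   as the root of the star taxonomy.
#' @rdname sample_task_weights
#' @export
attribute_means <- function(n_attributes, beta = 3) {
  rep(c(-1, -2 / 3, -1 / 3, 1 / 3, 2 / 3, 1) * beta, n_attributes)
}

#' Sample one-hot attribute instances
#'
#' Each of the `n_attributes` attributes adopts one of 6 values uniformly at
#' random, encoded as a one-hot block of 6 bits, so every instance is a
#' binary vector of length `6 * n_attributes` with exactly `n_attributes`
#' ones.
#'
#' @param n number of instances.
#' @param n_attributes number of attributes D.
#' @param seed integer seed.
#' @return A sparse binary `n x 6D` matrix.
#' @export
sample_instances <- function(n, n_attributes, seed = 1L) {
  stopifnot(n >= 1, n_attributes >= 1)
  choice <- .with_seed(seed,
    matrix(sample.int(6L, n * n_attributes, replace = TRUE),
           nrow = n))
  j <- sweep(choice, 2, (seq_len(n_attributes) - 1L) * 6L, "+")
  Matrix::sparseMatrix(i = rep(seq_len(n), n_attributes),
                       j = as.integer(j), x = 1,
                       dims = c(n, 6L * n_attributes))
}

#' Noise-free targets under the task models
#'
#' Targets are computed with the linear multi-task prediction function
#' \eqn{y = w_t^T x}; no label noise is added.
#'
#' @param task_weights `T x 6D` matrix from [sample_task_weights()].
#' @param instances instances in rows (binary, `6D` columns).
#' @return An `n x T` matrix of targets, one column per task.
#' @export
compute_targets <- function(task_weights, instances) {
  stopifnot(ncol(instances) == ncol(task_weights))
  as.matrix(instances %*% t(task_weights))
}

#' Task-similarity structures from the generating weights
#'
#' For the graph-regularized method, the similarity of two tasks is the
#' cosine of their generating weight vectors (`variant = "cosine"`); the
#' `"anti"` variant returns `1 - cosine` and `"random"` uniform draws on
#' \[0, 1\]. The diagonal is always fixed to 1. Cosines can be negative for
#' dissimilar tasks; since the graph regularizer requires non-negative
#' entries, negatives are clipped to 0 when `clip = TRUE` (the raw values
#' are attached as attribute `"raw"`).
#'
#' @param task_weights `T x 6D` matrix of task weights.
#' @param variant `"cosine"`, `"anti"` or `"random"`.
#' @param clip clip negative entries to 0 (required by GRMT).
#' @param seed integer seed (used by the `"random"` variant).
#' @return A symmetric `T x T` similarity matrix with unit diagonal.
#' @export
similarity_from_weights <- function(task_weights,
                                    variant = c("cosine", "anti", "random"),
                                    clip = TRUE, seed = 1L) {
  variant <- match.arg(variant)
  Tn <- nrow(task_weights)
  stopifnot(Tn >= 2)
  nrm <- sqrt(rowSums(task_weights^2))
  if (any(nrm == 0)) stop("zero-norm task weight vector")
  cosm <- tcrossprod(task_weights / nrm)
  A <- switch(variant,
    cosine = cosm,
    anti = 1 - cosm,
    random = .with_seed(seed, {
      R <- matrix(0, Tn, Tn)
      R[upper.tri(R)] <- stats::runif(Tn * (Tn - 1) / 2)
      R + t(R)
    }))
  diag(A) <- 1
  raw <- A
  if (clip) A[A < 0] <- 0
  attr(A, "raw") <- raw
  A
}

#' Star taxonomy whose edge weights relate tasks to the mean model
#'
#' A root representing the mean of the sampling Gaussians is connected
#' directly to every task; each edge weight is the cosine similarity of the
#' task's weight vector to the mean-model weights ([attribute_means()]).
#' `"anti"` uses `1 - cosine`, `"random"` uniform weights. Negative weights
#' are clipped to 0 (edge weights are pull strengths in \[0, 1\]).
#'
#' @param task_weights `T x 6D` matrix of task weights.
#' @param beta signal scale used to generate the weights.
#' @param variant `"cosine"`, `"anti"` or `"random"`.
#' @param task_labels optional leaf labels.
#' @param seed integer seed (for the `"random"` variant).
#' @return A `phylo` star taxonomy.
#' @export
star_taxonomy_from_weights <- function(task_weights, beta = 3,
                                       variant = c("cosine", "anti",
                                                   "random"),
                                       task_labels = NULL, seed = 1L) {
  variant <- match.arg(variant)
  Tn <- nrow(task_weights)
  mu <- attribute_means(ncol(task_weights) / 6, beta)
  cosv <- as.numeric(task_weights %*% mu) /
    (sqrt(rowSums(task_weights^2)) * sqrt(sum(mu^2)))
  w <- switch(variant,
    cosine = cosv,
    anti = 1 - cosv,
    random = .with_seed(seed, stats::runif(Tn)))
  w <- pmin(pmax(w, 0), 1)
  if (is.null(task_labels)) task_labels <- paste0("task", seq_len(Tn))
  star_taxonomy(task_labels, w)
}

#' Generate a complete synthetic multi-task regression benchmark
#'
#' Emulates the controlled benchmark used to study multi-task SVR: `n_tasks`
#' linear task models drawn around a shared mean pattern
#' ([sample_task_weights()]), `n_per_task` one-hot training instances
#' sampled separately for each task, a fixed test set of `n_test` instances
#' per task, and noise-free targets \eqn{y = w_t^T x}. Also returns the
#' cosine task-similarity matrix and the star taxonomy derived from the
#' generating weights.
#'
#' One global `seed` fans out to independent substreams for weights, per-task
#' training instances and test instances, so each component is individually
#' reproducible.
#'
#' @param n_per_task training instances per task (N).
#' @param n_tasks number of tasks (T).
#' @param n_attributes number of attributes (D); instances have `6 * D`
#'   binary features.
#' @param beta signal scale (default 3).
#' @param sigma2 Gaussian variance controlling task similarity (default
#'   `0.5 * beta`, the high-similarity setting; use `3 * beta` for low).
#' @param n_test test instances per task.
#' @param shared_instances logical; reuse the same training instances for
#'   every task (targets still differ through the task models). Default
#'   FALSE: instances are sampled separately per task.
#' @param seed integer seed.
#' @return A list of class `mt_simulation` with elements `train`, `test`
#'   ([mt_dataset()]s), `weights`, `mean_model`, `similarity`, `taxonomy`,
#'   and the generating parameters.
#' @export
simulate_mt_tasks <- function(n_per_task = 100, n_tasks = 10,
                              n_attributes = 10, beta = 3,
                              sigma2 = 0.5 * beta, n_test = 25,
                              shared_instances = FALSE, seed = 1L) {
  W <- sample_task_weights(n_tasks, n_attributes, beta, sigma2,
                           seed = .substream(seed, 1))
  n6 <- 6L * n_attributes
  tr_list <- vector("list", n_tasks)
  if (shared_instances) {
    Xs <- sample_instances(n_per_task, n_attributes, .substream(seed, 2))
    for (t in seq_len(n_tasks)) tr_list[[t]] <- Xs
  } else {
    for (t in seq_len(n_tasks))
      tr_list[[t]] <- sample_instances(n_per_task, n_attributes,
                                       .substream(seed, 2 + t))
  }
  Xtr <- do.call(rbind, tr_list)
  task_tr <- rep(seq_len(n_tasks), each = n_per_task)
  ytr <- numeric(nrow(Xtr))
  for (t in seq_len(n_tasks)) {
    idx <- which(task_tr == t)
    ytr[idx] <- as.numeric(Xtr[idx, , drop = FALSE] %*% W[t, ])
  }
  te_list <- lapply(seq_len(n_tasks), function(t)
    sample_instances(n_test, n_attributes, .substream(seed, 1000 + t)))
  Xte <- do.call(rbind, te_list)
  task_te <- rep(seq_len(n_tasks), each = n_test)
  yte <- numeric(nrow(Xte))
  for (t in seq_len(n_tasks)) {
    idx <- which(task_te == t)
    yte[idx] <- as.numeric(Xte[idx, , drop = FALSE] %*% W[t, ])
  }
  labels <- paste0("task", seq_len(n_tasks))
  structure(
    list(train = mt_dataset(Xtr, ytr, task_tr, task_labels = labels),
         test = mt_dataset(Xte, yte, task_te, task_labels = labels),
         weights = W, mean_model = attribute_means(n_attributes, beta),
         similarity = similarity_from_weights(W, "cosine"),
         taxonomy = star_taxonomy_from_weights(W, beta, "cosine",
                                               task_labels = labels),
         n_per_task = n_per_task, n_tasks = n_tasks,
         n_attributes = n_attributes, beta = beta, sigma2 = sigma2,
         seed = seed),
    class = "mt_simulation")
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat(sprintf(
    "<mt_simulation> T = %d tasks, N = %d/task, D = %d (dim %d), beta = %g, sigma2 = %g\n",
    x$n_tasks, x$n_per_task, x$n_attributes, 6 * x$n_attributes,
    x$beta, x$sigma2))
  invisible(x)
}

#' Summary statistics of simulated task similarity
#'
#' Reproduces the two ways of quantifying how similar the generated tasks
#' are: the mean pairwise cosine similarity between the task weight vectors,
#' and the mean pairwise Pearson correlation between the tasks' noise-free
#' targets evaluated on a *common* set of instances.
#'
#' @param n_tasks,n_attributes,beta,sigma2 generator parameters (see
#'   [sample_task_weights()]).
#' @param n_instances size of the common instance set for the target
#'   correlations.
#' @param n_seeds number of independent repetitions to average over.
#' @param seed integer base seed.
#' @return A tibble with one row per repetition: `seed`, `cosine` and
#'   `pearson` (means over task pairs), plus `cosine_sd` and `pearson_sd`
#'   (the spread across task pairs within the repetition).
#' @export
simulated_similarity_stats <- function(n_tasks = 10, n_attributes = 10,
                                       beta = 3, sigma2 = 0.5 * beta,
                                       n_instances = 100, n_seeds = 20,
                                       seed = 1L) {
  purrr::map_dfr(seq_len(n_seeds), function(r) {
    s <- .substream(seed, r)
    W <- sample_task_weights(n_tasks, n_attributes, beta, sigma2, seed = s)
    A <- similarity_from_weights(W, "cosine", clip = FALSE)
    raw <- attr(A, "raw")
    X <- sample_instances(n_instances, n_attributes,
                          seed = .substream(s, 7))
    Y <- compute_targets(W, X)
    P <- stats::cor(Y)
    up <- upper.tri(raw)
    tibble::tibble(seed = s, cosine = mean(raw[up]), pearson = mean(P[up]),
                   cosine_sd = stats::sd(raw[up]),
                   pearson_sd = stats::sd(P[up]))
  })
}
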