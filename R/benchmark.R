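#' Benchmark algorithms on freshly simulated multi-task data
#'
#' Generates `n_splits` independent simulated train/test data sets
#' ([simulate_mt_tasks()]) and evaluates each requested algorithm on every
#' split, selecting C (and, for `TDMTgs`, B) by `inner_folds`-fold inner
#' cross-validation over `grids`. The task-similarity inputs handed to GRMT
#' and TDMTtax are derived from the generating weights of each split, in the
#' requested `similarity_variant`: `"cosine"` (the true similarities),
#' `"anti"` (`1 - cosine`) or `"random"`.
#'
#' @param algorithms character subset of
#'   `c("tSVM", "1SVM", "GRMT", "TDMTtax", "TDMTgs")`.
#' @param n_per_task,n_tasks,n_attributes,beta,sigma2,n_test,shared_instances
#'   generator parameters, see [simulate_mt_tasks()].
#' @param n_splits number of independently generated train/test splits.
#' @param similarity_variant similarity supplied to the multi-task methods.
#' @param grids see [make_grids()].
#' @param inner_folds inner CV folds for model selection.
#' @param seed integer seed; split r uses a substream of it.
#' @return A tibble of class `mt_performance` with columns `algorithm`,
#'   `task`, `split`, `mse`.
#' @export
benchmark_simulated <- function(algorithms = c("tSVM", "1SVM", "GRMT",
                                               "TDMTtax"),
                                n_per_task = 45, n_tasks = 5,
                                n_attributes = 14, beta = 3,
                                sigma2 = 0.5 * beta, n_test = 25,
                                n_splits = 10,
                                shared_instances = FALSE,
                                similarity_variant = c("cosine", "anti",
                                                       "random"),
                                grids = make_grids(), inner_folds = 3L,
                                seed = 1L) {
  similarity_variant <- match.arg(similarity_variant)
  purrr::map_dfr(seq_len(n_splits), function(r) {
    s <- .substream(seed, 37 * r)
    sim <- simulate_mt_tasks(n_per_task, n_tasks, n_attributes, beta,
                             sigma2, n_test = n_test,
                             shared_instances = shared_instances, seed = s)
    A <- similarity_from_weights(sim$weights, similarity_variant, seed = s)
    taxo <- star_taxonomy_from_weights(
      sim$weights, beta, similarity_variant,
      task_labels = sim$train$task_labels, seed = s)
    purrr::map_dfr(algorithms, function(alg) {
      predictor <- .fit_algorithm(alg, sim$train, A, taxo, grids,
                                  inner_folds, seed = s)
      dplyr::mutate(.per_task_mse(predictor, sim$test),
                    algorithm = alg, split = r, .before = 1)
    })
  }) |>
    .mt_performance()
}

#' Degradation of multi-task methods under misleading task similarities
#'
#' Runs [benchmark_simulated()] twice on identical splits — once with the
#' true cosine task similarities, once with anti-correlated ones
#' (`1 - cosine`) — and reports the percent increase in mean test MSE that
#' each similarity-consuming algorithm suffers. A method that is robust to
#' the supplied similarities shows a small increase; a method that leans
#' heavily on them degrades strongly.
#'
#' @inheritParams benchmark_simulated
#' @return A tibble with columns `algorithm`, `mse_true`, `mse_anti`,
#'   `pct_increase`.
#' @export
similarity_robustness <- function(algorithms = c("TDMTtax", "GRMT"),
                                  n_per_task = 45, n_tasks = 5,
                                  n_attributes = 14, beta = 3,
                                  sigma2 = 0.5 * beta, n_test = 25,
                                  n_splits = 10, grids = make_grids(),
                                  inner_folds = 3L, seed = 1L) {
  run <- function(variant)
    benchmark_simulated(algorithms, n_per_task, n_tasks, n_attributes,
                        beta, sigma2, n_test, n_splits,
                        similarity_variant = variant, grids = grids,
                        inner_folds = inner_folds, seed = seed)
  true <- run("cosine") |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(mse_true = mean(.data$mse), .groups = "drop")
  anti <- run("anti") |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(mse_anti = mean(.data$mse), .groups = "drop")
  dplyr::inner_join(true, anti, by = "algorithm") |>
    dplyr::mutate(pct_increase =
                    100 * (.data$mse_anti / .data$mse_true - 1))
}

#' Learning curves on simulated data
#'
#' For each seed, draws one set of task models and one fixed test set, then
#' evaluates every algorithm at increasing training sizes. Training sets are
#' nested (each size is a prefix of the next), so the effect of additional
#' instances is isolated from resampling noise; the test set stays the same
#' across sizes.
#'
#' @inheritParams benchmark_simulated
#' @param n_grid increasing vector of training sizes per task.
#' @param n_seeds number of independent repetitions.
#' @return A tibble with columns `algorithm`, `n_per_task`, `seed_rep`,
#'   `task`, `mse`.
#' @export
learning_curve_simulated <- function(algorithms = c("tSVM", "1SVM", "GRMT",
                                                    "TDMTtax"),
                                     n_grid = c(15, 45, 75),
                                     n_tasks = 5, n_attributes = 14,
                                     beta = 3, sigma2 = 0.5 * beta,
                                     n_test = 25, n_seeds = 10,
                                     grids = make_grids(),
                                     inner_folds = 3L, seed = 1L) {
  n_grid <- sort(n_grid)
  n_max <- max(n_grid)
  purrr::map_dfr(seq_len(n_seeds), function(r) {
    s <- .substream(seed, 91 * r)
    sim <- simulate_mt_tasks(n_max, n_tasks, n_attributes, beta, sigma2,
                             n_test = n_test, seed = s)
    A <- similarity_from_weights(sim$weights, "cosine")
    taxo <- sim$taxonomy
    purrr::map_dfr(n_grid, function(N) {
      keep <- unlist(lapply(seq_len(n_tasks), function(t)
        which(sim$train$task == t)[seq_len(N)]))
      train <- sim$train[keep]
      purrr::map_dfr(algorithms, function(alg) {
        predictor <- .fit_algorithm(alg, train, A, taxo, grids,
                                    inner_folds, seed = s)
        dplyr::mutate(.per_task_mse(predictor, sim$test),
                      algorithm = alg, n_per_task = N, seed_rep = r,
                      .before = 1)
      })
    })
  })
}
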