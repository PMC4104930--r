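#' Mean squared error
#' @param y_true,y_pred numeric vectors of equal, positive length.
#' @return Non-negative scalar.
#' @export
mse <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal positive length")
  mean((y_true - y_pred)^2)
}

#' Standard hyperparameter grids
#'
#' The default grid is \eqn{\log_2 C \in \{-5, -3, \dots, 7\}} (7 values)
#' with \eqn{B \in \{0, 0.1, 0.25, 0.5, 0.75, 0.9, 1\}} and the tube
#' half-width fixed at \eqn{\epsilon = 0.1}. The `"kinome_grmt"` setting
#' uses the coarser, larger grid \eqn{\log_2 C \in \{2, 4, 6, 8\}} suitable
#' for graph-regularized training over many tasks, where larger costs are
#' typically selected.
#'
#' @param setting `"default"` or `"kinome_grmt"`.
#' @return A list with elements `C`, `B` and `epsilon`.
#' @export
make_grids <- function(setting = c("default", "kinome_grmt")) {
  setting <- match.arg(setting)
  C <- switch(setting,
              default = 2^seq(-5, 7, by = 2),
              kinome_grmt = 2^seq(2, 8, by = 2))
  list(C = C, B = c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1.0), epsilon = 0.1)
}

#' Tube half-width implied by a relative assay error
#'
#' An IC50 measured with relative deviation `rel` corresponds to a deviation
#' of \eqn{\log_{10}(1 + rel)} on the pIC50 scale; a typical 25% relative
#' IC50 error maps to about 0.1 pIC50 units, the default epsilon used
#' throughout.
#'
#' @param rel relative deviation of the measured IC50 (e.g. 0.25 for 25%).
#' @param digits rounding of the returned pIC50 deviation.
#' @return The implied epsilon in pIC50 units.
#' @examples
#' epsilon_from_relative_error(0.25) # 0.1
#' @export
epsilon_from_relative_error <- function(rel, digits = 1) {
  stopifnot(rel > -1)
  round(log10(1 + rel), digits)
}

#' Experiment protocol description
#'
#' @param kind `"random_splits"`, `"nested_cv"` or
#'   `"leave_one_sequence_out"`.
#' @param repetitions number of repetitions (random splits or CV restarts).
#' @param outer_folds outer folds for `"nested_cv"`.
#' @param inner_folds folds of the inner model-selection cross-validation.
#' @param train_per_task,test_per_task instances drawn per task for
#'   `"random_splits"`/`"leave_one_sequence_out"`; test size must be >= 5.
#' @param seed integer seed.
#' @return A list of class `mt_protocol`.
#' @export
mt_protocol <- function(kind = c("random_splits", "nested_cv",
                                 "leave_one_sequence_out"),
                        repetitions = 10L, outer_folds = 3L,
                        inner_folds = 3L, train_per_task = NULL,
                        test_per_task = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inner_folds >= 2)
  if (kind == "nested_cv") stopifnot(outer_folds >= 2)
  if (!is.null(test_per_task) && test_per_task < 5)
    stop("test size per task must be >= 5")
  structure(list(kind = kind, repetitions = as.integer(repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 train_per_task = train_per_task,
                 test_per_task = test_per_task, seed = as.integer(seed)),
            class = "mt_protocol")
}

# ---- model selection helpers -------------------------------------------

# C by k-fold CV for a per-task independent SVR (one C per task)
.cv_select_C_svr <- function(dataset, C_grid, epsilon, inner_folds, seed) {
  if (length(C_grid) == 1) return(C_grid)
  folds <- .stratified_folds(rep(1L, length(dataset$y)), inner_folds, seed)
  errs <- vapply(C_grid, function(C) {
    mean(vapply(seq_len(inner_folds), function(k) {
      tr <- dataset[folds != k]
      va <- dataset[folds == k]
      fit <- train_svr(tr, C = C, epsilon = epsilon,
                       options = solver_options(seed = seed))
      mse(va$y, predict(fit, va))
    }, numeric(1)))
  }, numeric(1))
  sort(C_grid)[which.min(errs[order(C_grid)])]  # ties -> smaller C
}

# C by task-stratified k-fold CV for GRMT (joint training)
.cv_select_C_grmt <- function(dataset, A, C_grid, epsilon, inner_folds,
                              seed) {
  if (length(C_grid) == 1) return(C_grid)
  folds <- .stratified_folds(dataset$task, inner_folds, seed)
  errs <- vapply(C_grid, function(C) {
    mean(vapply(seq_len(inner_folds), function(k) {
      tr <- dataset[folds != k]
      va <- dataset[folds == k]
      fit <- train_grmt(tr, A, C = C, epsilon = epsilon,
                        options = solver_options(seed = seed))
      mse(va$y, predict(fit, va))
    }, numeric(1)))
  }, numeric(1))
  sort(C_grid)[which.min(errs[order(C_grid)])]
}

# fit one algorithm with inner-CV model selection; returns a prediction
# closure (X, task) -> yhat
.fit_algorithm <- function(algorithm, train, A, taxonomy, grids,
                           inner_folds, seed,
                           unseen_tasks = integer()) {
  eps <- grids$epsilon
  opts <- solver_options(seed = seed)
  switch(algorithm,
    tSVM = {
      fits <- lapply(seq_len(n_tasks(train)), function(t) {
        sub <- train[train$task == t]
        if (!length(sub$y)) return(NULL)
        C <- .cv_select_C_svr(sub, grids$C, eps, inner_folds, seed + t)
        train_svr(sub, C = C, epsilon = eps, options = opts)
      })
      function(X, task) {
        out <- numeric(nrow(X))
        for (t in unique(task)) {
          if (is.null(fits[[t]]))
            stop("tSVM has no model for task ", t)
          idx <- which(task == t)
          out[idx] <- predict(fits[[t]], X[idx, , drop = FALSE])
        }
        out
      }
    },
    `1SVM` = {
      pooled <- .pool_tasks(train)
      C <- .cv_select_C_svr(pooled, grids$C, eps, inner_folds, seed)
      fit <- train_svr(pooled, C = C, epsilon = eps, options = opts)
      function(X, task) predict(fit, X)
    },
    GRMT = {
      C <- .cv_select_C_grmt(train, A, grids$C, eps, inner_folds, seed)
      fit <- train_grmt(train, A, C = C, epsilon = eps,
                        unseen_tasks = unseen_tasks, options = opts)
      function(X, task) predict(fit, X, task)
    },
    TDMTtax = {
      cfg <- tdmt_config("tax", C_grid = grids$C, inner_folds = inner_folds,
                         epsilon = eps, seed = seed)
      fit <- train_tdmt(taxonomy, train, cfg)
      function(X, task) predict(fit, X, task)
    },
    TDMTgs = {
      cfg <- tdmt_config("gs", C_grid = grids$C, B_grid = grids$B,
                         inner_folds = inner_folds, epsilon = eps,
                         seed = seed)
      fit <- train_tdmt(taxonomy, train, cfg)
      function(X, task) predict(fit, X, task)
    },
    stop("unknown algorithm: ", algorithm)
  )
}

.mt_performance <- function(df) {
  class(df) <- c("mt_performance", class(df))
  df
}

# per-task test MSEs of a fitted predictor
.per_task_mse <- function(predictor, test) {
  purrr::map_dfr(sort(unique(test$task)), function(t) {
    idx <- which(test$task == t)
    yhat <- predictor(test$X[idx, , drop = FALSE], rep(t, length(idx)))
    tibble::tibble(task = test$task_labels[t],
                   mse = mse(test$y[idx], yhat))
  })
}

#' Run an evaluation protocol over algorithms on a multi-task dataset
#'
#' All algorithms see identical training/test splits in every repetition, so
#' their per-(task, split) MSEs are paired by construction. Hyperparameters
#' are selected per algorithm by inner cross-validation over the supplied
#' grids. A task too small for the requested split sizes is excluded with a
#' warning.
#'
#' @param algorithms character subset of
#'   `c("tSVM", "1SVM", "GRMT", "TDMTtax", "TDMTgs")`.
#' @param dataset an [mt_dataset()].
#' @param similarity symmetric task-similarity matrix (required by GRMT).
#' @param taxonomy `phylo` task taxonomy (required by the TDMT variants).
#' @param protocol an [mt_protocol()] of kind `"random_splits"` or
#'   `"nested_cv"`.
#' @param grids see [make_grids()].
#' @return A tibble of class `mt_performance` with columns `algorithm`,
#'   `task`, `split`, `mse`.
#' @export
run_protocol <- function(algorithms, dataset, similarity = NULL,
                         taxonomy = NULL, protocol = mt_protocol(),
                         grids = make_grids()) {
  stopifnot(inherits(dataset, "mt_dataset"))
  .check_algo_inputs(algorithms, similarity, taxonomy)
  splits <- .protocol_splits(dataset, protocol)
  purrr::imap_dfr(splits, function(sp, r) {
    train <- dataset[sp$train]
    test <- dataset[sp$test]
    purrr::map_dfr(algorithms, function(alg) {
      predictor <- .fit_algorithm(alg, train, similarity, taxonomy, grids,
                                  protocol$inner_folds,
                                  seed = protocol$seed + 131 * r)
      dplyr::mutate(.per_task_mse(predictor, test),
                    algorithm = alg, split = r, .before = 1)
    })
  }) |>
    .mt_performance()
}

.check_algo_inputs <- function(algorithms, similarity, taxonomy) {
  if ("GRMT" %in% algorithms && is.null(similarity))
    stop("GRMT requires a similarity matrix")
  if (any(c("TDMTtax", "TDMTgs") %in% algorithms) && is.null(taxonomy))
    stop("TDMT requires a taxonomy")
}

# list of train/test instance index pairs per repetition
.protocol_splits <- function(dataset, protocol) {
  tasks <- seq_len(n_tasks(dataset))
  counts <- tabulate(dataset$task, n_tasks(dataset))
  if (protocol$kind == "random_splits") {
    ntr <- protocol$train_per_task
    nte <- protocol$test_per_task
    if (is.null(ntr) || is.null(nte))
      stop("random_splits needs train_per_task and test_per_task")
    usable <- counts >= ntr + nte
    if (!all(usable[counts > 0]))
      warning("excluding task(s) with too few instances: ",
              paste(dataset$task_labels[counts > 0 & !usable],
                    collapse = ", "))
    lapply(seq_len(protocol$repetitions), function(r) {
      .with_seed(.substream(protocol$seed, r), {
        tr <- te <- integer()
        for (t in tasks[usable]) {
          idx <- sample(which(dataset$task == t))
          tr <- c(tr, idx[seq_len(ntr)])
          te <- c(te, idx[ntr + seq_len(nte)])
        }
        list(train = tr, test = te)
      })
    })
  } else if (protocol$kind == "nested_cv") {
    k <- protocol$outer_folds
    out <- list()
    for (r in seq_len(protocol$repetitions)) {
      folds <- .stratified_folds(dataset$task, k,
                                 .substream(protocol$seed, 7000 + r))
      for (f in seq_len(k)) {
        out[[length(out) + 1]] <-
          list(train = which(folds != f), test = which(folds == f))
      }
    }
    out
  } else stop("use leave_one_sequence_out() for that protocol kind")
}

#' Leave-one-sequence-out evaluation
#'
#' For every task in turn, all of its training data are removed and its
#' training budget is redistributed uniformly over the remaining tasks
#' (remainder going to the tasks with the most available instances), keeping
#' the total training size equal to the standard protocol's. The multi-task
#' models must then predict the held-out task's fixed test set without ever
#' having seen one of its instances: the TDMT variants predict through the
#' held-out leaf's parent model, and GRMT drops the held-out task's ridge
#' term so its weight is determined purely by similarity to the trained
#' tasks. GRMT is skipped (with a message) for a held-out task whose
#' similarity to every other task is zero.
#'
#' @inheritParams run_protocol
#' @param protocol an [mt_protocol()] with `train_per_task` and
#'   `test_per_task` set.
#' @return A tibble of class `mt_performance` with columns `algorithm`,
#'   `task` (the held-out task), `split`, `mse`.
#' @export
leave_one_sequence_out <- function(algorithms, dataset, similarity = NULL,
                                   taxonomy = NULL,
                                   protocol = mt_protocol(
                                     "leave_one_sequence_out",
                                     train_per_task = 25,
                                     test_per_task = 10),
                                   grids = make_grids()) {
  stopifnot(inherits(dataset, "mt_dataset"), n_tasks(dataset) >= 2)
  .check_algo_inputs(algorithms, similarity, taxonomy)
  ntr <- protocol$train_per_task
  nte <- protocol$test_per_task
  Tn <- n_tasks(dataset)
  counts <- tabulate(dataset$task, Tn)
  purrr::map_dfr(seq_len(protocol$repetitions), function(r) {
    purrr::map_dfr(seq_len(Tn), function(t_out) {
      seed_r <- .substream(protocol$seed, 5000 + 61 * r + t_out)
      # redistribute t_out's budget uniformly; remainder to largest tasks
      rest <- setdiff(seq_len(Tn), t_out)
      budget <- rep(ntr, Tn)
      budget[t_out] <- 0
      extra <- ntr %/% length(rest)
      budget[rest] <- budget[rest] + extra
      rem <- ntr %% length(rest)
      if (rem > 0) {
        big <- rest[order(counts[rest], decreasing = TRUE)][seq_len(rem)]
        budget[big] <- budget[big] + 1
      }
      budget <- pmin(budget, pmax(counts - ifelse(seq_len(Tn) == t_out,
                                                  nte, 0), 0))
      sel <- .with_seed(seed_r, {
        tr <- te <- integer()
        for (t in seq_len(Tn)) {
          idx <- sample(which(dataset$task == t))
          if (t == t_out) {
            te <- c(te, idx[seq_len(min(nte, length(idx)))])
          } else {
            tr <- c(tr, idx[seq_len(budget[t])])
          }
        }
        list(train = tr, test = te)
      })
      train <- dataset[sel$train]
      test <- dataset[sel$test]
      purrr::map_dfr(algorithms, function(alg) {
        if (alg == "GRMT" &&
            all(similarity[t_out, -t_out] == 0)) {
          message("GRMT skipped for held-out task ",
                  dataset$task_labels[t_out],
                  ": zero similarity to all trained tasks")
          return(tibble::tibble())
        }
        predictor <- .fit_algorithm(
          alg, train, similarity, taxonomy, grids, protocol$inner_folds,
          seed = seed_r,
          unseen_tasks = if (alg == "GRMT") t_out else integer())
        yhat <- predictor(test$X, test$task)
        tibble::tibble(algorithm = alg,
                       task = dataset$task_labels[t_out],
                       split = r, mse = mse(test$y, yhat))
      })
    })
  }) |>
    .mt_performance()
}

#' Paired significance tests between two algorithms
#'
#' For every task, the per-split MSEs of the two algorithms (paired by
#' `(task, split)`) are compared with a two-sided Wilcoxon signed-rank test;
#' p-values across the task family are adjusted with Holm's method (default,
#' controls the family-wise error — the subset setting) or
#' Benjamini-Hochberg (controls the FDR — the kinome setting, one family per
#' baseline comparison over all targets). Each task is labelled `"Better"`
#' (significant, `algo_a` has lower median paired MSE), `"Worse"`
#' (significant, higher), or `"NoChange"`.
#'
#' All paired differences being exactly zero yields p = 1 by convention
#' (flagged in the `degenerate` column).
#'
#' @param table an `mt_performance` tibble (columns `algorithm`, `task`,
#'   `split`, `mse`).
#' @param algo_a,algo_b algorithm names to compare (`algo_a` is the focal
#'   method).
#' @param correction `"holm"` or `"BH"`.
#' @param alpha significance level.
#' @return A tibble with one row per task: `task`, `p_value`, `p_adjusted`,
#'   `median_diff` (median of `mse_a - mse_b`), `label`, `degenerate`; the
#'   summary counts are attached as attribute `"summary"`.
#' @export
paired_tests <- function(table, algo_a, algo_b,
                         correction = c("holm", "BH"), alpha = 0.05) {
  correction <- match.arg(correction)
  wide <- table |>
    dplyr::filter(.data$algorithm %in% c(algo_a, algo_b)) |>
    tidyr::pivot_wider(id_cols = c("task", "split"),
                       names_from = "algorithm", values_from = "mse")
  if (!all(c(algo_a, algo_b) %in% names(wide)))
    stop("both algorithms must appear in the table")
  if (anyNA(wide[[algo_a]]) || anyNA(wide[[algo_b]]))
    stop("algorithms are not evaluated on identical (task, split) pairs")
  res <- wide |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(
      p_value = {
        d <- .data[[algo_a]] - .data[[algo_b]]
        if (all(d == 0)) 1.0
        else .wilcoxon_p(.data[[algo_a]], .data[[algo_b]])
      },
      median_diff = stats::median(.data[[algo_a]] - .data[[algo_b]]),
      degenerate = all(.data[[algo_a]] == .data[[algo_b]]),
      .groups = "drop")
  res$p_adjusted <- stats::p.adjust(res$p_value, method = correction)
  res$label <- dplyr::case_when(
    res$p_adjusted < alpha & res$median_diff < 0 ~ "Better",
    res$p_adjusted < alpha & res$median_diff > 0 ~ "Worse",
    TRUE ~ "NoChange")
  attr(res, "summary") <- table(factor(res$label,
                                       c("Worse", "NoChange", "Better")))
  res
}

# exact Wilcoxon for <= 25 pairs, normal approximation with continuity
# correction above
.wilcoxon_p <- function(a, b) {
  n <- length(a)
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = n <= 25,
                       correct = TRUE)$p.value)
}
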